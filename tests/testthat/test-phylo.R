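# Distance trees, bootstrap supports, and the dual-tree clade rule.

test_that("nj_tree validates input and resolves three taxa in closed form", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  ## three-point formulas: x = (dab + dac - dbc)/2 etc.
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl["a"]), (5 + 9 - 10) / 2)
  expect_equal(unname(bl["b"]), (5 + 10 - 9) / 2)
  expect_equal(unname(bl["c"]), (9 + 10 - 5) / 2)
  bad <- d; bad[1, 2] <- 4
  expect_error(nj_tree(bad), "symmetric")
  dd <- d; diag(dd) <- 1
  expect_error(nj_tree(dd), "diagonal")
})

test_that("nj recovers the generating topology from an additive matrix", {
  set.seed(8)
  ref <- ape::rtree(8)
  ref$edge.length <- runif(nrow(ref$edge), 0.2, 1)
  d <- cophenetic(ref)
  tr <- nj_tree(d)
  expect_identical(ape::dist.topo(ape::unroot(ref), ape::unroot(tr))[1], 0)
  ## two identical taxa become siblings
  d2 <- d
  d2 <- cbind(rbind(d2, dup = d2["t1", ]), dup = c(d2[, "t1"], 0))
  d2["t1", "dup"] <- d2["dup", "t1"] <- 0
  tr2 <- nj_tree(d2)
  mrca <- ape::getMRCA(tr2, c("t1", "dup"))
  tips <- tr2$tip.label[ape::prop.part(tr2)[[mrca - length(tr2$tip.label)]]]
  expect_identical(sort(tips), c("dup", "t1"))
})

test_that("bootstrap supports behave at the extremes and are reproducible", {
  ## two deeply separated 4-leaf groups, 500 concordant columns
  set.seed(12)
  g1 <- matrix("A", 4, 500); g2 <- matrix("C", 4, 500)
  noise <- matrix(sample(c("A", "C", "G", "T"), 8 * 60, replace = TRUE), 8, 60)
  aln <- cbind(rbind(g1, g2), noise)
  rownames(aln) <- paste0("t", 1:8)
  ## perturb within groups so distances are distinct
  for (i in 1:8) aln[i, sample(500, 20)] <- "G"
  tr <- bootstrap_supports(aln, n_reps = 100, seed = 4)
  sides <- oracle_clade_sides(tr)
  central <- sides[vapply(names(sides), function(k) {
    s <- strsplit(k, "|", fixed = TRUE)[[1]]
    setequal(s, paste0("t", 1:4)) || setequal(s, paste0("t", 5:8))
  }, logical(1))]
  expect_true(length(central) >= 1)
  expect_true(all(unlist(central) >= 99))
  ## n_reps = 0: no supports, same topology
  tr0 <- bootstrap_supports(aln, n_reps = 0)
  expect_null(tr0$node.label)
  expect_identical(ape::dist.topo(tr, tr0)[1], 0)
  ## fixed seed reproduces supports
  tr2 <- bootstrap_supports(aln, n_reps = 100, seed = 4)
  expect_identical(tr$node.label, tr2$node.label)
})

test_that("delineate_clades requires support in both trees", {
  ## identical 9-leaf trees; {c,d,e} is fully supported, and the supported
  ## deep bipartition also exposes its minority side {f,g,h,i}
  nwk_a <- "((a:1,(b:1,(c:0.1,(d:0.1,e:0.1)100:0.1)100:1)50:1)100:1,(f:1,g:1)30:1,(h:1,i:1)40:1);"
  ta <- ape::read.tree(text = nwk_a)
  tb <- ape::read.tree(text = nwk_a)
  has_set <- function(cs, set) {
    any(vapply(cs$members, setequal, logical(1), set))
  }
  cs <- delineate_clades(ta, tb, min_support = 90, min_members = 3)
  expect_true(has_set(cs, c("c", "d", "e")))
  expect_true(all(cs$support_a >= 90 & cs$support_b >= 90 & cs$size >= 3))
  ## support 89 in one tree excludes the clade at threshold 90
  nwk_b <- sub("\\)100:0.1\\)100", ")100:0.1)89", nwk_a)
  tb89 <- ape::read.tree(text = nwk_b)
  cs89 <- delineate_clades(ta, tb89, min_support = 90, min_members = 3)
  expect_false(has_set(cs89, c("c", "d", "e")))
  ## min_members excludes small clades
  cs4 <- delineate_clades(ta, tb, min_support = 90, min_members = 4)
  expect_false(has_set(cs4, c("c", "d", "e")))
  ## a clade below threshold in both trees is never reported
  expect_false(has_set(cs, c("f", "g")))
  ## leaf-set mismatch errors
  tc <- ape::drop.tip(tb, "a")
  expect_error(delineate_clades(ta, tc), "identical leaf set")
})

test_that("moving one leaf between trees removes the affected clade only", {
  sim <- cached_sim("clade_sim", function() {
    suppressWarnings(simulate_pangenome(sim_config(
      n_genomes = 30, n_clades = 5, mean_len = 9000, sd_len = 400,
      mean_orfs = 10, sd_orfs = 1, n_core = 6, mean_unique = 1,
      module_prevalence = 0, seed = 3), sequences = FALSE))
  })
  aln <- og_alignment(sim$genes, sprintf("og_core%02d", 1:6))
  half <- ncol(aln) %/% 2
  ta <- bootstrap_supports(aln[, 1:half], n_reps = 200, seed = 1)
  tb <- bootstrap_supports(aln[, (half + 1):ncol(aln)], n_reps = 200, seed = 2)
  cs <- delineate_clades(ta, tb)
  truth <- lapply(split(sim$genome_info$genome_id, sim$genome_info$clade), sort)
  found <- lapply(cs$members, sort)
  expect_identical(length(found), length(truth))
  for (tt in truth) {
    expect_true(any(vapply(found, setequal, logical(1), tt)))
  }
  ## disjointness and support floors hold on every output row
  expect_identical(anyDuplicated(unlist(found)), 0L)
  expect_true(all(cs$support_a >= 90 & cs$support_b >= 90 & cs$size >= 3))
  ## perturb: in tree B's data, one member of the largest clade becomes an
  ## outlier; that clade (as a full set) must vanish, others stay intact
  big <- truth[[which.max(lengths(truth))]]
  leaf <- big[1]
  aln_b <- aln[, (half + 1):ncol(aln)]
  set.seed(99)
  aln_b[leaf, ] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                          ncol(aln_b), replace = TRUE)
  tb2 <- bootstrap_supports(aln_b, n_reps = 200, seed = 2)
  cs2 <- delineate_clades(ta, tb2)
  found2 <- lapply(cs2$members, sort)
  expect_false(any(vapply(found2, setequal, logical(1), big)))
  for (tt in truth[!vapply(truth, setequal, logical(1), big)]) {
    expect_true(any(vapply(found2, setequal, logical(1), tt)))
  }
  ## any residue of the perturbed clade is a strict subset of it
  extra <- found2[!vapply(found2, function(f) {
    any(vapply(truth, setequal, logical(1), f))
  }, logical(1))]
  for (e in extra) expect_true(all(e %in% big))
})

test_that("supports in [0, 1] are rescaled to percent with a warning", {
  nwk <- "((a:1,(c:0.1,(d:0.1,e:0.1)1.0:0.1)0.95:1)1.0:1,(f:1,g:1)0.3:1,h:1);"
  ta <- ape::read.tree(text = nwk)
  ws <- testthat::capture_warnings(cs <- delineate_clades(ta, ta, min_support = 90))
  expect_true(any(grepl("rescaling", ws)))
  expect_identical(sort(cs$members[[1]]), c("c", "d", "e"))
})

test_that("sister_group_labels reports the sister taxa and monophyly", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  res <- sister_group_labels(tr, c("a", "b"))
  expect_identical(sort(res$sister_tips), c("c", "d"))
  expect_true(res$monophyletic)
  ## scattered query: monophyly flag false (here the containing clade is the
  ## whole tree, which has no sister)
  expect_warning(res2 <- sister_group_labels(tr, c("a", "c")), "root")
  expect_false(res2$monophyletic)
  ## labeled sister group: viral clade nested among labeled bacteria
  tr2 <- ape::read.tree(
    text = "(((v1:1,v2:1):1,(p1:1,p2:1):1):1,(p3:1,p4:1):1);")
  labels <- c(v1 = "virus", v2 = "virus", p1 = "Alphaproteobacteria",
              p2 = "Alphaproteobacteria", p3 = "Alphaproteobacteria",
              p4 = "Alphaproteobacteria")
  res3 <- sister_group_labels(tr2, c("v1", "v2"), labels)
  expect_identical(unique(res3$sister_labels), "Alphaproteobacteria")
})
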