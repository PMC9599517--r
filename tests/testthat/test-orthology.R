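# Protein similarity, orthogroup clustering, AAI, reference screening.

test_that("protein_similarity reports identity over alignment columns", {
  p <- random_aa_str(20, seed = 1)
  e <- protein_similarity(p, p)
  expect_identical(e$identity, 100)
  expect_identical(e$coverage, 1)
  ## one substitution in a 10-mer: 90%
  a <- "MKLVNNPQRS"
  b <- "MKLVANPQRS"
  expect_equal(protein_similarity(a, b)$identity, 90)
  expect_error(protein_similarity("MK1", "MKL"), "non-amino-acid")
})

test_that("alignment scores match an independently coded affine-gap DP", {
  set.seed(5)
  for (i in 1:25) {
    a <- random_aa_str(sample(20:50, 1))
    b <- if (i %% 3 == 0) mutate_protein(a, 0.3) else random_aa_str(sample(20:50, 1))
    got <- protein_similarity(a, b)
    want <- oracle_global_align(a, b)
    expect_equal(got$score, want$score, tolerance = 1e-8,
                 info = paste("pair", i))
  }
})

test_that("high-identity pairs have identical identity in DP oracle and package", {
  set.seed(9)
  for (i in 1:10) {
    a <- random_aa_str(40)
    b <- mutate_protein(a, 0.1)
    got <- protein_similarity(a, b)
    want <- oracle_global_align(a, b)
    expect_equal(got$identity, want$identity, tolerance = 1e-8)
  }
})

test_that("candidate_pairs prefilters without losing similar pairs", {
  prots <- c(x = random_aa_str(60, seed = 2))
  prots["y"] <- prots["x"]
  prots["z"] <- random_aa_str(60)
  prs <- candidate_pairs(prots)
  expect_true(any(prs$id_a == "x" & prs$id_b == "y"))
  ## disjoint k-mer sets: absent
  prots2 <- c(a = strrep("AC", 20), b = strrep("KW", 20))
  expect_identical(nrow(candidate_pairs(prots2)), 0L)
  expect_error(candidate_pairs(prots, k = 2), "k must be")
  ## fixture: groups at modest divergence — every within-group pair with
  ## >= 45% identity survives the prefilter
  set.seed(3)
  anc <- lapply(1:4, function(i) random_aa_str(150))
  fam <- unlist(lapply(seq_along(anc), function(i) {
    setNames(vapply(1:3, function(j) mutate_protein(anc[[i]], 0.1),
                    character(1)),
             paste0("g", i, "_", 1:3))
  }))
  prs <- candidate_pairs(fam, k = 5, jaccard_min = 0.05)
  ed <- similarity_edges(fam, prefilter = FALSE)
  want <- ed[ed$identity >= 45, ]
  have <- paste(pmin(prs$id_a, prs$id_b), pmax(prs$id_a, prs$id_b))
  for (i in seq_len(nrow(want))) {
    expect_true(paste(pmin(want$gene_a[i], want$gene_b[i]),
                      pmax(want$gene_a[i], want$gene_b[i])) %in% have,
                info = paste(want$gene_a[i], want$gene_b[i]))
  }
})

test_that("build_orthogroups clusters thresholded components deterministically", {
  p <- random_aa_str(50, seed = 4)
  prots <- c(a1 = p, b1 = p, c1 = p)
  ed <- similarity_edges(prots, prefilter = FALSE)
  og <- build_orthogroups(ed)
  expect_identical(nrow(og$orthogroups), 3L)
  expect_identical(length(unique(og$orthogroups$og_id)), 1L)
  ## empty edge set: all singletons
  og0 <- build_orthogroups(ed[0, ], gene_ids = names(prots))
  expect_identical(nrow(og0$orthogroups), 0L)
  expect_identical(og0$singletons, sort(names(prots)))
  ## lowering min_identity only merges components: every strict-threshold
  ## group is wholly contained in one loose-threshold group
  sim <- protein_sim()
  prots <- setNames(sim$genes$protein, sim$genes$gene_id)
  ed <- similarity_edges(prots, prefilter = TRUE, k = 4, jaccard_min = 0.01)
  strict <- build_orthogroups(ed, min_identity = 60)$orthogroups
  loose <- build_orthogroups(ed, min_identity = 30)$orthogroups
  loose_of <- setNames(loose$og_id, loose$gene_id)
  for (grp in split(strict$gene_id, strict$og_id)) {
    expect_identical(length(unique(loose_of[grp])), 1L)
  }
})

test_that("planted orthogroups are recovered exactly (ARI = 1)", {
  sim <- protein_sim()
  prots <- setNames(sim$genes$protein, sim$genes$gene_id)
  ed <- similarity_edges(prots, prefilter = FALSE)
  og <- build_orthogroups(ed, gene_ids = names(prots))
  pred <- setNames(character(length(prots)), names(prots))
  pred[og$orthogroups$gene_id] <- og$orthogroups$og_id
  pred[og$singletons] <- og$singletons
  truth <- setNames(sim$genes$og_id, sim$genes$gene_id)
  expect_identical(mclust::adjustedRandIndex(pred[names(truth)], truth), 1)
  ## partition property: each gene in exactly one group or singleton
  expect_identical(sort(c(og$orthogroups$gene_id, og$singletons)),
                   sort(names(prots)))
})

test_that("AAI follows the reciprocal-best-hit definition", {
  p <- lapply(1:5, function(i) random_aa_str(80, seed = 40 + i))
  a <- setNames(vapply(p, identity, character(1)), paste0("a", 1:5))
  ## construct one-to-one partners with planted identities 100/90/80/70/60
  divs <- c(0, 0.1, 0.2, 0.3, 0.4)
  b <- setNames(vapply(1:5, function(i) {
    mutate_protein(a[[i]], divs[i], seed = 90 + i)
  }, character(1)), paste0("b", 1:5))
  ids <- vapply(1:5, function(i) protein_similarity(a[[i]], b[[i]])$identity,
                numeric(1))
  expect_equal(compute_aai(a, b), mean(ids), tolerance = 1e-8)
  ## self-AAI and symmetry
  expect_identical(compute_aai(a, a), 100)
  expect_equal(compute_aai(a, b), compute_aai(b, a), tolerance = 1e-8)
  ## undefined is NA, distinct from 0
  junk1 <- c(x = strrep("AC", 30))
  junk2 <- c(y = strrep("KW", 30))
  expect_warning(val <- compute_aai(junk1, junk2), "undefined")
  expect_true(is.na(val))
})

test_that("AAI fixture with planted RBH identities averages to 80", {
  ## five orthologous pairs at measured identities; AAI is their mean
  set.seed(77)
  a <- setNames(vapply(1:5, function(i) random_aa_str(100), character(1)),
                paste0("a", 1:5))
  target <- c(100, 90, 80, 70, 60)
  b <- a
  names(b) <- paste0("b", 1:5)
  for (i in 1:5) {
    ## iteratively mutate until the measured identity matches the target
    repeat {
      id <- protein_similarity(a[[i]], b[[i]])$identity
      if (id <= target[i]) break
      ch <- strsplit(b[[i]], "")[[1]]
      pos <- sample(100, 1)
      ch[pos] <- sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                ch[pos]), 1)
      cand <- paste(ch, collapse = "")
      if (protein_similarity(a[[i]], cand)$identity >= target[i]) b[[i]] <- cand
      else break
    }
  }
  got <- vapply(1:5, function(i) protein_similarity(a[[i]], b[[i]])$identity,
                numeric(1))
  expect_equal(got, target, tolerance = 1e-8)
  expect_equal(compute_aai(a, b), 80, tolerance = 1e-8)
})

test_that("screen_by_reference applies the 45% identity floor", {
  ref <- random_aa_str(150, seed = 55)
  genomes <- list(
    exact = c(ref, random_aa_str(100)),
    none = vapply(1:3, function(i) random_aa_str(120), character(1)))
  expect_identical(screen_by_reference(genomes, ref), "exact")
  ## construct proteins just below and above the floor
  below <- mutate_protein(ref, 0.8, seed = 1)
  above <- mutate_protein(ref, 0.3, seed = 1)
  id_below <- protein_similarity(ref, below)$identity
  id_above <- protein_similarity(ref, above)$identity
  expect_lt(id_below, 45)
  expect_gt(id_above, 45)
  g2 <- list(lo = c(below), hi = c(above))
  expect_identical(screen_by_reference(g2, ref), "hi")
  expect_error(screen_by_reference(g2, character(0)), "non-empty")
})
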