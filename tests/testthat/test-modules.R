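# AMG classification, partner analysis, module extraction and statistics.

toy_genes <- function(components, strand = "+", contig = "c1",
                      pad_before = 2, pad_after = 2) {
  comps <- c(rep("none", pad_before), components, rep("none", pad_after))
  n <- length(comps)
  data.frame(
    contig_id = contig,
    gene_id = paste0(contig, "_", seq_len(n)),
    start = (seq_len(n) - 1L) * 700L, length = 650L,
    strand = ifelse(comps == "none", "+", strand),
    label = ifelse(comps == "none", "hypothetical protein", comps),
    category = ifelse(comps == "none", "hypothetical", "AMG-T8SS"),
    component = comps, stringsAsFactors = FALSE)
}

test_that("classify_amgs selects cellular-function categories only", {
  ft <- data.frame(
    gene_id = paste0("g", 1:4),
    label = c("thymidylate synthase (TS)", "terminase", "hypothetical protein",
              "ferrochelatase"),
    category = c("AMG-nucleotide", "core-viral", "hypothetical", "AMG-other"),
    stringsAsFactors = FALSE)
  amg <- classify_amgs(ft)
  expect_identical(amg$gene_id, c("g1", "g4"))
  ## a curated core label is excluded even when categorized as AMG
  ft$category[2] <- "AMG-other"
  amg2 <- classify_amgs(ft, core_set = "terminase")
  expect_identical(amg2$gene_id, c("g1", "g4"))
  ## synthetic fixture: AMG set equals planted truth
  sim <- protein_sim()
  amg3 <- classify_amgs(sim$genes)
  expect_identical(sort(amg3$gene_id),
                   sort(sim$genes$gene_id[startsWith(sim$genes$category, "AMG-")]))
})

test_that("adjacency implication matches an exhaustive scan", {
  ## every x flanked by y: holds
  g <- data.frame(genome_id = "g", gene_id = paste0("g", 1:5),
                  start = 0:4 * 100, strand = "+",
                  label = c("h", "x", "y", "h", "h"),
                  category = "hypothetical", stringsAsFactors = FALSE)
  expect_true(adjacency_implication(g, "x", "y")$holds)
  ## isolated x: that genome is a counterexample
  g2 <- g; g2$label <- c("h", "x", "h", "h", "y")
  res <- adjacency_implication(g2, "x", "y", max_gap_genes = 1,
                               circular = FALSE)
  expect_false(res$holds)
  expect_identical(res$counterexamples, "g")
  ## circular wrap: x at one end, y at the other
  g3 <- g; g3$label <- c("y", "h", "h", "h", "x")
  expect_true(adjacency_implication(g3, "x", "y", max_gap_genes = 0,
                                    circular = TRUE)$holds)
  expect_false(adjacency_implication(g3, "x", "y", max_gap_genes = 0,
                                     circular = FALSE)$holds)
  ## random genomes: equals a brute-force neighborhood scan
  set.seed(6)
  for (rep in 1:20) {
    n <- sample(6:14, 1)
    labs <- sample(c("x", "y", "h"), n, replace = TRUE,
                   prob = c(0.2, 0.2, 0.6))
    gg <- data.frame(genome_id = "r", gene_id = paste0("r", 1:n),
                     start = (1:n) * 10, strand = "+", label = labs,
                     category = "hypothetical", stringsAsFactors = FALSE)
    got <- adjacency_implication(gg, "x", "y", max_gap_genes = 1,
                                 circular = TRUE)$holds
    ix <- which(labs == "x"); iy <- which(labs == "y")
    want <- TRUE
    if (length(ix) > 0) {
      want <- FALSE
      for (i in ix) {
        for (j in iy) {
          d <- min(abs(i - j), n - abs(i - j))
          if (d >= 1 && d <= 2) want <- TRUE
        }
      }
    }
    expect_identical(got, want, info = paste("rep", rep))
  }
  ## generator invariant: ferrochelatase always next to a 2OG oxygenase
  sim <- protein_sim()
  expect_true(adjacency_implication(sim$genes, "ferrochelatase",
                                    "2OG-Fe(II) oxygenase")$holds)
})

test_that("partner_amg_pairs requires colocation and a shared category", {
  g <- data.frame(
    genome_id = "g", gene_id = paste0("g", 1:6),
    start = 0:5 * 100, strand = "+",
    label = c("TS", "h", "aG/PT-PPlase1", "purM", "ferrochelatase", "h"),
    category = c("AMG-hypermodification", "hypothetical",
                 "AMG-hypermodification", "AMG-nucleotide", "AMG-other",
                 "hypothetical"),
    stringsAsFactors = FALSE)
  prs <- partner_amg_pairs(g, window_genes = 5)
  key <- paste(prs$label_a, prs$label_b)
  expect_true("TS aG/PT-PPlase1" %in% key)
  ## different categories adjacent: not partners
  expect_false(any(grepl("purM ferrochelatase", key)))
  expect_false(any(grepl("ferrochelatase purM", key)))
  ## brute force equality on a random fixture
  set.seed(14)
  cats <- c("AMG-nucleotide", "AMG-other", "hypothetical")
  gg <- data.frame(genome_id = "r", gene_id = paste0("r", 1:12),
                   start = 0:11 * 50, strand = "+",
                   label = paste0("l", 1:12),
                   category = sample(cats, 12, replace = TRUE),
                   stringsAsFactors = FALSE)
  got <- partner_amg_pairs(gg, window_genes = 3, circular = FALSE)
  want <- 0L
  for (i in 1:11) for (j in (i + 1):12) {
    if (startsWith(gg$category[i], "AMG-") && gg$category[i] == gg$category[j] &&
        (j - i) <= 4) want <- want + 1L
  }
  expect_identical(nrow(got), want)
})

test_that("module extraction reads compositions canonically", {
  g <- toy_genes(c("HK", "CsgF", "CsgG", "CsgA/B", "FecR"))
  m <- extract_modules(g)
  expect_identical(m$composition, "HK-CsgF-CsgG-CsgA/B-FecR")
  expect_false(m$terminal)
  expect_identical(m$span, 4L * 700L + 650L)
  ## zero components
  expect_identical(nrow(extract_modules(toy_genes(character(0)))), 0L)
  ## reverse-strand module: gene order reversed on the contig, canonical
  ## composition identical
  grev <- toy_genes(rev(c("HK", "CsgF", "CsgG", "CsgA/B", "FecR")),
                    strand = "-")
  mrev <- extract_modules(grev)
  expect_identical(mrev$composition, "HK-CsgF-CsgG-CsgA/B-FecR")
  expect_identical(mrev$strand, "-")
  ## duplicate components preserved
  g2 <- toy_genes(c("HK", "HK", "CsgF", "CsgG", "CsgA/B", "FecR", "CsgA/B"))
  expect_identical(extract_modules(g2)$composition,
                   "HK-HK-CsgF-CsgG-CsgA/B-FecR-CsgA/B")
  ## a gap larger than max_gap_genes splits the run
  g3 <- toy_genes(c("HK", "CsgF", "none", "none", "CsgG", "CsgA/B"))
  m3 <- extract_modules(g3, max_gap_genes = 1)
  expect_identical(nrow(m3), 2L)
  m3b <- extract_modules(g3, max_gap_genes = 2)
  expect_identical(nrow(m3b), 1L)
})

test_that("terminal filtering removes exactly the planted truncations", {
  g <- toy_genes(c("CsgF", "CsgG"), pad_before = 0)  # module at contig start
  m <- extract_modules(g)
  expect_true(m$terminal)
  expect_identical(nrow(filter_terminal(m)), 0L)
  st <- simulate_virome_stations(n_stations = 6, per_station_orfs = 2500,
                                 module_prevalence = 0.008,
                                 truncation_rate = 0.3, seed = 21)
  inst <- extract_modules(st$genes)
  expect_identical(nrow(inst), nrow(st$modules))
  kept <- filter_terminal(inst)
  expect_identical(sort(kept$contig_id),
                   sort(st$modules$contig_id[!st$modules$truncated]))
  ## post-filter compositions equal the planted (complete) compositions
  planted <- st$modules[match(kept$contig_id, st$modules$contig_id), ]
  expect_identical(kept$composition, planted$composition_planted)
})

test_that("composition tables rank correctly and resolve ties lexicographically", {
  inst <- data.frame(
    contig_id = paste0("c", 1:7),
    composition = c(rep("A-B", 3), rep("B-C", 3), "A-C"),
    family = c(rep("Podoviridae", 4), rep("Myoviridae", 3)),
    terminal = FALSE, stringsAsFactors = FALSE)
  tab <- composition_table(inst, by_family = TRUE)
  pod <- tab[tab$family == "Podoviridae", ]
  expect_identical(pod$composition[1], "A-B")
  expect_equal(pod$percent, c(75, 25))
  ## single composition: 100%
  one <- composition_table(inst[1:2, ], by_family = FALSE)
  expect_equal(one$percent, 100)
  ## tie: lexicographic order, both reported
  tie <- data.frame(contig_id = c("a", "b"), composition = c("Z-A", "B-C"),
                    family = "f", stringsAsFactors = FALSE)
  tt <- composition_table(tie)
  expect_identical(tt$composition, c("B-C", "Z-A"))
})

test_that("family assignment honors per-(component, family) identity floors", {
  st <- simulate_virome_stations(n_stations = 2, per_station_orfs = 800,
                                 module_prevalence = 0.01, seed = 33)
  floors <- family_identity_floors(st$references)
  expect_true(all(floors$floor > 50))
  ## exact copy of a reference is assigned its family
  r1 <- st$references[st$references$component == "CsgG", ][1, ]
  res <- assign_family(r1$protein, st$references, "CsgG", floors)
  expect_identical(res$family, r1$family)
  expect_identical(res$best_identity, 100)
  ## a heavily diverged query falls below the floor: unassigned
  far <- mutate_protein(r1$protein, 0.6, seed = 2)
  res2 <- assign_family(far, st$references, "CsgG", floors)
  expect_identical(res2$family, "unassigned")
  ## missing floor errors
  bad_floors <- floors[floors$component != "CsgG", ]
  expect_error(assign_family(r1$protein, st$references, "CsgG", bad_floors),
               "floor")
  ## planted component proteins are assigned to their planted family
  comp_genes <- st$genes[st$genes$component != "none", ]
  comp_genes <- head(comp_genes, 10)
  for (i in seq_len(nrow(comp_genes))) {
    got <- assign_family(comp_genes$protein[i], st$references,
                         comp_genes$component[i], floors)
    expect_identical(got$family, comp_genes$family[i])
  }
})

test_that("station frequencies normalize hits by total viral ORFs", {
  hits <- data.frame(station_id = c("s1", "s2"), component = "CsgG",
                     hits = c(0L, 5L), stringsAsFactors = FALSE)
  out <- station_frequencies(hits, c(s1 = 8000, s2 = 10000))
  expect_identical(out$frequency, c(0, 5e-4))
  expect_error(station_frequencies(hits, c(s1 = 8000, s2 = 0)), "positive")
  expect_error(station_frequencies(hits, c(s1 = 8000)), "missing")
})

test_that("region fraction and pairwise count ratio follow their definitions", {
  expect_equal(region_fraction(58000, 4524), 7.8)
  expect_equal(region_fraction(1000, 1000), 100)
  expect_error(region_fraction(1000, 2000), "exceeds")
  r <- pairwise_count_ratio(c(3, 4, 5))
  expect_equal(r$mean, (0.75 + 0.6 + 0.8) / 3, tolerance = 1e-9)
  expect_identical(r$n_pairs, 3L)
  expect_equal(pairwise_count_ratio(c(7, 7, 7))$mean, 1)
  expect_equal(pairwise_count_ratio(c(7, 7, 7))$sd, 0)
  expect_equal(pairwise_count_ratio(c(2, 4))$mean, 0.5)
  ## zero handling: a single zero gives ratio 0, all-zero pairs are an error
  expect_equal(pairwise_count_ratio(c(0, 5))$mean, 0)
  expect_error(pairwise_count_ratio(c(0, 0)), "undefined")
  ## planted module spans: extraction agrees with the planted truth
  sim <- small_sim()
  mods <- extract_modules(sim$genes)
  mods <- mods[order(mods$contig_id), ]
  planted <- sim$modules[order(sim$modules$genome_id), ]
  expect_identical(mods$span, planted$span)
  expect_identical(mods$composition, planted$composition)
  for (i in seq_len(nrow(mods))) {
    expect_equal(region_fraction(sim$genomes[[mods$contig_id[i]]], mods[i, ]),
                 100 * planted$span[i] / nchar(sim$genomes[[planted$genome_id[i]]]))
  }
})
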