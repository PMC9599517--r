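# Synthetic-data generator.
#
# Plants a pan-genome with known clade structure, orthogroups, gene modules
# and terminal repeats, calibrated to the summary statistics of the
# environmental HTVC023P-type Pelagiphage genome set (mean genome length
# 58,776 +/- 2,523 bp, 42.1% G+C, 82 +/- 9 ORFs/genome, 13 core orthogroups,
# ~17 unique genes/genome, 10 clades, T8SS modules in a minority of genomes).
# Every planted feature is recorded as ground truth so downstream modules can
# be verified exactly.

T8SS_COMPONENTS <- c("HK", "CsgF", "CsgG", "CsgA/B", "FecR", "AC")

#' Default planted T8SS module composition mixture
#'
#' The canonical five-component operon, its two-HK variant, and the extended
#' variant with a second CsgA/B copy plus adenylate cyclase, with mixture
#' probabilities 0.6/0.3/0.1.
#'
#' @return Named list of composition strings and probabilities.
#' @export
default_module_compositions <- function() {
  list(
    "HK-CsgF-CsgG-CsgA/B-FecR"             = 0.6,
    "HK-HK-CsgF-CsgG-CsgA/B-FecR"          = 0.3,
    "HK-CsgF-CsgG-CsgA/B-FecR-CsgA/B-AC"   = 0.1
  )
}

#' Simulation configuration
#'
#' Population parameters for [simulate_pangenome()]. Defaults are the study
#' conditions of the HTVC023P-type genome set: 82 genomes in 10 clades,
#' genome length 58,776 +/- 2,523 bp, G+C 0.421, 82 +/- 9 ORFs per genome,
#' 13 core orthogroups, on average 17 unique genes per genome, and T8SS
#' modules planted in 9/82 of the genomes. Within/between-clade protein
#' divergences (0.05 / 0.30 substitutions per site) are calibration choices
#' producing ~90% within-clade and ~51% between-clade protein identity.
#'
#' @param n_genomes,n_clades Number of genomes and planted clades.
#' @param mean_len,sd_len Genome length distribution (bases).
#' @param gc Target G+C fraction (0 < gc < 1).
#' @param mean_orfs,sd_orfs ORFs-per-genome distribution.
#' @param n_core Number of core orthogroups (present in every genome).
#' @param mean_unique Mean number of unique (single-genome) genes per genome.
#' @param module_prevalence Fraction of genomes carrying a planted T8SS module.
#' @param within_clade_divergence,between_clade_divergence Protein divergence
#'   (substitutions/site) inside a clade and between clade ancestors;
#'   `between >= within >= 0` required.
#' @param seed Master seed; all per-genome streams are derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genomes = 82, n_clades = 10,
                       mean_len = 58776, sd_len = 2523, gc = 0.421,
                       mean_orfs = 82, sd_orfs = 9,
                       n_core = 13, mean_unique = 17,
                       module_prevalence = 9 / 82,
                       within_clade_divergence = 0.05,
                       between_clade_divergence = 0.30,
                       seed = 1L) {
  cfg <- list(n_genomes = as.integer(n_genomes), n_clades = as.integer(n_clades),
              mean_len = mean_len, sd_len = sd_len, gc = gc,
              mean_orfs = mean_orfs, sd_orfs = sd_orfs,
              n_core = as.integer(n_core), mean_unique = mean_unique,
              module_prevalence = module_prevalence,
              within_clade_divergence = within_clade_divergence,
              between_clade_divergence = between_clade_divergence,
              seed = as.integer(seed))
  stopifnot(cfg$n_genomes >= 1, cfg$n_clades >= 1, cfg$n_core >= 0,
            cfg$gc > 0, cfg$gc < 1,
            cfg$within_clade_divergence >= 0,
            cfg$between_clade_divergence >= cfg$within_clade_divergence,
            cfg$module_prevalence >= 0, cfg$module_prevalence <= 1)
  if (cfg$n_core > cfg$mean_orfs) {
    stop("n_core (", cfg$n_core, ") must not exceed mean_orfs (", cfg$mean_orfs, ")")
  }
  if (cfg$n_genomes < 3 * cfg$n_clades) {
    stop("need at least 3 genomes per clade (n_genomes >= 3 * n_clades)")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Substitute amino acids at a fixed expected rate
#'
#' Each position is substituted independently with probability `divergence`;
#' a substituted position receives one of the 19 other amino acids uniformly,
#' so the expected fraction of changed positions equals `divergence` and the
#' length is preserved.
#'
#' @param protein Amino-acid string.
#' @param divergence Substitution probability per site, in `[0, 1]`.
#' @param seed Optional seed (the caller's RNG state is restored afterwards).
#' @return Mutated protein string.
#' @export
mutate_protein <- function(protein, divergence, seed = NULL) {
  p <- check_protein(protein)
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0, 1]")
  with_seed(seed, {
    chars <- strsplit(p, "")[[1]]
    hit <- runif(length(chars)) < divergence
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit], function(a) {
        sample(setdiff(AA_ALPHABET, a), 1L)
      }, character(1))
    }
    paste(chars, collapse = "")
  })
}

random_protein <- function(len) {
  paste(c("M", sample(AA_ALPHABET, len - 1L, replace = TRUE, prob = AA_FREQ)),
        collapse = "")
}

# Mutate a protein but keep the initiator methionine, so back-translation
# always yields an ATG start.
mutate_keep_start <- function(protein, divergence) {
  if (nchar(protein) < 2L) return(protein)
  paste0("M", mutate_protein(substr(protein, 2L, nchar(protein)), divergence))
}

## ---- codon machinery -------------------------------------------------------

codon_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      code <- genetic_code11()
      code <- code[!(code %in% "*")]
      cache <<- split(names(code), unname(code))
    }
    cache
  }
})

# Expected overall G+C of a random-amino-acid codon when the G/C-ending
# synonymous codon is preferred with probability weight p3.
expected_codon_gc <- function(p3) {
  tab <- codon_table()
  per_aa <- vapply(tab, function(codons) {
    third_gc <- substr(codons, 3, 3) %in% c("G", "C")
    w <- ifelse(third_gc, p3, 1 - p3)
    w <- w / sum(w)
    gc_counts <- vapply(strsplit(codons, ""), function(x) sum(x %in% c("G", "C")),
                        numeric(1))
    sum(w * gc_counts) / 3
  }, numeric(1))
  mean(per_aa)
}

# Solve for the third-position G/C preference that yields the target overall
# G+C given the fraction of genome bases that are codons vs AT-only stop cores
# vs random spacer at the target G+C.
calibrate_p3 <- function(gc, frac_coding, frac_core) {
  frac_rand <- 1 - frac_coding - frac_core
  f <- function(p3) frac_coding * expected_codon_gc(p3) + frac_rand * gc - gc
  lo <- f(0.02); hi <- f(0.98)
  if (lo >= 0) return(0.02)
  if (hi <= 0) return(0.98)
  uniroot(f, c(0.02, 0.98), tol = 1e-4)$root
}

# Back-translate a protein, preferring G/C third positions with probability
# weight p3, and append a stop codon.
back_translate <- function(protein, p3) {
  tab <- codon_table()
  chars <- strsplit(protein, "")[[1]]
  out <- character(length(chars))
  for (grp in split(seq_along(chars), chars)) {
    aa <- chars[grp[1]]
    codons <- tab[[aa]]
    third_gc <- substr(codons, 3, 3) %in% c("G", "C")
    w <- ifelse(third_gc, p3, 1 - p3)
    out[grp] <- sample(codons, length(grp), replace = TRUE, prob = w / sum(w))
  }
  stop_c <- sample(STOP_CODONS, 1L, prob = c(0.7, 0.15, 0.15))
  paste0(paste(out, collapse = ""), stop_c)
}

# Minimal six-frame ORF scan of a stop-core-flanked gene chunk; returns the
# ORFs other than the planted gene itself as a matrix (start0, len, strand
# 1 = "+", 2 = "-"). Operates on an integer-coded sequence (A=0, C=1, G=2,
# T=3) for speed.
CODON_STOPS <- c(48L, 50L, 56L)   # TAA, TAG, TGA
CODON_STARTS <- c(14L, 46L, 62L)  # ATG, GTG, TTG

dna_to_int <- function(chars) match(chars, c("A", "C", "G", "T")) - 1L

chunk_spurious <- function(ints, gene_len, gene_strand, min_len) {
  n <- length(ints)
  out <- NULL
  for (st in 1:2) {
    cc <- if (st == 1L) ints else rev(3L - ints)
    for (f in 0:2) {
      cs <- seq.int(f + 1L, n - 2L, by = 3L)
      codons <- 16L * cc[cs] + 4L * cc[cs + 1L] + cc[cs + 2L]
      stop_ix <- which(codons %in% CODON_STOPS)
      if (length(stop_ix) == 0L) next
      is_start <- codons %in% CODON_STARTS
      prev <- 0L
      for (j in stop_ix) {
        lo <- prev + 1L
        prev <- j
        if (j - lo < 1L) next
        ks <- which(is_start[lo:(j - 1L)])
        if (length(ks) == 0L) next
        k <- lo + ks[1L] - 1L
        len <- (j - k + 1L) * 3L
        if (len < min_len) next
        a <- cs[k]; b <- cs[j] + 2L
        left <- if (st == 1L) a else n - b + 1L
        out <- rbind(out, c(left - 1L, len, st))
      }
    }
  }
  if (is.null(out)) return(NULL)
  own <- out[, 1] == 12L & out[, 2] == gene_len &
    out[, 3] == (if (gene_strand == "+") 1L else 2L)
  out <- out[!own, , drop = FALSE]
  if (nrow(out) == 0L) NULL else out
}

# TRUE when the chunk interval [s0, s0 + slen) read on `strand` contains an
# internal stop codon (the terminal stop excluded). `ints` is integer-coded.
has_internal_stop <- function(ints, s0, slen, strand) {
  sub <- ints[(s0 + 1L):(s0 + slen)]
  if (strand == "-") sub <- rev(3L - sub)
  cs <- seq.int(1L, slen - 2L, by = 3L)
  codons <- 16L * sub[cs] + 4L * sub[cs + 1L] + sub[cs + 2L]
  any(codons[-length(codons)] %in% CODON_STOPS)
}

# Back-translate so that the gene, flanked by stop cores, contains no ORF
# >= min_len other than the gene itself, wherever synonymous codon choices
# permit. Spurious ORFs in the other five reading frames are eliminated by
# synonymous substitution of one codon (or two adjacent codons, since stop
# motifs in shifted frames straddle host codon boundaries) inside the
# offending ORF. A reverse ORF whose codons align anti-parallel to the host
# codons can be impossible to interrupt without changing the protein (no
# Leu/Ser in its span); such rare survivors are returned in the
# "spurious_orfs" attribute (chunk coordinates) so the caller can record them
# as incidental overlapping ORFs. Because every gene is isolated by six-frame
# stop cores, gene-local cleanliness implies genome-wide cleanliness.
back_translate_clean <- function(protein, p3, strand, min_len = 90,
                                 max_outer = 60L) {
  tab <- codon_table()
  bases <- c("A", "C", "G", "T")
  codon_ints <- function(codon) dna_to_int(strsplit(codon, "")[[1]])
  paa <- strsplit(protein, "")[[1]]
  n_aa <- length(paa)
  L <- 3L * (n_aa + 1L)
  nt <- back_translate(protein, p3)  # gene-reading orientation, stop included
  gene_ints <- dna_to_int(strsplit(nt, "")[[1]])
  core_ints <- dna_to_int(strsplit(STOP_CORE, "")[[1]])
  orient <- function(gi) if (strand == "-") rev(3L - gi) else gi
  ## chunk held in sync with gene_ints; gene position q (1-based,
  ## gene-reading) sits at chunk index 12 + q ("+") or 12 + L - q + 1 ("-")
  chunk <- c(core_ints, orient(gene_ints), core_ints)
  poke <- function(span_q, vals) {
    if (strand == "+") chunk[12L + span_q] <<- vals
    else chunk[12L + L - span_q + 1L] <<- 3L - vals
  }
  read3 <- function(p, ss) {  # codon code at 0-based chunk pos p, strand ss
    a <- chunk[p + 1L]; b <- chunk[p + 2L]; cc <- chunk[p + 3L]
    if (ss == "-") 16L * (3L - cc) + 4L * (3L - b) + (3L - a)
    else 16L * a + 4L * b + cc
  }
  hopeless <- character(0)
  for (outer in seq_len(max_outer)) {
    spur <- chunk_spurious(chunk, L, strand, min_len)
    if (is.null(spur)) break
    keys <- paste(spur[, 1], spur[, 2], spur[, 3])
    live <- which(!(keys %in% hopeless))
    if (length(live) == 0L) break
    for (r in live) {
    s0 <- spur[r, 1]; slen <- spur[r, 2]
    sstrand <- if (spur[r, 3] == 1L) "+" else "-"
    ## gene-reading codon indices overlapping the offending ORF
    qlo <- max(s0 + 1L - 12L, 1L)        # 1-based within the oriented gene
    qhi <- min(s0 + slen - 12L, L)
    if (strand == "-") { tmp <- qlo; qlo <- L - qhi + 1L; qhi <- L - tmp + 1L }
    clo <- max(2L, ceiling(qlo / 3))     # keep the ATG start
    chi <- min(n_aa, ceiling(qhi / 3))   # keep the stop codon
    if (chi < clo) { hopeless <- c(hopeless, keys[r]); next }
    ## one synonymous codon swap that puts a stop inside the ORF
    patched <- FALSE
    for (ci in resample(clo:chi)) {
      span <- (3L * ci - 2L):(3L * ci)
      old <- gene_ints[span]
      cur <- paste(bases[old + 1L], collapse = "")
      for (alt in resample(setdiff(tab[[paa[ci]]], cur))) {
        v <- codon_ints(alt)
        gene_ints[span] <- v; poke(span, v)
        if (has_internal_stop(chunk, s0, slen, sstrand)) { patched <- TRUE; break }
        gene_ints[span] <- old; poke(span, old)
      }
      if (patched) break
    }
    ## coordinated swap of two adjacent codons (stop motifs in shifted
    ## frames straddle host codon boundaries)
    if (!patched && chi > clo) {
      for (ci in resample(clo:(chi - 1L))) {
        span <- (3L * ci - 2L):(3L * ci + 3L)
        old <- gene_ints[span]
        combos <- expand.grid(a = tab[[paa[ci]]], b = tab[[paa[ci + 1L]]],
                              stringsAsFactors = FALSE)
        for (cb in resample(seq_len(nrow(combos)))) {
          v <- c(codon_ints(combos$a[cb]), codon_ints(combos$b[cb]))
          gene_ints[span] <- v; poke(span, v)
          if (has_internal_stop(chunk, s0, slen, sstrand)) { patched <- TRUE; break }
          gene_ints[span] <- old; poke(span, old)
        }
        if (patched) break
      }
    }
    ## third choice: remove the ORF's start codons (a stretch with no start
    ## codon at >= min_len from its stop is not an ORF). The stretch's stop
    ## is at its right end for "+", at its left end for "-".
    if (!patched) {
      ps <- if (sstrand == "+") {
        seq.int(s0, s0 + slen - min_len, by = 3L)
      } else {
        seq.int(s0 + min_len - 3L, s0 + slen - 3L, by = 3L)
      }
      for (p in ps) {
        if (read3(p, sstrand) %in% CODON_STARTS) {
          ## host codons overlapping [p, p+3)
          qa <- if (strand == "-") L - (p + 3L - 12L) + 1L else p + 1L - 12L
          qb <- if (strand == "-") L - (p + 1L - 12L) + 1L else p + 3L - 12L
          cis <- unique(pmin(pmax(ceiling(c(qa, qb) / 3), 2L), n_aa))
          cis <- seq.int(min(cis), max(cis))
          done <- FALSE
          for (ci in cis) {
            span <- (3L * ci - 2L):(3L * ci)
            old <- gene_ints[span]
            cur <- paste(bases[old + 1L], collapse = "")
            for (alt in resample(setdiff(tab[[paa[ci]]], cur))) {
              v <- codon_ints(alt)
              gene_ints[span] <- v; poke(span, v)
              if (!(read3(p, sstrand) %in% CODON_STARTS)) {
                done <- TRUE; patched <- TRUE; break
              }
              gene_ints[span] <- old; poke(span, old)
            }
            if (done) break
          }
        }
      }
    }
    if (!patched) hopeless <- c(hopeless, keys[r])
    }
  }
  final <- chunk_spurious(chunk, L, strand, min_len)
  out <- paste(bases[orient(gene_ints) + 1L], collapse = "")
  if (!is.null(final)) attr(out, "spurious_orfs") <- final
  out
}

# Draw a gene (protein + clean nucleotide sequence). The protein generator is
# re-drawn a few times when its back-translation retains spurious ORFs that
# synonymous design cannot remove (mild selection against codon-pathological
# variants); a residual survivor is returned with its "spurious_orfs"
# attribute intact.
draw_clean_gene <- function(gen, p3, strand, max_draws = 6L) {
  best <- NULL
  best_bad <- Inf
  for (d in seq_len(max_draws)) {
    p <- gen()
    nt <- back_translate_clean(p, p3, strand)
    sp <- attr(nt, "spurious_orfs")
    if (is.null(sp)) return(list(protein = p, nt = nt))
    if (nrow(sp) < best_bad) { best_bad <- nrow(sp); best <- list(protein = p, nt = nt) }
  }
  best
}

## ---- pan-genome simulation -------------------------------------------------

#' Simulate a clade-structured phage pan-genome with planted truth
#'
#' Generates `n_genomes` circular genomes. Each genome carries every core
#' orthogroup, a clade-biased sample of shared orthogroups, unique genes, and
#' (in `module_prevalence` of the genomes) a contiguous T8SS gene module.
#' Proteins within an orthogroup are derived from a common ancestor: one
#' variant per clade at `between_clade_divergence`, then one copy per genome
#' at `within_clade_divergence` (core orthogroups — the marker genes that
#' screens and trees are built from — use 0.7 of the between-clade
#' divergence, reflecting their stronger conservation). Genes are packed
#' head-to-tail, each flanked
#' by a 12-nt six-frame stop core, back-translated with third positions
#' calibrated to the target G+C; residual spurious ORFs are removed by
#' synonymous-codon substitution so the planted genes are exactly the maximal
#' ORFs of the genome. Ferrochelatase is always planted adjacent to a
#' 2OG-Fe(II) oxygenase, and thymidylate synthase adjacent to aG/PT-PPlase1,
#' reproducing the partner-AMG structure.
#'
#' @param config A [sim_config()].
#' @param sequences Generate nucleotide genome sequences (default). With
#'   `FALSE` only the protein/annotation layer is produced (genome sequences
#'   are `NA`), which is much faster when downstream analysis needs proteins,
#'   clades and orthogroups but not ORF calling or circularization.
#' @return A list with elements `genomes` (named character vector of circular
#'   genome sequences), `genome_info` (data.frame: `genome_id`, `clade`,
#'   `station`), `genes` (data.frame: `genome_id`, `gene_id`, `start`,
#'   `length`, `strand`, `wraps_origin`, `protein`, `og_id`, `label`,
#'   `category`, `component`, `module_id`), `modules` (planted module
#'   instances with composition, span and strand), `og_info` (orthogroup id,
#'   tier, label, category, component), `ancestors` (named list of ancestor
#'   proteins per orthogroup), and `config`.
#' @export
simulate_pangenome <- function(config = sim_config(), sequences = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_pangenome_impl(config, sequences))
}

simulate_pangenome_impl <- function(cfg, sequences = TRUE) {
  n <- cfg$n_genomes
  genome_ids <- sprintf("cvg%03d", seq_len(n))

  ## clade memberships: every clade gets >= 3 members
  extra <- as.vector(stats::rmultinom(1, n - 3L * cfg$n_clades,
                                      rep(1, cfg$n_clades)))
  clade_sizes <- 3L + extra
  clade_of <- rep(sprintf("clade%02d", seq_len(cfg$n_clades)), clade_sizes)
  clade_of <- sample(clade_of)  # random assignment order
  names(clade_of) <- genome_ids
  stations <- sprintf("ST%02d", sample.int(39, n, replace = TRUE))

  ## orthogroup inventory --------------------------------------------------
  mean_aa <- max(60L, round((0.90 * cfg$mean_len / cfg$mean_orfs - 37) / 3) - 1L)
  sd_aa <- max(10, round(mean_aa * 0.2))
  draw_len <- function(k) pmax(60L, round(rnorm(k, mean_aa, sd_aa)))

  core_labels <- c("DNA polymerase A (PolA)", "terminase large subunit",
                   "DEAD/DEAH box helicase", "primase", "major capsid protein",
                   "co-chaperonin GroES", "portal protein")
  core_labels <- c(core_labels,
                   sprintf("conserved hypothetical core %d",
                           seq_len(max(0, cfg$n_core - length(core_labels)))))
  core_labels <- core_labels[seq_len(cfg$n_core)]

  n_clade_og <- 30L
  n_global_og <- 200L
  amg_labels <- c("phosphoribosylaminoimidazole synthetase (purM)",
                  "peptide deformylase", "glycosyltransferase",
                  "5'-deoxynucleotidase",
                  "beta-glucosyl-HMC-alpha-glucosyl-transferase",
                  "queuosine biosynthesis protein", "ribonucleotide reductase")
  amg_categories <- c("AMG-nucleotide", "AMG-nucleotide", "AMG-hypermodification",
                      "AMG-nucleotide", "AMG-hypermodification", "AMG-other",
                      "AMG-nucleotide")

  og <- list()
  add_og <- function(id, tier, label, category, component = "none", clade = NA) {
    og[[length(og) + 1L]] <<- data.frame(
      og_id = id, tier = tier, label = label, category = category,
      component = component, home_clade = clade, stringsAsFactors = FALSE)
  }
  for (i in seq_len(cfg$n_core)) {
    add_og(sprintf("og_core%02d", i), "core", core_labels[i], "core-viral")
  }
  ## special partner-AMG orthogroups
  add_og("og_TS", "shared", "thymidylate synthase (TS)", "AMG-hypermodification")
  add_og("og_PP", "shared", "aG/PT-PPlase1", "AMG-hypermodification")
  add_og("og_FC", "shared", "ferrochelatase", "AMG-other")
  add_og("og_OX", "shared", "2OG-Fe(II) oxygenase", "AMG-other")
  ## T8SS component orthogroups
  for (comp in T8SS_COMPONENTS) {
    add_og(paste0("og_t8ss_", gsub("[^A-Za-z]", "", comp)), "module",
           paste0("Curli/T8SS component ", comp), "AMG-T8SS", component = comp)
  }
  ## clade-restricted and globally patchy shared orthogroups
  k <- 0L
  for (cl in sprintf("clade%02d", seq_len(cfg$n_clades))) {
    for (i in seq_len(n_clade_og)) {
      k <- k + 1L
      add_og(sprintf("og_s%04d", k), "shared", "hypothetical protein",
             "hypothetical", clade = cl)
    }
  }
  for (i in seq_len(n_global_og)) {
    k <- k + 1L
    lab <- "hypothetical protein"; cat <- "hypothetical"
    if (runif(1) < 0.08) {  # a sprinkling of non-partner AMGs
      j <- sample.int(length(amg_labels), 1L)
      lab <- amg_labels[j]; cat <- amg_categories[j]
    }
    add_og(sprintf("og_s%04d", k), "shared", lab, cat)
  }
  og_info <- do.call(rbind, og)
  rownames(og_info) <- og_info$og_id

  ## ancestors and per-clade variants; T8SS component ancestors take the
  ## typical sizes of their protein families (histidine kinases are large,
  ## the Curli subunits and chaperone small)
  anc_len <- draw_len(nrow(og_info))
  comp_aa <- c(HK = 450L, CsgF = 140L, CsgG = 270L, `CsgA/B` = 150L,
               FecR = 310L, AC = 380L)
  is_mod <- og_info$tier == "module"
  anc_len[is_mod] <- comp_aa[og_info$component[is_mod]]
  ancestors <- setNames(
    vapply(anc_len, random_protein, character(1)),
    og_info$og_id)
  clades <- sprintf("clade%02d", seq_len(cfg$n_clades))
  ## core (marker) genes are more conserved than the average gene: they are
  ## the genes marker screens and trees are built from
  og_div <- ifelse(og_info$tier == "core", 0.7, 1) *
    cfg$between_clade_divergence
  variants <- lapply(clades, function(cl) {
    setNames(vapply(seq_along(ancestors), function(k) {
      mutate_keep_start(ancestors[[k]], og_div[k])
    }, character(1)), names(ancestors))
  })
  names(variants) <- clades

  ## module carriers: clustered in a few clades, like the study's clades
  n_carriers <- round(cfg$module_prevalence * n)
  carrier_ids <- character(0)
  if (n_carriers > 0) {
    carrier_clades <- sample(clades, min(4L, cfg$n_clades))
    pool <- genome_ids[clade_of %in% carrier_clades]
    if (length(pool) < n_carriers) pool <- genome_ids
    carrier_ids <- sample(pool, n_carriers)
  }
  comp_mix <- default_module_compositions()
  comp_of_carrier <- sample(names(comp_mix), max(1L, n_carriers), replace = TRUE,
                            prob = unlist(comp_mix))[seq_len(n_carriers)]
  names(comp_of_carrier) <- carrier_ids

  ## hypermodification (TS/PP) carriers: three clades; FC/OX carriers: random
  hm_clades <- sample(clades, min(3L, cfg$n_clades))
  hm_carriers <- genome_ids[clade_of %in% hm_clades]
  fc_carriers <- genome_ids[runif(n) < 0.4]

  ## shared OG sampling weights per clade
  shared_ids <- og_info$og_id[og_info$tier == "shared" &
                                !og_info$og_id %in% c("og_TS", "og_PP", "og_FC", "og_OX")]
  shared_home <- og_info[shared_ids, "home_clade"]

  ## G+C calibration from the planned layout
  core_frac <- (24 * cfg$mean_orfs + 0.2 * 0.1 * cfg$mean_len) / cfg$mean_len
  coding_frac <- (3 * (mean_aa + 2) * cfg$mean_orfs) / cfg$mean_len
  p3 <- calibrate_p3(cfg$gc, min(coding_frac, 0.95), min(core_frac, 0.5))

  genomes <- setNames(character(n), genome_ids)
  gene_rows <- vector("list", n)
  module_rows <- list()

  for (i in seq_len(n)) {
    gid <- genome_ids[i]
    set.seed(derive_seed(cfg$seed, i))
    cl <- clade_of[[gid]]

    module_comps <- character(0)
    if (gid %in% carrier_ids) {
      module_comps <- strsplit(comp_of_carrier[[gid]], "-", fixed = TRUE)[[1]]
    }
    n_g <- max(cfg$n_core + 3L, round(rnorm(1, cfg$mean_orfs, cfg$sd_orfs)))
    n_unique <- rpois(1, cfg$mean_unique)
    n_shared <- max(0L, n_g - cfg$n_core - n_unique - length(module_comps) -
                      (gid %in% hm_carriers) * 2L - (gid %in% fc_carriers) * 2L)

    w <- ifelse(is.na(shared_home), 1, ifelse(shared_home == cl, 8, 0.2))
    picked <- sample(shared_ids, min(n_shared, length(shared_ids)), prob = w)

    ## assemble the gene units (blocks stay contiguous and co-oriented)
    units <- list()
    for (ogid in og_info$og_id[og_info$tier == "core"]) units <- c(units, list(ogid))
    for (ogid in picked) units <- c(units, list(ogid))
    if (gid %in% hm_carriers) units <- c(units, list(c("og_TS", "og_PP")))
    if (gid %in% fc_carriers) units <- c(units, list(c("og_OX", "og_FC")))
    module_unit <- NULL
    if (length(module_comps) > 0) {
      module_unit <- og_info$og_id[match(module_comps, og_info$component)]
      units <- c(units, list(module_unit))
    }
    for (u in seq_len(n_unique)) units <- c(units, list(sprintf("unique_%s_%02d", gid, u)))

    units <- sample(units)
    unit_strands <- sample(c("+", "-"), length(units), replace = TRUE)

    gene_og <- unlist(units)
    gene_strand <- rep(unit_strands, lengths(units))
    is_unique <- startsWith(gene_og, "unique_")

    ## draw proteins and assemble: [core rand core gene] ... [filler]
    prot <- character(length(gene_og))
    parts <- character(0)
    starts <- integer(length(gene_og)); lens <- integer(length(gene_og))
    pos <- 0L
    resid <- NULL  # rare ORFs that synonymous design could not remove
    for (jj in seq_along(gene_og)) {
      rand <- random_dna(sample.int(27L, 1L) - 1L, cfg$gc)
      spacer <- paste0(STOP_CORE, rand, STOP_CORE)
      gen <- if (is_unique[jj]) {
        function() random_protein(draw_len(1L))
      } else {
        function() mutate_keep_start(variants[[cl]][[gene_og[jj]]],
                                     cfg$within_clade_divergence)
      }
      if (sequences) {
        g <- draw_clean_gene(gen, p3, gene_strand[jj])
        prot[jj] <- g$protein
        nt <- g$nt
        extra <- attr(nt, "spurious_orfs")
        nt <- as.character(nt)
        parts <- c(parts, spacer, nt)
        pos <- pos + nchar(spacer)
        starts[jj] <- pos
        lens[jj] <- nchar(nt)
        if (!is.null(extra)) {
          extra[, 1] <- extra[, 1] + starts[jj] - 12L  # chunk -> genome coords
          resid <- rbind(resid, extra)
        }
        pos <- pos + lens[jj]
      } else {
        prot[jj] <- gen()
        pos <- pos + nchar(spacer)
        starts[jj] <- pos
        lens[jj] <- 3L * (nchar(prot[jj]) + 1L)
        pos <- pos + lens[jj]
      }
    }
    seq <- NA_character_
    if (sequences) {
      target <- round(rnorm(1, cfg$mean_len, cfg$sd_len))
      filler_len <- max(12L, target - pos)
      filler <- character(0)
      left <- filler_len
      while (left > 0L) {
        blk <- paste0(STOP_CORE, random_dna(min(48L, max(0L, left - 12L)), cfg$gc))
        filler <- c(filler, blk)
        left <- left - nchar(blk)
      }
      seq <- paste(c(parts, filler), collapse = "")
    }

    genes_i <- data.frame(
      genome_id = gid,
      gene_id = sprintf("%s_g%03d", gid, seq_along(gene_og)),
      start = starts, length = lens, strand = gene_strand,
      wraps_origin = FALSE, protein = prot, og_id = gene_og,
      stringsAsFactors = FALSE)
    genes_i$og_id[is_unique] <- genes_i$gene_id[is_unique]  # singleton ids
    info <- og_info[match(genes_i$og_id, og_info$og_id), ]
    genes_i$label <- ifelse(is_unique, "hypothetical protein", info$label)
    genes_i$category <- ifelse(is_unique, "hypothetical", info$category)
    genes_i$component <- ifelse(is_unique, "none", info$component)
    genes_i$module_id <- NA_character_

    ## incidental overlapping ORFs that survive synonymous design become
    ## ordinary truth genes (hypothetical singletons), so the recorded gene
    ## table is exactly the genome's maximal ORF set
    if (!is.null(resid)) {
      inc <- data.frame(
        genome_id = gid,
        gene_id = sprintf("%s_i%03d", gid, seq_len(nrow(resid))),
        start = as.integer(resid[, 1]), length = as.integer(resid[, 2]),
        strand = ifelse(resid[, 3] == 1L, "+", "-"),
        wraps_origin = FALSE, protein = NA_character_,
        og_id = NA_character_, label = "hypothetical protein",
        category = "hypothetical", component = "none",
        module_id = NA_character_, stringsAsFactors = FALSE)
      inc$og_id <- inc$gene_id
      genes_i <- rbind(genes_i, inc)
    }

    if (length(module_comps) > 0) {
      mrows <- which(genes_i$og_id %in% module_unit)
      mrows <- mrows[genes_i$og_id[mrows] %in% module_unit]
      midx <- which(genes_i$component != "none")
      genes_i$module_id[midx] <- paste0(gid, "_mod1")
      span_start <- min(genes_i$start[midx])
      span_end <- max(genes_i$start[midx] + genes_i$length[midx])
      module_rows[[length(module_rows) + 1L]] <- data.frame(
        genome_id = gid, module_id = paste0(gid, "_mod1"),
        composition = comp_of_carrier[[gid]],
        strand = genes_i$strand[midx[1]],
        start = span_start, end = span_end, span = span_end - span_start,
        stringsAsFactors = FALSE)
    }

    if (sequences) {
      na_p <- which(is.na(genes_i$protein))
      for (jj in na_p) {
        genes_i$protein[jj] <- translate_gene(genes_i[jj, ], seq, circular = TRUE)
      }
    }
    genes_i <- genes_i[order(genes_i$start), , drop = FALSE]
    rownames(genes_i) <- NULL

    genomes[[gid]] <- seq
    gene_rows[[i]] <- genes_i
  }

  list(
    genomes = genomes,
    genome_info = data.frame(genome_id = genome_ids,
                             clade = unname(clade_of[genome_ids]),
                             station = stations, stringsAsFactors = FALSE),
    genes = do.call(rbind, c(gene_rows, list(make.row.names = FALSE))),
    modules = if (length(module_rows)) {
      do.call(rbind, c(module_rows, list(make.row.names = FALSE)))
    } else NULL,
    og_info = og_info,
    ancestors = as.list(ancestors),
    config = cfg
  )
}

## ---- linear contigs with terminal repeats ----------------------------------

#' Emit linear contigs with planted terminal direct repeats
#'
#' Each circular genome is rotated by a random offset and its first
#' `overlap_len` bases are appended at the end, producing a linear contig with
#' an exact terminal direct repeat — the signature used to circularize
#' assembled contigs.
#'
#' @param genomes Named character vector (or `DNAStringSet`) of circular
#'   genome sequences.
#' @param overlap_len Planted repeat length in bases (0 plants no repeat);
#'   must be smaller than every genome length. May be a vector recycled over
#'   genomes.
#' @param seed Optional seed for the rotation offsets.
#' @return A list with `contigs` (named character vector; names get a
#'   `_ctg` suffix) and `truth` (data.frame: `contig_id`, `genome_id`,
#'   `offset`, `repeat_len`).
#' @export
emit_linear_contigs <- function(genomes, overlap_len = 100, seed = NULL) {
  seqs <- as_seq_vector(genomes)
  overlap_len <- rep_len(as.integer(overlap_len), length(seqs))
  if (any(overlap_len < 0 | overlap_len >= nchar(seqs))) {
    stop("overlap_len must be in [0, genome length)")
  }
  with_seed(seed, {
    offsets <- vapply(nchar(seqs), function(L) sample.int(L, 1L) - 1L, integer(1))
    contigs <- character(length(seqs))
    for (i in seq_along(seqs)) {
      g <- seqs[[i]]; L <- nchar(g); off <- offsets[i]
      rot <- if (off == 0L) g else paste0(substr(g, off + 1L, L), substr(g, 1L, off))
      contigs[i] <- if (overlap_len[i] > 0L) {
        paste0(rot, substr(rot, 1L, overlap_len[i]))
      } else rot
    }
    names(contigs) <- paste0(names(seqs), "_ctg")
    list(contigs = contigs,
         truth = data.frame(contig_id = names(contigs),
                            genome_id = names(seqs),
                            offset = offsets, repeat_len = overlap_len,
                            stringsAsFactors = FALSE))
  })
}

## ---- virome stations -------------------------------------------------------

#' Simulate annotated virome contig sets for a panel of ocean stations
#'
#' Emulates per-station virome annotation tables (as produced by screening
#' assembled contigs against component references): each station receives
#' contigs totalling `per_station_orfs` genes, of which a known fraction carry
#' a planted T8SS module (complete, or truncated at a contig terminus with
#' probability `truncation_rate`). Component genes carry proteins drawn from
#' family-specific ancestors so family assignment is testable; all other genes
#' are unannotated filler.
#'
#' @param n_stations Number of stations (the study profiled 65).
#' @param per_station_orfs Total genes per station.
#' @param module_prevalence Probability that a gene slot seeds a module;
#'   the expected number of planted modules per station is
#'   `per_station_orfs * module_prevalence` (the study observed component
#'   frequencies around 0.001).
#' @param truncation_rate Fraction of planted modules cut by a contig end.
#' @param composition_probs Named list/vector of composition strings
#'   (canonical order, `-`-separated) and their mixture probabilities.
#' @param family_probs Named vector of viral family probabilities.
#' @param seed Master seed.
#' @return A list with `genes` (data.frame: `station_id`, `contig_id`,
#'   `gene_id`, `start`, `length`, `strand`, `label`, `category`, `component`,
#'   `family`, `protein`), `modules` (planted truth: station, contig,
#'   composition planted and retained, family, truncated flag),
#'   `component_counts` (per station/component/family planted hit counts),
#'   `references` (data.frame of family-labelled component reference
#'   proteins), and `totals` (named per-station total ORF counts).
#' @export
simulate_virome_stations <- function(n_stations = 65, per_station_orfs = 10000,
                                     module_prevalence = 0.001,
                                     truncation_rate = 0.1,
                                     composition_probs = default_module_compositions(),
                                     family_probs = c(Podoviridae = 0.5,
                                                      Myoviridae = 0.5),
                                     seed = 1L) {
  stopifnot(module_prevalence >= 0, module_prevalence <= 1,
            truncation_rate >= 0, truncation_rate <= 1,
            per_station_orfs >= 1, n_stations >= 1)
  comps <- names(composition_probs)
  probs <- unlist(composition_probs)
  with_seed(seed, {
    ## family-specific component ancestors and references
    base <- setNames(lapply(T8SS_COMPONENTS, function(x) random_protein(200L)),
                     T8SS_COMPONENTS)
    fams <- names(family_probs)
    fam_anc <- lapply(fams, function(f) {
      lapply(base, mutate_keep_start, divergence = 0.25)
    })
    names(fam_anc) <- fams
    refs <- do.call(rbind, lapply(fams, function(f) {
      do.call(rbind, lapply(T8SS_COMPONENTS, function(cp) {
        data.frame(ref_id = sprintf("%s_%s_ref%d", f, gsub("[^A-Za-z]", "", cp), 1:3),
                   family = f, component = cp,
                   protein = vapply(1:3, function(i) {
                     mutate_keep_start(fam_anc[[f]][[cp]], 0.08)
                   }, character(1)),
                   stringsAsFactors = FALSE)
      }))
    }))

    station_ids <- sprintf("GOV_%03d", seq_len(n_stations))
    gene_tabs <- vector("list", n_stations)
    module_tabs <- list()
    for (s in seq_len(n_stations)) {
      set.seed(derive_seed(seed, s))
      sid <- station_ids[s]
      n_mod <- rbinom(1, per_station_orfs, module_prevalence)
      rows <- list()
      mod_meta <- list()
      genes_used <- 0L
      ctg <- 0L
      make_filler <- function(k, contig_id) {
        if (k <= 0L) return(NULL)
        data.frame(station_id = sid, contig_id = contig_id,
                   component = "none", family = NA_character_,
                   protein = NA_character_, stringsAsFactors = FALSE)[rep(1, k), ]
      }
      for (m in seq_len(n_mod)) {
        ctg <- ctg + 1L
        contig_id <- sprintf("%s_c%04d", sid, ctg)
        comp_str <- sample(comps, 1L, prob = probs)
        comp_vec <- strsplit(comp_str, "-", fixed = TRUE)[[1]]
        fam <- sample(fams, 1L, prob = family_probs)
        truncated <- runif(1) < truncation_rate
        retained <- comp_vec
        side <- NA_character_
        if (truncated && length(comp_vec) > 1L) {
          n_cut <- sample.int(length(comp_vec) - 1L, 1L)
          side <- sample(c("left", "right"), 1L)
          retained <- if (side == "left") tail(comp_vec, -n_cut) else head(comp_vec, -n_cut)
        } else truncated <- FALSE
        strand <- sample(c("+", "-"), 1L)
        listed <- if (strand == "+") retained else rev(retained)
        comp_df <- data.frame(station_id = sid, contig_id = contig_id,
                              component = listed, family = fam,
                              protein = vapply(listed, function(cp) {
                                mutate_keep_start(fam_anc[[fam]][[cp]], 0.08)
                              }, character(1)),
                              stringsAsFactors = FALSE)
        n_fill <- sample(8:20, 1L)
        if (truncated) {
          ## module flush against one contig end
          before <- if (side == "left") 0L else n_fill
          after <- n_fill - before
        } else {
          before <- sample.int(n_fill - 2L, 1L)
          after <- n_fill - before
        }
        block <- rbind(make_filler(before, contig_id), comp_df,
                       make_filler(after, contig_id))
        block$strand <- ifelse(block$component == "none",
                               sample(c("+", "-"), nrow(block), replace = TRUE),
                               strand)
        rows[[length(rows) + 1L]] <- block
        genes_used <- genes_used + nrow(block)
        mod_meta[[length(mod_meta) + 1L]] <- data.frame(
          station_id = sid, contig_id = contig_id, family = fam,
          composition_planted = comp_str,
          composition_retained = paste(retained, collapse = "-"),
          truncated = truncated, strand = strand, stringsAsFactors = FALSE)
      }
      ## filler-only contigs up to the per-station ORF total
      while (genes_used < per_station_orfs) {
        ctg <- ctg + 1L
        contig_id <- sprintf("%s_c%04d", sid, ctg)
        k <- min(sample(15:40, 1L), per_station_orfs - genes_used)
        blk <- make_filler(k, contig_id)
        blk$strand <- sample(c("+", "-"), k, replace = TRUE)
        rows[[length(rows) + 1L]] <- blk
        genes_used <- genes_used + k
      }
      tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
      tab <- tab[seq_len(per_station_orfs), , drop = FALSE]
      ## positional coordinates within each contig
      tab$gene_id <- sprintf("%s_g%06d", sid, seq_len(nrow(tab)))
      idx <- stats::ave(seq_len(nrow(tab)), tab$contig_id, FUN = seq_along)
      tab$start <- (idx - 1L) * 700L
      tab$length <- 650L
      tab$label <- ifelse(tab$component == "none", "hypothetical protein",
                          paste0("Curli/T8SS component ", tab$component))
      tab$category <- ifelse(tab$component == "none", "hypothetical", "AMG-T8SS")
      gene_tabs[[s]] <- tab
      if (length(mod_meta)) {
        module_tabs[[length(module_tabs) + 1L]] <-
          do.call(rbind, c(mod_meta, list(make.row.names = FALSE)))
      }
    }
    genes <- do.call(rbind, c(gene_tabs, list(make.row.names = FALSE)))
    modules <- if (length(module_tabs)) {
      do.call(rbind, c(module_tabs, list(make.row.names = FALSE)))
    } else NULL
    comp_counts <- NULL
    hits <- genes[genes$component != "none", c("station_id", "component", "family")]
    if (nrow(hits) > 0) {
      comp_counts <- as.data.frame(table(station_id = hits$station_id,
                                         component = hits$component,
                                         family = hits$family),
                                   stringsAsFactors = FALSE)
      names(comp_counts)[4] <- "hits"
    }
    totals <- table(genes$station_id)
    list(genes = genes, modules = modules, component_counts = comp_counts,
         references = refs,
         totals = setNames(as.integer(totals), names(totals)))
  })
}
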