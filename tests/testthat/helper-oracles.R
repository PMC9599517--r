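# Independent brute-force oracles used to verify the package implementations.
# These are written from the definitions, not from the package code paths.

# Longest exact (or >= min_identity) suffix-prefix overlap by scanning every
# candidate length from long to short. O(L * K) with K capped at max_k.
oracle_suffix_prefix <- function(seq, min_overlap = 100, min_identity = 1,
                                 max_k = 600) {
  L <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  hi <- min(max_k, floor(L / 2))
  if (hi < min_overlap) return(NULL)
  for (k in seq.int(hi, min_overlap, by = -1)) {
    a <- chars[seq_len(k)]
    b <- chars[seq.int(L - k + 1L, L)]
    hit <- a == b & a != "N"
    if (mean(hit) >= min_identity) return(as.integer(k))
  }
  NULL
}

# Plain six-frame ORF scan: doubles the sequence for circular genomes and
# deduplicates wrap copies. Walks codons position by position.
oracle_six_frame <- function(seq, min_len = 90, circular = FALSE,
                             starts = c("ATG", "GTG", "TTG")) {
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(seq)
  s_fwd <- if (circular) paste0(seq, seq) else seq
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
  }
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") s_fwd else rc(s_fwd)
    n <- nchar(s)
    for (f in 1:3) {
      run_start <- NULL        # codon position of first start in current run
      seen_stop <- !circular   # linear: leading run counts; circular: wait
      p <- f
      while (p + 2 <= n) {
        codon <- substr(s, p, p + 2)
        if (codon %in% stops) {
          if (seen_stop && !is.null(run_start)) {
            len <- p + 3 - run_start
            if (len >= min_len && len <= L) {
              left <- if (strand == "+") run_start else n - (p + 2) + 1
              start0 <- (left - 1) %% L
              res[[length(res) + 1L]] <- c(start0, len, strand)
            }
          }
          run_start <- NULL
          seen_stop <- TRUE
        } else if (is.null(run_start) && codon %in% starts) {
          run_start <- p
        }
        p <- p + 3
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(start = integer(), length = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  df <- unique(data.frame(start = as.integer(vapply(res, `[`, "", 1)),
                          length = as.integer(vapply(res, `[`, "", 2)),
                          strand = vapply(res, `[`, "", 3),
                          stringsAsFactors = FALSE))
  df[order(df$start, df$strand, df$length), , drop = FALSE]
}

# Textbook global alignment with affine gaps (Gotoh), BLOSUM62. A gap of
# length g costs open + g * extend. Returns the optimal score and the
# identity (over all alignment columns) of one optimal traceback.
oracle_global_align <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  sm <- get_blosum62()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # align av[i] with bv[j]
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (a aligned to gap)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - (i - 1) * gap_extend
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - (j - 1) * gap_extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sm[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend,
                     Y[i - 1, j] - gap_open - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend,
                     X[i, j - 1] - gap_open - gap_extend)
    }
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  ## traceback (prefer M, then X, then Y) for an identity estimate
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  matches <- 0L; cols <- 0L
  tol <- 1e-9
  while (i > 1 || j > 1) {
    cols <- cols + 1L
    if (state == 1L) {
      s <- sm[av[i - 1], bv[j - 1]]
      if (av[i - 1] == bv[j - 1]) matches <- matches + 1L
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which(abs(prev + s - M[i, j]) < tol)[1]
      i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      cand <- c(M[i - 1, j] - gap_open - gap_extend,
                X[i - 1, j] - gap_extend,
                Y[i - 1, j] - gap_open - gap_extend)
      state <- which(abs(cand - X[i, j]) < tol)[1]
      i <- i - 1
    } else {
      cand <- c(M[i, j - 1] - gap_open - gap_extend,
                Y[i, j - 1] - gap_extend,
                X[i, j - 1] - gap_open - gap_extend)
      state <- c(1L, 3L, 2L)[which(abs(cand - Y[i, j]) < tol)[1]]
      j <- j - 1
    }
  }
  list(score = score, identity = 100 * matches / cols)
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# All clade-side leaf sets of a tree with the support of the subtending
# edge, by walking the edge matrix directly.
oracle_clade_sides <- function(tree) {
  ntip <- length(tree$tip.label)
  tips_of <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], tips_of))
  }
  internal <- setdiff(unique(tree$edge[, 1]), ntip + 1L)  # exclude root
  out <- list()
  for (node in sort(internal)) {
    side <- sort(tips_of(node))
    sup <- suppressWarnings(as.numeric(tree$node.label[node - ntip]))
    out[[paste(side, collapse = "|")]] <- sup
  }
  out
}

random_dna_str <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_aa_str <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Shared small simulations, built once per test session.
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(name, builder) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, builder(), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}

small_sim <- function() {
  cached_sim("small", function() {
    suppressWarnings(simulate_pangenome(sim_config(
      n_genomes = 6, n_clades = 2, mean_len = 9000, sd_len = 400,
      mean_orfs = 12, sd_orfs = 2, n_core = 4, mean_unique = 2,
      module_prevalence = 0.34, seed = 42)))
  })
}

protein_sim <- function() {
  cached_sim("protein", function() {
    suppressWarnings(simulate_pangenome(sim_config(
      n_genomes = 12, n_clades = 3, mean_len = 9000, sd_len = 400,
      mean_orfs = 13, sd_orfs = 2, n_core = 5, mean_unique = 2,
      module_prevalence = 0.25, seed = 7), sequences = FALSE))
  })
}
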