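# Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Typical amino-acid composition of globular proteins (UniProt-like),
# used when drawing synthetic ancestor/unique proteins.
AA_FREQ <- c(A = 8.2, C = 1.4, D = 5.4, E = 6.2, F = 3.9, G = 7.1, H = 2.3,
             I = 5.9, K = 5.8, L = 9.9, M = 2.4, N = 4.1, P = 4.7, Q = 3.9,
             R = 5.5, S = 6.6, T = 5.4, V = 6.9, W = 1.1, Y = 2.9)[AA_ALPHABET]
STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

# 12-mer that contains a stop codon in all six reading frames and is its own
# reverse complement; placed on both sides of every planted gene so that the
# planted ORF set is exactly the maximal ORF set of the genome.
STOP_CORE <- "TTAATTAATTAA"

#' Run code with a temporary RNG state
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's RNG stream. When `seed` is `NULL` the expression runs on the
#' current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed from a master seed and a counter, so that
# per-genome / per-station streams are independent of generation order.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 69621) %% 2147483562) + 1L
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop(what, " must be a single non-empty character string")
  }
  bad <- gsub("[ACGTN]", "", toupper(seq))
  if (nzchar(bad)) {
    stop(what, " contains non-ACGTN characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  toupper(seq)
}

check_protein <- function(p, what = "protein") {
  if (!is.character(p) || length(p) != 1L || is.na(p) || !nzchar(p)) {
    stop(what, " must be a single non-empty character string")
  }
  p <- toupper(p)
  bad <- gsub(paste0("[", paste(AA_ALPHABET, collapse = ""), "]"), "", p)
  if (nzchar(bad)) {
    stop(what, " contains non-amino-acid characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  p
}

# Random DNA with a given G+C fraction.
random_dna <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

is_rotation_of <- function(a, b) {
  nchar(a) == nchar(b) && grepl(a, paste0(b, b), fixed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() without the surprise scalar behavior
resample <- function(x) x[sample.int(length(x))]
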