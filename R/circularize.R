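# Terminal direct-repeat detection and circularization.
#
# A linear assembly contig whose start is repeated exactly at its end is the
# signature of a complete (circular or circularly permuted) phage genome; the
# repeat is detected, one copy is trimmed off, and the trimmed sequence is
# flagged circular.

#' Detect a terminal direct repeat on a linear contig
#'
#' Finds the longest prefix of the contig that reappears as its suffix
#' (a terminal direct repeat), requiring length `>= min_overlap` and identity
#' `>= min_identity` over the ungapped end-to-end comparison. With the default
#' `min_identity = 1` the repeat must be exact. `N` bases never match, not
#' even another `N`. Reverse-complement terminal repeats are not considered
#' circularization evidence.
#'
#' @param contig Nucleotide sequence (character string) or a named length-1
#'   character vector.
#' @param min_overlap Minimum repeat length in bases (default 100, the
#'   conventional self-overlap requirement).
#' @param min_identity Minimum identity fraction over the compared ends
#'   (default 1 = exact). Relaxed identity is computed over an ungapped
#'   end alignment anchored on a prefix seed match.
#' @return A list of class `terminal_repeat` with `length`, `identity`,
#'   `head_interval` and `tail_interval` (0-based half-open), or `NULL` when
#'   no qualifying repeat exists.
#' @export
detect_terminal_repeat <- function(contig, min_overlap = 100, min_identity = 1.0) {
  seq <- check_dna(contig, "contig")
  L <- nchar(seq)
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  if (L <= 2L * min_overlap) {
    stop("contig (", L, " nt) is too short to evaluate: need length > 2 * min_overlap",
         call. = FALSE)
  }
  seed <- substr(seq, 1L, min_overlap)
  max_mm <- as.integer(floor((1 - min_identity) * min_overlap))
  hits <- Biostrings::matchPattern(seed,
                                   Biostrings::DNAString(substr(seq, min_overlap + 1L, L)),
                                   max.mismatch = max_mm, fixed = TRUE)
  if (length(hits) == 0L) return(NULL)
  cand_start <- IRanges::start(hits) + min_overlap  # 1-based in full contig
  ## candidate repeat length k: suffix starting at position L - k + 1
  ks <- L - cand_start + 1L
  ks <- sort(unique(ks[ks >= min_overlap & 2L * ks <= L]), decreasing = TRUE)
  if (length(ks) == 0L) return(NULL)
  chars <- strsplit(seq, "")[[1]]
  for (k in ks) {
    a <- chars[1:k]
    b <- chars[(L - k + 1L):L]
    ok <- a == b & a != "N"
    identity <- mean(ok)
    if (identity >= min_identity) {
      rep <- list(length = k, identity = identity,
                  head_interval = c(0L, k), tail_interval = c(L - k, L))
      class(rep) <- "terminal_repeat"
      return(rep)
    }
  }
  NULL
}

#' Trim a terminal repeat and emit a circular genome record
#'
#' Removes the tail copy of a detected terminal repeat, leaving one copy of
#' the repeated sequence, and flags the result circular.
#'
#' @param contig The contig the repeat was detected on (character string).
#' @param repeat_hit A `terminal_repeat` from [detect_terminal_repeat()].
#' @param id Identifier for the resulting genome record.
#' @return A list of class `genome_record`: `id`, `seq`, `circular = TRUE`,
#'   `repeat_len`.
#' @export
trim_to_circle <- function(contig, repeat_hit, id = "genome") {
  seq <- check_dna(contig, "contig")
  if (!inherits(repeat_hit, "terminal_repeat")) {
    stop("repeat_hit must be a terminal_repeat (see detect_terminal_repeat)")
  }
  L <- nchar(seq)
  k <- repeat_hit$length
  if (repeat_hit$tail_interval[2] != L || k != diff(repeat_hit$head_interval)) {
    stop("repeat does not belong to this contig (interval mismatch)")
  }
  if (2L * k > L) stop("degenerate repeat: covers more than half the contig")
  if (repeat_hit$identity >= 1 &&
      substr(seq, 1L, k) != substr(seq, L - k + 1L, L)) {
    stop("repeat does not belong to this contig (sequence mismatch)")
  }
  out <- list(id = id, seq = substr(seq, 1L, L - k), circular = TRUE,
              repeat_len = k)
  class(out) <- "genome_record"
  out
}

#' Keep contigs strictly larger than a length cutoff
#'
#' The conventional completeness screen: only contigs larger than 10 kb are
#' processed further. The cutoff is strict (a 10,000 nt contig is excluded).
#'
#' @param contigs Named character vector or `DNAStringSet`.
#' @param min_len Length cutoff in bases (exclusive).
#' @return The filtered named character vector.
#' @export
length_filter <- function(contigs, min_len = 10000) {
  seqs <- as_seq_vector(contigs)
  seqs[nchar(seqs) > min_len]
}

#' Circularize a set of contigs
#'
#' Applies [detect_terminal_repeat()] and [trim_to_circle()] across a contig
#' set, returning trimmed circular genomes and a per-contig decision report.
#' Contigs shorter than `2 * min_overlap` are reported as unevaluable rather
#' than erroring the batch.
#'
#' @inheritParams detect_terminal_repeat
#' @param contigs Named character vector or `DNAStringSet`.
#' @return A list with `genomes` (named character vector of trimmed circular
#'   sequences) and `report` (data.frame: `contig_id`, `contig_len`,
#'   `repeat_len`, `identity`, `decision` in
#'   `circularized`/`no_repeat`/`too_short`).
#' @export
circularize_contigs <- function(contigs, min_overlap = 100, min_identity = 1.0) {
  seqs <- as_seq_vector(contigs)
  genomes <- character(0)
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    L <- nchar(seqs[[i]])
    if (L <= 2L * min_overlap) {
      rows[[i]] <- data.frame(contig_id = id, contig_len = L,
                              repeat_len = NA_integer_, identity = NA_real_,
                              decision = "too_short", stringsAsFactors = FALSE)
      next
    }
    hit <- detect_terminal_repeat(seqs[[i]], min_overlap, min_identity)
    if (is.null(hit)) {
      rows[[i]] <- data.frame(contig_id = id, contig_len = L,
                              repeat_len = NA_integer_, identity = NA_real_,
                              decision = "no_repeat", stringsAsFactors = FALSE)
    } else {
      rec <- trim_to_circle(seqs[[i]], hit, id = sub("_ctg$", "", id))
      genomes[[rec$id]] <- rec$seq
      rows[[i]] <- data.frame(contig_id = id, contig_len = L,
                              repeat_len = hit$length, identity = hit$identity,
                              decision = "circularized", stringsAsFactors = FALSE)
    }
  }
  list(genomes = genomes,
       report = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
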