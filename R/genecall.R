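# Circular-aware ORF calling and translation.
#
# This is a deliberately simple, deterministic caller: within every
# stop-bounded stretch of a reading frame the longest ORF (first allowed start
# codon) is reported. It stands in for a trained gene finder on synthetic
# genomes, where genes are planted as exactly such maximal ORFs; externally
# called genes can be supplied through `read_gff3()` instead.

#' Find open reading frames on a linear or circular genome
#'
#' Scans all six reading frames for ORFs that begin at an allowed start codon
#' (`ATG`/`GTG`/`TTG`), end at a stop codon, and have nucleotide length
#' (including the stop) of at least `min_len`. Within each stop-bounded
#' stretch of a frame only the longest variant (the first allowed start) is
#' reported. On circular genomes frames wrap the origin; ORF coordinates are
#' reported modulo the genome length.
#'
#' @param genome Nucleotide sequence (single character string, `ACGTN`).
#' @param min_len Minimum ORF length in bases, stop codon included. Default 90.
#' @param circular Logical; scan as a circular genome (frames wrap the origin).
#' @param genome_id Identifier used for the `genome_id`/`gene_id` columns.
#' @param start_codons Allowed initiation codons.
#'
#' @return A data.frame with one row per ORF: `genome_id`, `gene_id`, `start`
#'   (0-based, leftmost forward-strand coordinate of the interval
#'   `[start, start + length)`, taken modulo the genome length), `length`
#'   (bases, stop included), `strand` (`"+"`/`"-"`), `wraps_origin`, and
#'   `protein` (translation under genetic code 11, stop excluded; `GTG`/`TTG`
#'   initiators are translated literally, not forced to methionine). Rows are
#'   ordered by `start`, then strand.
#' @export
#' @examples
#' find_orfs("ATGAAATAA", min_len = 9)
find_orfs <- function(genome, min_len = 90, circular = FALSE,
                      genome_id = "genome", start_codons = START_CODONS) {
  seq <- check_dna(genome, "genome")
  L <- nchar(seq)
  if (min_len < 6) stop("min_len must be at least 6 (start plus stop codon)")
  s <- if (circular) paste0(seq, seq) else seq
  rows <- list()
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") s else revcomp(s)
    n <- nchar(ss)
    chars <- strsplit(ss, "")[[1]]
    for (f in 0:2) {
      if (n - f < 3) next
      cs <- seq.int(f + 1L, n - 2L, by = 3L)
      codons <- paste0(chars[cs], chars[cs + 1L], chars[cs + 2L])
      stop_ix <- which(codons %in% STOP_CODONS)
      if (length(stop_ix) == 0L) next  # no stop in frame: no reportable ORF
      is_start <- codons %in% start_codons
      prev <- if (circular) NA_integer_ else 0L
      for (j in stop_ix) {
        lo <- if (is.na(prev)) NA_integer_ else prev + 1L
        prev <- j
        if (is.na(lo)) next  # circular: skip stretch without upstream stop
        if (j - lo < 1L) next
        ks <- which(is_start[lo:(j - 1L)])
        if (length(ks) == 0L) next
        k <- lo + ks[1L] - 1L
        len <- (j - k + 1L) * 3L
        if (len < min_len || len > L) next
        a <- cs[k]
        b <- cs[j] + 2L
        if (strand == "+") {
          left <- a
        } else {
          left <- n - b + 1L
        }
        start0 <- (left - 1L) %% L
        rows[[length(rows) + 1L]] <- list(
          start = start0, length = len, strand = strand,
          wraps_origin = start0 + len > L,
          protein = translate_codons(codons[k:(j - 1L)])
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(empty_gene_frame(genome_id))
  }
  df <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  df <- unique(df)  # circular scans see each ORF in both copies
  df <- df[order(df$start, df$strand, df$length), , drop = FALSE]
  data.frame(
    genome_id = genome_id,
    gene_id = sprintf("%s_%04d", genome_id, seq_len(nrow(df))),
    df, row.names = NULL, stringsAsFactors = FALSE
  )
}

empty_gene_frame <- function(genome_id) {
  data.frame(genome_id = character(), gene_id = character(),
             start = integer(), length = integer(), strand = character(),
             wraps_origin = logical(), protein = character(),
             stringsAsFactors = FALSE)
}

# Translate a codon character vector under genetic code 11.
translate_codons <- function(codons) {
  code <- genetic_code11()
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

genetic_code11 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc11 <- Biostrings::getGeneticCode("11")
      cache <<- setNames(as.character(gc11), names(gc11))
    }
    cache
  }
})

#' Translate one gene from its genome
#'
#' Extracts the interval `[start, start + length)` (modulo the genome length
#' when the gene wraps the origin of a circular genome), reverse-complements it
#' for `-` strand genes, and translates under genetic code 11. The terminal
#' stop codon, when present, is dropped from the protein.
#'
#' @param gene A list or one-row data.frame with `start` (0-based), `length`,
#'   `strand`, and optionally `wraps_origin`.
#' @param genome Nucleotide sequence of the genome (character string).
#' @param circular Logical; genome is circular (permits origin wrap).
#' @return Protein string (no stop).
#' @export
translate_gene <- function(gene, genome, circular = FALSE) {
  seq <- check_dna(genome, "genome")
  L <- nchar(seq)
  start <- as.integer(gene$start)
  len <- as.integer(gene$length)
  if (is.na(start) || is.na(len) || start < 0L || start >= L || len < 3L) {
    stop("invalid gene coordinates")
  }
  if (len %% 3L != 0L) stop("gene length must be divisible by 3")
  if (start + len > L) {
    if (!circular) stop("gene extends past the end of a linear genome")
    nt <- paste0(substr(seq, start + 1L, L), substr(seq, 1L, start + len - L))
  } else {
    nt <- substr(seq, start + 1L, start + len)
  }
  if (identical(gene$strand, "-")) nt <- revcomp(nt)
  chars <- strsplit(nt, "")[[1]]
  cs <- seq.int(1L, len - 2L, by = 3L)
  codons <- paste0(chars[cs], chars[cs + 1L], chars[cs + 2L])
  n <- length(codons)
  internal_stop <- which(codons[-n] %in% STOP_CODONS)
  if (length(internal_stop) > 0L) {
    stop("internal stop codon at codon ", internal_stop[1L],
         ": gene coordinates are likely wrong")
  }
  if (codons[n] %in% STOP_CODONS) codons <- codons[-n]
  translate_codons(codons)
}

#' Call ORFs on a set of genomes
#'
#' Convenience wrapper applying [find_orfs()] to every element of a named
#' character vector or `DNAStringSet`.
#'
#' @param genomes Named character vector or `Biostrings::DNAStringSet`.
#' @param circular Logical scalar or vector (recycled) flagging circular
#'   genomes.
#' @inheritParams find_orfs
#' @return Combined gene data.frame (see [find_orfs()]).
#' @export
call_genes <- function(genomes, circular = TRUE, min_len = 90) {
  seqs <- as_seq_vector(genomes)
  circular <- rep_len(circular, length(seqs))
  out <- mapply(function(s, id, circ) find_orfs(s, min_len = min_len,
                                                circular = circ, genome_id = id),
                seqs, names(seqs), circular, SIMPLIFY = FALSE)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

as_seq_vector <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    setNames(as.character(x), names(x))
  } else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- sprintf("seq%03d", seq_along(x))
    toupper(x)
  } else {
    stop("expected a character vector or DNAStringSet")
  }
}
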