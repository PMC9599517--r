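# File interchange: FASTA, GFF3, TSV, newick.

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (DNA or protein).
#' @param file Output path.
#' @param type `"dna"` or `"protein"`.
#' @export
write_fasta <- function(seqs, file, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = file)
  invisible(file)
}

#' Read a FASTA file into a named character vector
#'
#' @param file Input path.
#' @param type `"dna"` or `"protein"`.
#' @export
read_fasta <- function(file, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::readDNAStringSet(file)
         else Biostrings::readAAStringSet(file)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write a gene table as GFF3
#'
#' Genes wrapping a circular origin are written with `end` beyond the genome
#' length and a `wraps_origin=true` attribute, since GFF3 has no native
#' origin-spanning representation.
#'
#' @param genes Gene table (`genome_id`, `gene_id`, `start` 0-based,
#'   `length`, `strand`, and optional `label`, `category`, `component`).
#' @param file Output path.
#' @param source Value of the GFF3 source column.
#' @export
write_gff3 <- function(genes, file, source = "phagepan") {
  attr_field <- function(i) {
    parts <- c(paste0("ID=", genes$gene_id[i]))
    for (col in c("label", "category", "component", "og_id")) {
      if (col %in% names(genes) && !is.na(genes[[col]][i])) {
        parts <- c(parts, paste0(col, "=", gsub("[;=\t]", "_", genes[[col]][i])))
      }
    }
    if (isTRUE(genes$wraps_origin[i])) parts <- c(parts, "wraps_origin=true")
    paste(parts, collapse = ";")
  }
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(genes)), function(i) {
               paste(genes$genome_id[i], source, "CDS",
                     genes$start[i] + 1L, genes$start[i] + genes$length[i],
                     ".", genes$strand[i], "0", attr_field(i), sep = "\t")
             }, character(1)))
  writeLines(lines, file)
  invisible(file)
}

#' Read externally called genes from GFF3
#'
#' Uses `rtracklayer` when available, falling back to a minimal parser of the
#' nine mandatory columns. Externally supplied gene calls take precedence
#' over the built-in ORF caller when both exist.
#'
#' @param file GFF3 path.
#' @return Gene table: `genome_id`, `gene_id`, `start` (0-based), `length`,
#'   `strand`, plus any of `label`, `category`, `component` present as
#'   attributes.
#' @export
read_gff3 <- function(file) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- as.data.frame(rtracklayer::import(file, format = "gff3"))
    out <- data.frame(
      genome_id = as.character(gr$seqnames),
      gene_id = if ("ID" %in% names(gr)) as.character(gr$ID)
                else sprintf("gene%05d", seq_len(nrow(gr))),
      start = gr$start - 1L,
      length = gr$width,
      strand = as.character(gr$strand),
      stringsAsFactors = FALSE)
    for (col in c("label", "category", "component")) {
      if (col %in% names(gr)) out[[col]] <- as.character(gr[[col]])
    }
  } else {
    lines <- readLines(file)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    get_attr <- function(a, key) {
      m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]*)"), a))[[1]]
      if (length(m) == 2L) m[2] else NA_character_
    }
    out <- do.call(rbind, lapply(f, function(x) {
      data.frame(genome_id = x[1],
                 gene_id = get_attr(x[9], "ID"),
                 start = as.integer(x[4]) - 1L,
                 length = as.integer(x[5]) - as.integer(x[4]) + 1L,
                 strand = x[7],
                 label = get_attr(x[9], "label"),
                 category = get_attr(x[9], "category"),
                 component = get_attr(x[9], "component"),
                 stringsAsFactors = FALSE)
    }))
  }
  out$strand[!out$strand %in% c("+", "-")] <- "+"
  out
}

#' Write a data.frame as TSV
#' @param x data.frame.
#' @param file Output path.
#' @export
write_tsv <- function(x, file) {
  listcols <- vapply(x, is.list, logical(1))
  x[listcols] <- lapply(x[listcols], vapply,
                        FUN.VALUE = character(1),
                        function(v) paste(v, collapse = ","))
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a TSV into a data.frame
#' @param file Input path.
#' @export
read_tsv <- function(file) {
  read.delim(file, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
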