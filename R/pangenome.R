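# Presence/absence accounting: pan-genome size, core genes, shared vs unique
# classification, pairwise shared-orthogroup percentages.

#' Build the genome-by-orthogroup presence matrix
#'
#' Cell `(g, og)` counts the members of orthogroup `og` found in genome `g`
#' (0 = absent; paralogs give counts > 1). Rows cover every genome seen in
#' `genes`, including genomes with no orthogroup members.
#'
#' @param orthogroups data.frame with `og_id`, `gene_id` (as from
#'   [build_orthogroups()]).
#' @param genes data.frame with `gene_id`, `genome_id` covering every
#'   orthogroup member.
#' @return Integer matrix, rows = genome ids, columns = orthogroup ids.
#' @export
build_presence_matrix <- function(orthogroups, genes) {
  missing <- setdiff(orthogroups$gene_id, genes$gene_id)
  if (length(missing) > 0L) {
    stop("orthogroup members with no genome assignment: ",
         paste(head(missing, 5), collapse = ", "))
  }
  genomes <- sort(unique(genes$genome_id))
  ogs <- sort(unique(orthogroups$og_id))
  m <- matrix(0L, nrow = length(genomes), ncol = length(ogs),
              dimnames = list(genomes, ogs))
  if (nrow(orthogroups) > 0L) {
    gmap <- setNames(genes$genome_id, genes$gene_id)
    tab <- table(factor(gmap[orthogroups$gene_id], levels = genomes),
                 factor(orthogroups$og_id, levels = ogs))
    m[] <- as.integer(tab)
  }
  m
}

#' Core orthogroups: present in every genome
#'
#' @param matrix Presence matrix from [build_presence_matrix()].
#' @return Character vector of orthogroup ids with a nonzero cell in every
#'   genome. A single-genome matrix makes every orthogroup trivially core
#'   (warned).
#' @export
core_orthogroups <- function(matrix) {
  if (nrow(matrix) == 0L || ncol(matrix) == 0L) return(character(0))
  if (nrow(matrix) == 1L) {
    warning("single-genome matrix: every orthogroup is trivially core")
  }
  colnames(matrix)[colSums(matrix > 0L) == nrow(matrix)]
}

#' Classify genes as shared or unique
#'
#' A gene is *shared* when its orthogroup spans two or more genomes; genes in
#' no orthogroup, and paralog families confined to a single genome, are
#' *unique* (one or more copies within a single genome, no detection in the
#' others).
#'
#' @param matrix Presence matrix.
#' @param genes data.frame with `gene_id`, `genome_id`, and `og_id`
#'   (`NA` for genes in no orthogroup).
#' @return `genes` with an added `class` column (`"shared"`/`"unique"`).
#' @export
classify_shared_unique <- function(matrix, genes) {
  span <- colSums(matrix > 0L)
  og_shared <- names(span)[span >= 2L]
  genes$class <- ifelse(!is.na(genes$og_id) & genes$og_id %in% og_shared,
                        "shared", "unique")
  genes
}

#' Percent of proteins in mutually shared orthogroups for a genome pair
#'
#' `100 * (proteins of a and b belonging to orthogroups present in both) /
#' (total proteins of a and b)` — protein-weighted sharing. The unweighted
#' alternative (`weighted = FALSE`) is the Jaccard percentage of the two
#' genomes' orthogroup sets.
#'
#' @param matrix Presence matrix.
#' @param genome_a,genome_b Row names in `matrix`.
#' @param totals Optional named vector of total gene counts per genome
#'   (orthogroup members plus singletons). Defaults to `rowSums(matrix)`,
#'   which equals the true totals only when every gene is in an orthogroup.
#' @param weighted Protein-weighted definition (default) or orthogroup-count
#'   Jaccard.
#' @return Percent in `[0, 100]`; symmetric in its two genome arguments.
#' @export
shared_og_percent <- function(matrix, genome_a, genome_b, totals = NULL,
                              weighted = TRUE) {
  if (!genome_a %in% rownames(matrix) || !genome_b %in% rownames(matrix)) {
    stop("both genomes must be rows of the presence matrix")
  }
  a <- matrix[genome_a, ]; b <- matrix[genome_b, ]
  both <- a > 0L & b > 0L
  if (!weighted) {
    either <- a > 0L | b > 0L
    if (sum(either) == 0L) return(0)
    return(100 * sum(both) / sum(either))
  }
  if (is.null(totals)) totals <- rowSums(matrix)
  denom <- totals[[genome_a]] + totals[[genome_b]]
  if (denom == 0L) return(0)
  100 * (sum(a[both]) + sum(b[both])) / denom
}

#' Pan-genome summary statistics
#'
#' Aggregates total gene count, the percentage of genes belonging to
#' (multi-genome) orthogroups, orthogroup and core counts, and per-genome
#' shared/unique gene counts.
#'
#' @param matrix Presence matrix.
#' @param genes data.frame with `gene_id`, `genome_id`, `og_id` (`NA` when in
#'   no orthogroup).
#' @return A list of class `pangenome_summary`: `total_genes`,
#'   `genes_in_orthogroups_pct`, `n_orthogroups` (spanning >= 2 genomes),
#'   `n_core`, and `per_genome` (data.frame `genome_id`, `shared`, `unique`,
#'   `total`).
#' @export
pangenome_summary <- function(matrix, genes) {
  if (nrow(genes) == 0L) {
    warning("no genes: empty pan-genome summary")
    out <- list(total_genes = 0L, genes_in_orthogroups_pct = 0,
                n_orthogroups = 0L, n_core = 0L,
                per_genome = data.frame(genome_id = character(),
                                        shared = integer(), unique = integer(),
                                        total = integer()))
    class(out) <- "pangenome_summary"
    return(out)
  }
  cls <- classify_shared_unique(matrix, genes)
  per <- do.call(rbind, lapply(split(cls, cls$genome_id), function(d) {
    data.frame(genome_id = d$genome_id[1],
               shared = sum(d$class == "shared"),
               unique = sum(d$class == "unique"),
               total = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  span <- colSums(matrix > 0L)
  out <- list(
    total_genes = nrow(genes),
    genes_in_orthogroups_pct = 100 * sum(cls$class == "shared") / nrow(genes),
    n_orthogroups = sum(span >= 2L),
    n_core = length(core_orthogroups(matrix)),
    per_genome = per)
  class(out) <- "pangenome_summary"
  out
}

#' @export
print.pangenome_summary <- function(x, ...) {
  cat("Pan-genome:", x$total_genes, "genes;",
      sprintf("%.1f%%", x$genes_in_orthogroups_pct), "in orthogroups;",
      x$n_orthogroups, "orthogroups (>= 2 genomes);",
      x$n_core, "core\n")
  cat("Mean unique genes/genome:",
      sprintf("%.1f", mean(x$per_genome$unique)), "\n")
  invisible(x)
}
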