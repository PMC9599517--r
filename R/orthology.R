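# Pairwise protein similarity, orthogroup clustering, AAI, and
# reference-based screening.
#
# Similarity is global alignment (Needleman-Wunsch with affine gaps, BLOSUM62)
# with identity counted over all alignment columns, gap columns included — a
# conservative reading of "amino-acid similarity". Orthogroups are connected
# components of the identity/coverage-thresholded similarity graph: a
# deterministic, oracle-testable stand-in for score-based MCL clustering, and
# adequate at the divergence regimes the generator plants.

#' Globally align two proteins and report identity and coverage
#'
#' @param prot_a,prot_b Amino-acid strings.
#' @param gap_open,gap_extend Affine gap penalties (a gap of length g costs
#'   `gap_open + g * gap_extend`).
#' @param ids Optional character vector of length 2 used for the `gene_a`,
#'   `gene_b` fields.
#' @return A one-row data.frame of class `similarity_edge`: `gene_a`,
#'   `gene_b`, `identity` (percent of alignment columns, gaps in the
#'   denominator), `coverage` (aligned residue pairs / length of the shorter
#'   protein), `score`.
#' @export
protein_similarity <- function(prot_a, prot_b, gap_open = 10, gap_extend = 0.5,
                               ids = c("a", "b")) {
  a <- check_protein(prot_a, "prot_a")
  b <- check_protein(prot_b, "prot_b")
  res <- align_protein_pairs(a, b, gap_open, gap_extend)
  out <- data.frame(gene_a = ids[1], gene_b = ids[2],
                    identity = res$identity, coverage = res$coverage,
                    score = res$score, stringsAsFactors = FALSE)
  class(out) <- c("similarity_edge", class(out))
  out
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Vectorized global alignment of paired protein vectors, chunked to bound
# memory on large batches.
align_protein_pairs <- function(a, b, gap_open = 10, gap_extend = 0.5,
                                chunk = 2000L) {
  n_total <- length(a)
  ident <- numeric(n_total); cov <- numeric(n_total); sc <- numeric(n_total)
  for (lo in seq.int(1L, n_total, by = chunk)) {
    hi <- min(lo + chunk - 1L, n_total)
    idx <- lo:hi
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(a[idx]), Biostrings::AAStringSet(b[idx]),
      type = "global", substitutionMatrix = blosum62(),
      gapOpening = gap_open, gapExtension = gap_extend)
    pat <- as.character(Biostrings::pattern(aln))
    sub <- as.character(Biostrings::subject(aln))
    for (i in seq_along(idx)) {
      pa <- strsplit(pat[i], "")[[1]]
      sa <- strsplit(sub[i], "")[[1]]
      cols <- length(pa)
      matches <- sum(pa == sa & pa != "-")
      aligned <- sum(pa != "-" & sa != "-")
      ident[idx[i]] <- 100 * matches / cols
      cov[idx[i]] <- aligned / min(nchar(a[idx[i]]), nchar(b[idx[i]]))
    }
    sc[idx] <- Biostrings::score(aln)
  }
  list(identity = ident, coverage = cov, score = sc)
}

#' Prefilter candidate protein pairs by k-mer Jaccard similarity
#'
#' Cheap all-vs-all screen: pairs whose k-mer set Jaccard index reaches
#' `jaccard_min` are passed on to alignment. A reliable superset of
#' high-identity pairs; at identities much below ~60% use a smaller `k` and
#' threshold (the pipeline-scale runs use `k = 4`, `jaccard_min = 0.01`).
#'
#' @param proteins Named character vector of protein sequences.
#' @param k k-mer length (>= 3).
#' @param jaccard_min Minimum Jaccard index.
#' @return data.frame `id_a`, `id_b`, `jaccard` (id_a < id_b).
#' @export
candidate_pairs <- function(proteins, k = 5, jaccard_min = 0.05) {
  if (k < 3) stop("k must be >= 3")
  n <- length(proteins)
  ids <- names(proteins) %||% as.character(seq_len(n))
  kmer_sets <- lapply(proteins, function(p) {
    L <- nchar(p)
    if (L < k) return(character(0))
    unique(substring(p, 1:(L - k + 1), k:L))
  })
  ## inverted index: count shared k-mers per pair (pair encoded as a double)
  idx <- rep(seq_len(n), lengths(kmer_sets))
  km <- unlist(kmer_sets, use.names = FALSE)
  pair_keys <- lapply(split(idx, km), function(grp) {
    if (length(grp) < 2L) return(numeric(0))
    grp <- sort(grp)
    prs <- combn(grp, 2L)
    (prs[1L, ] - 1) * n + prs[2L, ]
  })
  keys <- unlist(pair_keys, use.names = FALSE)
  if (length(keys) == 0L) {
    return(data.frame(id_a = character(), id_b = character(),
                      jaccard = numeric(), stringsAsFactors = FALSE))
  }
  r <- rle(sort(keys))
  inter <- r$lengths
  i <- as.integer((r$values - 1) %/% n) + 1L
  j <- as.integer(r$values - (i - 1) * n)
  uni <- lengths(kmer_sets)[i] + lengths(kmer_sets)[j] - inter
  jac <- ifelse(uni > 0, inter / uni, 0)
  keep <- jac >= jaccard_min
  out <- data.frame(id_a = ids[i[keep]], id_b = ids[j[keep]],
                    jaccard = jac[keep], stringsAsFactors = FALSE)
  out[order(out$id_a, out$id_b), , drop = FALSE]
}

#' Compute similarity edges for a set of proteins
#'
#' Aligns either all pairs (`prefilter = FALSE`) or the k-mer candidate pairs,
#' returning one symmetric edge per aligned pair.
#'
#' @param proteins Named character vector.
#' @inheritParams candidate_pairs
#' @inheritParams protein_similarity
#' @param prefilter Use [candidate_pairs()] before aligning.
#' @return data.frame `gene_a`, `gene_b`, `identity`, `coverage`, `score`.
#' @export
similarity_edges <- function(proteins, prefilter = length(proteins) > 200,
                             k = 4, jaccard_min = 0.01,
                             gap_open = 10, gap_extend = 0.5) {
  ids <- names(proteins) %||% as.character(seq_along(proteins))
  names(proteins) <- ids
  if (prefilter) {
    prs <- candidate_pairs(proteins, k = k, jaccard_min = jaccard_min)
    ia <- prs$id_a; ib <- prs$id_b
  } else {
    if (length(proteins) < 2L) {
      return(data.frame(gene_a = character(), gene_b = character(),
                        identity = numeric(), coverage = numeric(),
                        score = numeric(), stringsAsFactors = FALSE))
    }
    prs <- combn(ids, 2L)
    ia <- prs[1L, ]; ib <- prs[2L, ]
  }
  if (length(ia) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      identity = numeric(), coverage = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  res <- align_protein_pairs(unname(proteins[ia]), unname(proteins[ib]),
                             gap_open, gap_extend)
  data.frame(gene_a = ia, gene_b = ib, identity = res$identity,
             coverage = res$coverage, score = res$score,
             stringsAsFactors = FALSE)
}

#' Cluster similarity edges into orthogroups
#'
#' Orthogroups are the connected components (of size >= 2) of the graph whose
#' edges pass both the identity and coverage thresholds. Genes in no passing
#' edge are reported as singletons. Orthogroup ids are assigned by the
#' lexicographically smallest member id, so output is deterministic.
#'
#' @param edges data.frame with `gene_a`, `gene_b`, `identity`, `coverage`
#'   (as from [similarity_edges()]).
#' @param min_identity Minimum percent identity for an edge to count.
#' @param min_coverage Minimum coverage for an edge to count.
#' @param gene_ids Optional universe of gene ids; genes absent from passing
#'   edges become singletons.
#' @return A list with `orthogroups` (data.frame `og_id`, `gene_id`) and
#'   `singletons` (character vector).
#' @export
build_orthogroups <- function(edges, min_identity = 30, min_coverage = 0.5,
                              gene_ids = NULL) {
  keep <- edges$identity >= min_identity & edges$coverage >= min_coverage
  ed <- edges[keep, , drop = FALSE]
  universe <- sort(unique(c(gene_ids, edges$gene_a, edges$gene_b)))
  if (nrow(ed) == 0L) {
    return(list(orthogroups = data.frame(og_id = character(),
                                         gene_id = character(),
                                         stringsAsFactors = FALSE),
                singletons = universe))
  }
  g <- igraph::graph_from_data_frame(ed[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = universe))
  comp <- igraph::components(g)
  member <- split(names(comp$membership), comp$membership)
  member <- member[lengths(member) >= 2L]
  ## deterministic ordering by smallest member id
  member <- member[order(vapply(member, min, character(1)))]
  og_ids <- sprintf("OG%04d", seq_along(member))
  orthogroups <- data.frame(
    og_id = rep(og_ids, lengths(member)),
    gene_id = unlist(member, use.names = FALSE),
    stringsAsFactors = FALSE)
  singletons <- setdiff(universe, orthogroups$gene_id)
  list(orthogroups = orthogroups, singletons = singletons)
}

#' Average amino-acid identity between two proteomes
#'
#' Aligns all protein pairs between the two genomes, finds reciprocal best
#' hits (best score in both directions; ties broken by score then
#' lexicographic gene id), and returns the mean percent identity over the RBH
#' pairs. Symmetric by construction; the AAI of a proteome with itself is 100.
#'
#' @param proteins_a,proteins_b Named character vectors of proteins.
#' @param min_identity Evidence floor (percent): reciprocal best-hit pairs
#'   below this identity are discarded, emulating the absence of a search
#'   hit between non-homologous proteins in alignment-search based AAI.
#' @return AAI percent, or `NA_real_` (with a warning) when there are no
#'   reciprocal best hits — undefined, as distinct from 0.
#' @export
compute_aai <- function(proteins_a, proteins_b, min_identity = 20) {
  if (length(proteins_a) < 1L || length(proteins_b) < 1L) {
    stop("both genomes must have at least one protein")
  }
  ida <- names(proteins_a) %||% paste0("a", seq_along(proteins_a))
  idb <- names(proteins_b) %||% paste0("b", seq_along(proteins_b))
  na <- length(proteins_a); nb <- length(proteins_b)
  pa <- rep(unname(proteins_a), times = nb)
  pb <- rep(unname(proteins_b), each = na)
  res <- align_protein_pairs(pa, pb)
  score <- matrix(res$score, nrow = na, ncol = nb, dimnames = list(ida, idb))
  ident <- matrix(res$identity, nrow = na, ncol = nb, dimnames = list(ida, idb))
  best_b_for_a <- apply(score, 1L, function(r) colnames(score)[order(-r, colnames(score))[1]])
  best_a_for_b <- apply(score, 2L, function(c) rownames(score)[order(-c, rownames(score))[1]])
  rbh <- which(best_a_for_b[best_b_for_a[ida]] == ida)
  vals <- ident[cbind(ida[rbh], best_b_for_a[ida[rbh]])]
  vals <- vals[vals >= min_identity]
  if (length(vals) == 0L) {
    warning("no reciprocal best hits: AAI undefined")
    return(NA_real_)
  }
  mean(vals)
}

#' Screen genomes for similarity to reference proteins
#'
#' Retains genomes containing at least one protein whose global identity to at
#' least one reference protein reaches `min_identity` percent — the marker
#' screen used to select genomes related to cultured isolates (e.g., >= 45%
#' PolA amino-acid similarity).
#'
#' @param genome_proteins Named list: genome id -> character vector of
#'   proteins.
#' @param reference_proteins Character vector of reference proteins.
#' @param min_identity Percent identity floor (default 45).
#' @return Character vector of retained genome ids.
#' @export
screen_by_reference <- function(genome_proteins, reference_proteins,
                                min_identity = 45) {
  if (length(reference_proteins) == 0L) stop("reference set must be non-empty")
  keep <- vapply(genome_proteins, function(prots) {
    for (ref in reference_proteins) {
      res <- align_protein_pairs(prots, rep(ref, length(prots)))
      if (any(res$identity >= min_identity)) return(TRUE)
    }
    FALSE
  }, logical(1))
  names(genome_proteins)[keep]
}
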