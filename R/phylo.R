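# Distance trees with bootstrap supports, and the dual-tree clade
# delineation rule: a clade is reported only when the same leaf set appears
# as a supported bipartition in BOTH trees, with at least `min_members`
# members and at least `min_support` bootstrap support in each tree.

#' Neighbor-joining tree from a distance matrix
#'
#' Thin, validated front end to the standard neighbor-joining algorithm
#' (`ape::nj`). The input must be symmetric with a zero diagonal.
#'
#' @param distance_matrix Square numeric matrix (or `dist`) with labels.
#' @return An `ape::phylo` tree (no support values).
#' @export
nj_tree <- function(distance_matrix) {
  d <- as.matrix(distance_matrix)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be square and symmetric")
  }
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  ape::nj(stats::as.dist(d))
}

#' Proportion-of-differences (p) distance between aligned sequences
#'
#' @param alignment Character matrix (rows = taxa, columns = aligned sites).
#' @return Symmetric distance matrix of per-site mismatch proportions.
#' @export
p_distance <- function(alignment) {
  if (!is.matrix(alignment)) stop("alignment must be a character matrix")
  n <- nrow(alignment); p <- ncol(alignment)
  lv <- sort(unique(as.vector(alignment)))
  code <- matrix(match(alignment, lv), nrow = n)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    xi <- code[i, ]
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- sum(xi != code[j, ]) / p
    }
  }
  rownames(D) <- colnames(D) <- rownames(alignment)
  D
}

#' Concatenated ortholog alignment matrix
#'
#' Builds a character matrix (rows = genomes, columns = residue positions)
#' by concatenating one member protein per genome from each of the given
#' orthogroups. Orthogroup members must have equal protein lengths (the
#' generator plants substitution-only orthologs, so concatenation is an
#' alignment); genomes missing an orthogroup, or paralogous extra copies,
#' are an error.
#'
#' @param genes Gene table with `genome_id`, `og_id`, `protein`.
#' @param og_ids Orthogroups to concatenate (e.g. the core set).
#' @return Character matrix with genome ids as row names.
#' @export
og_alignment <- function(genes, og_ids) {
  genomes <- sort(unique(genes$genome_id))
  blocks <- lapply(og_ids, function(og) {
    d <- genes[!is.na(genes$og_id) & genes$og_id == og, ]
    if (!setequal(d$genome_id, genomes) || nrow(d) != length(genomes)) {
      stop("orthogroup ", og, " is not single-copy in every genome")
    }
    if (length(unique(nchar(d$protein))) != 1L) {
      stop("orthogroup ", og, " has members of unequal length")
    }
    do.call(rbind, strsplit(d$protein[match(genomes, d$genome_id)], ""))
  })
  m <- do.call(cbind, blocks)
  rownames(m) <- genomes
  m
}

#' Bootstrap supports by column resampling
#'
#' Classical (Felsenstein) bootstrap: alignment columns are resampled with
#' replacement `n_reps` times, a tree is built from each replicate, and each
#' internal edge of the reference tree is annotated with the percentage of
#' replicate trees containing the same bipartition. The reference tree is
#' built from the unresampled alignment.
#'
#' @param alignment Character matrix (rows = taxa).
#' @param tree_builder Function mapping an alignment matrix to a `phylo`;
#'   defaults to neighbor joining on p-distances.
#' @param n_reps Number of bootstrap replicates; 0 returns the unannotated
#'   reference tree.
#' @param seed Optional seed (restores the caller's RNG state).
#' @return A `phylo` with percentage supports in `node.label`.
#' @export
bootstrap_supports <- function(alignment, tree_builder = NULL, n_reps = 1000,
                               seed = NULL) {
  if (!is.matrix(alignment) || ncol(alignment) < 1L) {
    stop("alignment must be a matrix with at least one column")
  }
  if (is.null(tree_builder)) {
    tree_builder <- function(m) nj_tree(p_distance(m))
  }
  ref <- tree_builder(alignment)
  if (n_reps == 0L) return(ref)
  counts <- with_seed(seed, {
    ape::boot.phylo(ref, alignment, FUN = tree_builder, B = n_reps,
                    rooted = FALSE, quiet = TRUE)
  })
  ref$node.label <- round(100 * counts / n_reps, 1)
  ref
}

## ---- bipartition machinery -------------------------------------------------

# Candidate clades of a support tree: for each internal edge, the minority
# side of its bipartition (a clade must contain fewer than half the leaves;
# this makes the candidate set independent of rooting), keyed by the sorted
# member list, with the edge's support.
clade_candidates <- function(tree) {
  tree <- normalize_supports(tree)
  tips <- tree$tip.label
  n <- length(tips)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  nn <- tree$Nnode
  supports <- suppressWarnings(as.numeric(tree$node.label %||% rep(NA_real_, nn)))
  if (length(supports) < nn) supports <- c(supports, rep(NA_real_, nn - length(supports)))
  out <- list()
  for (i in seq_along(pp)) {
    if (i == 1L) next  # root "bipartition" = all tips
    side <- labs[pp[[i]]]
    other <- setdiff(tips, side)
    cand <- if (length(side) <= length(other)) side else other
    if (length(cand) < 2L) next
    key <- paste(sort(cand), collapse = "\r")
    sup <- supports[i]
    prev <- out[[key]]
    if (is.null(prev) || (!is.na(sup) && (is.na(prev) || sup > prev))) {
      out[[key]] <- sup
    }
  }
  out
}

# Scale supports given in [0, 1] to percent.
normalize_supports <- function(tree) {
  nl <- tree$node.label
  if (is.null(nl)) return(tree)
  vals <- suppressWarnings(as.numeric(nl))
  num <- vals[!is.na(vals)]
  if (length(num) > 0L && all(num >= 0) && all(num <= 1) && any(num < 1)) {
    warning("node supports look like fractions in [0, 1]; rescaling to percent")
    tree$node.label <- ifelse(is.na(vals), nl, as.character(vals * 100))
  }
  tree
}

#' Delineate clades coherent and supported in two trees
#'
#' A candidate clade is a leaf set that appears as a (minority-side)
#' bipartition with support `>= min_support` in *both* trees and has at least
#' `min_members` members. Only maximal candidates are reported (no reported
#' clade nests inside another), so the reported clades are pairwise disjoint.
#' If two surviving candidates partially overlap (possible across two trees),
#' neither is reported and a warning is raised.
#'
#' @param tree_a,tree_b `phylo` trees over identical leaf sets, with
#'   bootstrap percentages as `node.label` (fractions in `[0, 1]` are
#'   rescaled with a warning).
#' @param min_support Minimum support required in both trees (default 90).
#' @param min_members Minimum clade size (default 3).
#' @return data.frame of class `clade_set`: `clade_id` (Roman numerals in
#'   decreasing size order), `size`, `support_a`, `support_b`, and `members`
#'   (list column of leaf labels).
#' @export
delineate_clades <- function(tree_a, tree_b, min_support = 90, min_members = 3) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label)) {
    stop("the two trees must share an identical leaf set")
  }
  ca <- clade_candidates(tree_a)
  cb <- clade_candidates(tree_b)
  keys <- intersect(names(ca), names(cb))
  sup_a <- unlist(ca[keys]) %||% numeric(0)
  sup_b <- unlist(cb[keys]) %||% numeric(0)
  sets <- strsplit(keys, "\r", fixed = TRUE)
  sizes <- lengths(sets)
  ok <- !is.na(sup_a) & !is.na(sup_b) &
    sup_a >= min_support & sup_b >= min_support & sizes >= min_members
  sets <- sets[ok]; sup_a <- sup_a[ok]; sup_b <- sup_b[ok]; sizes <- sizes[ok]
  ## maximal-only, with partial-overlap exclusion
  ord <- order(-sizes, vapply(sets, function(s) s[1], character(1)))
  accepted <- integer(0)
  dropped <- logical(length(sets))
  for (i in ord) {
    rel <- "disjoint"
    conflict <- integer(0)
    for (j in accepted) {
      ov <- length(intersect(sets[[i]], sets[[j]]))
      if (ov == 0L) next
      if (ov == sizes[i]) { rel <- "nested"; break }
      rel <- "partial"; conflict <- c(conflict, j)
    }
    if (rel == "disjoint") {
      accepted <- c(accepted, i)
    } else if (rel == "partial") {
      warning("partially overlapping supported candidates; reporting neither")
      accepted <- setdiff(accepted, conflict)
      dropped[c(i, conflict)] <- TRUE
    }
    ## nested candidates are silently absorbed by the larger clade
  }
  accepted <- accepted[!dropped[accepted]]
  if (length(accepted) == 0L) {
    out <- data.frame(clade_id = character(), size = integer(),
                      support_a = numeric(), support_b = numeric(),
                      stringsAsFactors = FALSE)
    out$members <- list()
    class(out) <- c("clade_set", class(out))
    return(out)
  }
  accepted <- accepted[order(-sizes[accepted],
                             vapply(sets[accepted], function(s) s[1], character(1)))]
  out <- data.frame(
    clade_id = as.character(utils::as.roman(seq_along(accepted))),
    size = sizes[accepted],
    support_a = unname(sup_a[accepted]),
    support_b = unname(sup_b[accepted]),
    stringsAsFactors = FALSE)
  out$members <- sets[accepted]
  class(out) <- c("clade_set", class(out))
  out
}

#' Labels of the sister group of a query clade
#'
#' Finds the smallest clade containing the query leaves, reports whether the
#' query itself is monophyletic, and returns the taxonomy labels of that
#' clade's sister group.
#'
#' @param tree A rooted (or as-read) `phylo`.
#' @param query_leaf_set Character vector of tip labels.
#' @param label_map Named character vector: tip label -> taxonomy label.
#'   Defaults to the tip labels themselves.
#' @return A list: `sister_labels` (character multiset), `sister_tips`,
#'   `monophyletic` (logical).
#' @export
sister_group_labels <- function(tree, query_leaf_set, label_map = NULL) {
  tips <- tree$tip.label
  if (!all(query_leaf_set %in% tips)) stop("query leaves missing from tree")
  if (is.null(label_map)) label_map <- setNames(tips, tips)
  n <- length(tips)
  if (length(query_leaf_set) == 1L) {
    node <- match(query_leaf_set, tips)
  } else {
    node <- ape::getMRCA(tree, query_leaf_set)
  }
  desc <- tips_under(tree, node)
  mono <- setequal(desc, query_leaf_set)
  parent <- tree$edge[tree$edge[, 2] == node, 1]
  if (length(parent) == 0L) {
    warning("query clade spans the root: no sister group")
    return(list(sister_labels = character(0), sister_tips = character(0),
                monophyletic = mono))
  }
  sibs <- setdiff(tree$edge[tree$edge[, 1] == parent, 2], node)
  sister_tips <- unlist(lapply(sibs, function(s) tips_under(tree, s)))
  list(sister_labels = unname(label_map[sister_tips]),
       sister_tips = sister_tips, monophyletic = mono)
}

tips_under <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, function(k) tips_under(tree, k)))
}

#' Read a newick tree with support values
#'
#' Internal-node labels are interpreted as bootstrap supports; values in
#' `[0, 1]` are rescaled to percent with a warning.
#'
#' @param file Path to a newick file.
#' @return A `phylo` with normalized `node.label`.
#' @export
read_support_tree <- function(file) {
  normalize_supports(ape::read.tree(file))
}
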