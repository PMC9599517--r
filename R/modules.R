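# AMG classification, partner-AMG colocation analysis, and T8SS (Curli)
# module extraction, canonicalization, composition tables, family assignment,
# station frequency profiling and associated statistics.
#
# All operations work on annotated gene tables: one row per gene with at
# least `contig_id` (or `genome_id`), a position (`start`, or row order),
# `strand`, and the functional fields `label`, `category` (one of
# core-viral / AMG-nucleotide / AMG-hypermodification / AMG-T8SS / AMG-other /
# hypothetical) and `component` (HK / CsgF / CsgG / CsgA/B / FecR / AC /
# none). Gene-index gaps are counted as intervening genes: `max_gap_genes`
# is the number of non-matching genes tolerated between two neighbors
# (0 = strictly adjacent).

contig_column <- function(genes) {
  if ("contig_id" %in% names(genes)) "contig_id"
  else if ("genome_id" %in% names(genes)) "genome_id"
  else stop("gene table needs a contig_id or genome_id column")
}

order_genes <- function(genes) {
  if ("start" %in% names(genes)) genes[order(genes$start), , drop = FALSE]
  else genes
}

#' Classify auxiliary metabolic genes (AMGs)
#'
#' AMGs are genes assigned a putative cellular-function category
#' (`AMG-nucleotide`, `AMG-hypermodification`, `AMG-T8SS`, `AMG-other`),
#' excluding the core viral replication/packaging set; `core-viral` and
#' `hypothetical` genes never qualify.
#'
#' @param function_table Gene table with `label` and `category` columns.
#' @param core_set Character vector of labels to exclude regardless of
#'   category (the curated core viral gene set).
#' @return The AMG subset of `function_table`.
#' @export
classify_amgs <- function(function_table, core_set = character(0)) {
  stopifnot(all(c("label", "category") %in% names(function_table)))
  keep <- startsWith(function_table$category, "AMG-") &
    !(function_table$label %in% core_set)
  function_table[keep, , drop = FALSE]
}

#' Test a colocation implication between two gene labels
#'
#' Checks whether every genome that encodes an `label_x` gene also has a
#' `label_y` gene within `max_gap_genes` intervening genes of at least one
#' of its `label_x` copies (the observed rule: whenever a phage encoded
#' ferrochelatase, a 2OG-Fe(II) oxygenase was adjacent to it). On circular
#' genomes adjacency wraps the origin.
#'
#' @param genes Gene table (`genome_id`/`contig_id`, position, `label`).
#' @param label_x,label_y Labels to test.
#' @param max_gap_genes Intervening genes tolerated (default 1).
#' @param circular Treat each genome's gene order as circular.
#' @return List: `holds` (logical) and `counterexamples` (genome ids with an
#'   `label_x` but no sufficiently close `label_y`).
#' @export
adjacency_implication <- function(genes, label_x, label_y, max_gap_genes = 1,
                                  circular = TRUE) {
  col <- contig_column(genes)
  bad <- character(0)
  for (d in split(genes, genes[[col]])) {
    d <- order_genes(d)
    n <- nrow(d)
    ix <- which(d$label == label_x)
    if (length(ix) == 0L) next
    iy <- which(d$label == label_y)
    found <- FALSE
    if (length(iy) > 0L) {
      for (i in ix) {
        dd <- abs(iy - i)
        if (circular) dd <- pmin(dd, n - dd)
        if (any(dd <= max_gap_genes + 1L & dd > 0L)) { found <- TRUE; break }
      }
    }
    if (!found) bad <- c(bad, d[[col]][1])
  }
  list(holds = length(bad) == 0L, counterexamples = bad)
}

#' Find partner-AMG pairs in a genome
#'
#' Partner-AMGs are AMG pairs that are colocated (within `window_genes`
#' intervening genes of each other) *and* involved in related functions
#' (identical AMG category).
#'
#' @param genes Gene table for one or more genomes with `label`, `category`.
#' @param window_genes Colocation window (intervening genes; default 5).
#' @param circular Gene order wraps the origin.
#' @return data.frame `genome_id`, `gene_a`, `gene_b`, `label_a`, `label_b`,
#'   `category`, `distance` (gene-index distance).
#' @export
partner_amg_pairs <- function(genes, window_genes = 5, circular = TRUE) {
  col <- contig_column(genes)
  out <- list()
  for (d in split(genes, genes[[col]])) {
    d <- order_genes(d)
    n <- nrow(d)
    amg <- which(startsWith(d$category, "AMG-"))
    if (length(amg) < 2L) next
    prs <- combn(amg, 2L)
    for (pcol in seq_len(ncol(prs))) {
      i <- prs[1, pcol]; j <- prs[2, pcol]
      if (d$category[i] != d$category[j]) next
      dd <- abs(j - i)
      if (circular) dd <- min(dd, n - dd)
      if (dd <= window_genes + 1L) {
        out[[length(out) + 1L]] <- data.frame(
          genome_id = d[[col]][1],
          gene_a = d$gene_id[i], gene_b = d$gene_id[j],
          label_a = d$label[i], label_b = d$label[j],
          category = d$category[i], distance = dd,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(genome_id = character(), gene_a = character(),
                      gene_b = character(), label_a = character(),
                      label_b = character(), category = character(),
                      distance = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Extract T8SS-like gene modules from annotated contigs
#'
#' A module instance is a maximal run of component-labelled genes with at
#' most `max_gap_genes` intervening non-component genes. The composition is
#' read in canonical orientation: the orientation in which CsgF precedes
#' CsgG; when undecidable, the majority gene strand of the run (reverse
#' majority flips the reading order). Duplicate adjacent components (two HKs,
#' a second CsgA/B) are preserved. An instance is flagged `terminal` when a
#' component gene is the first or last gene of its contig.
#'
#' @param genes Gene table with `component` (and optionally `start`,
#'   `length`, `family`).
#' @param vocabulary Component labels that define a module.
#' @param max_gap_genes Intervening non-component genes tolerated (default 1).
#' @return data.frame of module instances: `contig_id`, `composition`,
#'   `n_components`, `span` (bases, first component start to last component
#'   end, `NA` without coordinates), `terminal`, `strand`, `family`,
#'   `first_gene`, `last_gene`.
#' @export
extract_modules <- function(genes, vocabulary = T8SS_COMPONENTS,
                            max_gap_genes = 1) {
  stopifnot("component" %in% names(genes))
  col <- contig_column(genes)
  out <- list()
  for (d in split(genes, genes[[col]])) {
    d <- order_genes(d)
    n <- nrow(d)
    comp_ix <- which(d$component %in% vocabulary)
    if (length(comp_ix) == 0L) next
    run_id <- cumsum(c(1L, diff(comp_ix) > max_gap_genes + 1L))
    for (run in split(comp_ix, run_id)) {
      comps <- d$component[run]
      strands <- d$strand[run]
      reversed <- FALSE
      f <- match("CsgF", comps); g <- match("CsgG", comps)
      if (!is.na(f) && !is.na(g) && f != g) {
        reversed <- f > g
      } else if (mean(strands == "-") > 0.5) {
        reversed <- TRUE
      }
      if (reversed) comps <- rev(comps)
      span <- NA_integer_
      if (all(c("start", "length") %in% names(d))) {
        span <- max(d$start[run] + d$length[run]) - min(d$start[run])
      }
      fam <- if ("family" %in% names(d)) {
        fams <- unique(d$family[run]); fams <- fams[!is.na(fams)]
        if (length(fams) == 1L) fams else "unassigned"
      } else "unassigned"
      out[[length(out) + 1L]] <- data.frame(
        contig_id = d[[col]][1],
        composition = paste(comps, collapse = "-"),
        n_components = length(run),
        span = span,
        terminal = min(run) == 1L || max(run) == n,
        strand = if (mean(strands == "-") > 0.5) "-" else "+",
        family = fam,
        first_gene = d$gene_id[min(run)] %||% NA_character_,
        last_gene = d$gene_id[max(run)] %||% NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(contig_id = character(), composition = character(),
                      n_components = integer(), span = integer(),
                      terminal = logical(), strand = character(),
                      family = character(), first_gene = character(),
                      last_gene = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Drop module instances at contig termini
#'
#' Instances whose first or last contig gene is a module component are
#' possible truncations of an incompletely assembled region and are removed
#' from composition analysis.
#'
#' @param instances Module table from [extract_modules()].
#' @param contigs Unused; accepted for call-site symmetry with extraction.
#' @return The non-terminal subset of `instances`.
#' @export
filter_terminal <- function(instances, contigs = NULL) {
  instances[!instances$terminal, , drop = FALSE]
}

#' Rank module compositions
#'
#' Counts composition strings, optionally per viral family, and reports each
#' as a percentage of all modules of that family. Count ties are ranked
#' lexicographically.
#'
#' @param instances Module table.
#' @param top_k Keep the `top_k` most common compositions (per family).
#' @param by_family Rank within each family separately.
#' @return data.frame `family` (when `by_family`), `composition`, `count`,
#'   `percent`.
#' @export
composition_table <- function(instances, top_k = 10, by_family = TRUE) {
  if (nrow(instances) == 0L) {
    return(data.frame(family = character(), composition = character(),
                      count = integer(), percent = numeric(),
                      stringsAsFactors = FALSE))
  }
  groups <- if (by_family) split(instances, instances$family) else list(all = instances)
  out <- lapply(names(groups), function(f) {
    d <- groups[[f]]
    tab <- as.data.frame(table(composition = d$composition),
                         stringsAsFactors = FALSE)
    names(tab)[2] <- "count"
    tab$percent <- 100 * tab$count / nrow(d)
    tab <- tab[order(-tab$count, tab$composition), , drop = FALSE]
    tab <- head(tab, top_k)
    data.frame(family = f, tab, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (!by_family) res$family <- NULL
  res
}

#' Per-(component, family) identity floors from labelled references
#'
#' The floor for a (component, family) combination is the minimum pairwise
#' identity observed among its reference proteins of known affiliation; hits
#' below the floor are left unassigned.
#'
#' @param references data.frame with `family`, `component`, `protein`.
#' @return data.frame `component`, `family`, `floor` (percent identity).
#' @export
family_identity_floors <- function(references) {
  stopifnot(all(c("family", "component", "protein") %in% names(references)))
  groups <- split(references, list(references$component, references$family),
                  drop = TRUE)
  out <- lapply(groups, function(d) {
    fl <- if (nrow(d) < 2L) 0 else {
      prs <- combn(seq_len(nrow(d)), 2L)
      min(align_protein_pairs(d$protein[prs[1, ]], d$protein[prs[2, ]])$identity)
    }
    data.frame(component = d$component[1], family = d$family[1], floor = fl,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Assign a component protein to a viral family
#'
#' The best-identity reference of the protein's component determines the
#' family; if that best identity falls below the (component, family) floor —
#' the minimum identity among the known-family references — the protein is
#' left `"unassigned"`.
#'
#' @param protein Query protein string.
#' @param references data.frame with `family`, `component`, `protein` (at
#'   least one reference per family per component).
#' @param component Component of the query (subsets the references).
#' @param floors Optional floor table from [family_identity_floors()];
#'   computed from `references` when omitted. A missing floor for the winning
#'   family is an error.
#' @return List: `family` (or `"unassigned"`), `best_identity`, `best_ref`.
#' @export
assign_family <- function(protein, references, component,
                          floors = NULL) {
  refs <- references[references$component == component, , drop = FALSE]
  if (nrow(refs) == 0L) stop("no references for component ", component)
  if (is.null(floors)) floors <- family_identity_floors(references)
  res <- align_protein_pairs(rep(protein, nrow(refs)), refs$protein)
  best <- order(-res$identity, refs$ref_id %||% refs$family)[1]
  fam <- refs$family[best]
  fl <- floors$floor[floors$component == component & floors$family == fam]
  if (length(fl) == 0L) {
    stop("no identity floor for component ", component, ", family ", fam)
  }
  list(family = if (res$identity[best] >= fl) fam else "unassigned",
       best_identity = res$identity[best],
       best_ref = (refs$ref_id %||% refs$family)[best])
}

#' Normalize per-station component hit counts by total viral ORFs
#'
#' @param hits data.frame with `station_id`, `component`, optionally
#'   `family`, and `hits`.
#' @param total_orfs Named vector: station id -> total viral ORFs (> 0).
#' @return `hits` with an added `frequency` column (`hits / total_orfs`).
#' @export
station_frequencies <- function(hits, total_orfs) {
  stopifnot(all(c("station_id", "hits") %in% names(hits)))
  tot <- total_orfs[hits$station_id]
  if (any(is.na(tot))) {
    stop("missing total ORF counts for: ",
         paste(unique(hits$station_id[is.na(tot)]), collapse = ", "))
  }
  if (any(tot <= 0)) stop("total_orfs must be positive for every station")
  hits$frequency <- hits$hits / unname(tot)
  hits
}

#' Fraction of a genome occupied by a module region
#'
#' `100 * span / genome length`, the span running from the first component
#' start to the last component end (intervening genes included).
#'
#' @param genome Genome sequence (character) or its length in bases.
#' @param module_instance A row from [extract_modules()] (uses `span`), or a
#'   number of bases.
#' @return Percent of the genome.
#' @export
region_fraction <- function(genome, module_instance) {
  len <- if (is.character(genome)) nchar(genome) else as.numeric(genome)
  span <- if (is.numeric(module_instance)) module_instance else module_instance$span
  if (is.na(span) || span <= 0) stop("module instance has no usable span")
  if (span > len) stop("module span exceeds genome length")
  100 * span / len
}

#' Pairwise min/max ratio of per-gene counts
#'
#' For every unordered pair of genes, the ratio of the smaller to the larger
#' count; pairs where both counts are zero are skipped (a single zero gives
#' ratio 0). Near-equal counts across the genes of a region (mean ratio close
#' to 1) indicate the region is recruited as a unit.
#'
#' @param counts Numeric vector of per-gene counts (length >= 2).
#' @return List: `mean`, `sd`, `n_pairs`.
#' @export
pairwise_count_ratio <- function(counts) {
  if (length(counts) < 2L) stop("need counts for at least 2 genes")
  if (any(counts < 0)) stop("counts must be non-negative")
  prs <- combn(counts, 2L)
  lo <- pmin(prs[1, ], prs[2, ]); hi <- pmax(prs[1, ], prs[2, ])
  keep <- hi > 0
  if (!any(keep)) stop("all pairs are zero/zero: ratio undefined")
  r <- lo[keep] / hi[keep]
  list(mean = mean(r), sd = if (length(r) > 1L) sd(r) else 0, n_pairs = length(r))
}
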