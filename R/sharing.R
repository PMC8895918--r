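#' Shared-clonotype occupancy across individuals
#'
#' For a group of individuals of the same strain, tissue and isotype, counts
#' in how many individuals each distinct clonotype occurs (its occupancy
#' `k`) and reports the percentage of the clonotype union at each occupancy.
#' Sharing is by presence/absence of the clonotype key, unweighted by
#' abundance; the `k = 1` bin is the fraction of clonotypes private to a
#' single individual.
#'
#' @param subsets Named list with one clone table (or character vector of
#'   clonotype keys) per individual; at least two individuals.
#' @param level Clonotype definition passed to [clonotype_profile()] when
#'   tables are supplied (default `"aa"`).
#' @return Tibble with `k` (1..number of individuals), `n_clonotypes` and
#'   `pct`; percentages sum to 100.
#' @examples
#' subs <- list(m1 = c("CARW", "CASSW"), m2 = c("CARW", "CAAAW"))
#' sharing_ratios(subs)
#' @export
sharing_ratios <- function(subsets, level = "aa") {
  if (!is.list(subsets) || length(subsets) < 2) {
    abort("`subsets` must be a list with at least two individuals")
  }
  keys <- lapply(subsets, function(s) {
    if (is.data.frame(s)) {
      names(clonotype_profile(s, level = level))
    } else {
      unique(as.character(s))
    }
  })
  occupancy <- table(unlist(lapply(keys, unique)))
  m <- length(subsets)
  tab <- table(factor(occupancy, levels = seq_len(m)))
  tibble::tibble(
    k = seq_len(m),
    n_clonotypes = as.integer(tab),
    pct = 100 * as.integer(tab) / sum(tab)
  )
}

#' Cross-individual clonal lineages
#'
#' Pools the distinct `(V, J, CDR3 nt)` clonotypes of all supplied samples
#' (typically every blood and spleen sample of one strain and isotype),
#' clusters them with the lineage criteria — same V, J and CDR3 length, at
#' least `threshold_pct` nucleotide identity, connected components of at
#' least `min_nodes` — and traces each retained node back to the samples in
#' which its exact `(V, J, CDR3 nt)` triple occurs. A lineage is present in
#' a sample when at least one of its nodes traces back to it; its abundance
#' in that sample is the summed node frequency (node clone count divided by
#' the sample's total clone count).
#'
#' @param clones Clone table covering all samples, with a `sample_id` column
#'   (plus `tissue` and any other per-sample metadata) and the usual
#'   `v_gene`, `j_gene`, `cdr3_nt`, `count` columns. Supply a single isotype
#'   at a time.
#' @param threshold_pct Identity threshold in percent (default 95).
#' @param min_nodes Minimum lineage size retained (default 3; use 5 for the
#'   stricter large-lineage variant, or 2 to study the size distribution).
#' @return An object of class `cross_lineages`: list with `network` (the
#'   pooled [build_lineages()] result), `lineages` (tibble: `lineage_id`,
#'   `n_nodes`, `n_samples`, `n_blood`, `n_spleen` when a `tissue` column
#'   exists), `presence` (tibble: `lineage_id`, `sample_id`, `n_nodes`,
#'   `abundance`), `nodes` (per-node lineage table) and `samples` (per-sample
#'   metadata with total clone counts).
#' @export
build_cross_lineages <- function(clones, threshold_pct = 95, min_nodes = 3L) {
  stopifnot(is.data.frame(clones))
  if (!"sample_id" %in% names(clones)) {
    abort("`clones` must have a sample_id column for trace-back")
  }
  meta_cols <- intersect(c("mouse_id", "strain", "tissue", "batch", "isotype"),
                         names(clones))
  samples <- clones |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(meta_cols), dplyr::first),
      total_count = sum(.data$count),
      .groups = "drop"
    )

  net <- build_lineages(clones, threshold_pct = threshold_pct,
                        min_nodes = min_nodes)
  nodes <- net$nodes[!is.na(net$nodes$lineage_id),
                     c("lineage_id", "v_gene", "j_gene", "cdr3_nt",
                       "cdr3_length", "degree")]

  per_sample <- clones |>
    dplyr::group_by(.data$sample_id, .data$v_gene, .data$j_gene,
                    .data$cdr3_nt) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::left_join(samples[, c("sample_id", "total_count")],
                     by = "sample_id") |>
    dplyr::mutate(freq = .data$count / .data$total_count)

  presence <- nodes |>
    dplyr::inner_join(per_sample, by = c("v_gene", "j_gene", "cdr3_nt")) |>
    dplyr::group_by(.data$lineage_id, .data$sample_id) |>
    dplyr::summarise(n_nodes = dplyr::n(), abundance = sum(.data$freq),
                     .groups = "drop")

  lineages <- nodes |>
    dplyr::count(.data$lineage_id, name = "n_nodes") |>
    dplyr::left_join(
      presence |>
        dplyr::count(.data$lineage_id, name = "n_samples"),
      by = "lineage_id"
    )
  lineages$n_samples[is.na(lineages$n_samples)] <- 0L
  if ("tissue" %in% names(samples)) {
    by_tissue <- presence |>
      dplyr::left_join(samples[, c("sample_id", "tissue")], by = "sample_id") |>
      dplyr::group_by(.data$lineage_id) |>
      dplyr::summarise(n_blood = sum(.data$tissue == "blood"),
                       n_spleen = sum(.data$tissue == "spleen"),
                       .groups = "drop")
    lineages <- dplyr::left_join(lineages, by_tissue, by = "lineage_id")
    lineages$n_blood[is.na(lineages$n_blood)] <- 0L
    lineages$n_spleen[is.na(lineages$n_spleen)] <- 0L
  }

  structure(
    list(network = net, lineages = lineages, presence = presence,
         nodes = nodes, samples = samples,
         threshold_pct = threshold_pct, min_nodes = as.integer(min_nodes)),
    class = "cross_lineages"
  )
}

#' @export
print.cross_lineages <- function(x, ...) {
  cat(sprintf(
    "Cross-individual lineages: %d lineages (>= %d nodes) over %d samples\n",
    nrow(x$lineages), x$min_nodes, nrow(x$samples)))
  invisible(x)
}

#' Lineage occupancy over blood and spleen samples
#'
#' Tabulates, as percentages of all retained lineages, how many blood and how
#' many spleen samples each cross-individual lineage is present in. Every
#' lineage contributes to exactly one `(n_blood, n_spleen)` cell, so the
#' matrix sums to 100.
#'
#' @param cl A [build_cross_lineages()] result whose samples carry a
#'   `tissue` column.
#' @return Numeric matrix with rows `n_blood = 0..B` and columns
#'   `n_spleen = 0..S`, where `B` and `S` are the numbers of blood and
#'   spleen samples; empty (0 x 0) when there are no lineages.
#' @export
lineage_occupancy <- function(cl) {
  stopifnot(inherits(cl, "cross_lineages"))
  if (!"tissue" %in% names(cl$samples)) {
    abort("samples carry no `tissue` column; occupancy over tissues is undefined")
  }
  if (nrow(cl$lineages) == 0) return(matrix(numeric(0), 0, 0))
  n_blood_samples <- sum(cl$samples$tissue == "blood")
  n_spleen_samples <- sum(cl$samples$tissue == "spleen")
  tab <- table(
    factor(cl$lineages$n_blood, levels = 0:n_blood_samples),
    factor(cl$lineages$n_spleen, levels = 0:n_spleen_samples)
  )
  out <- matrix(100 * as.numeric(tab) / sum(tab),
                nrow = nrow(tab), ncol = ncol(tab),
                dimnames = list(n_blood = rownames(tab),
                                n_spleen = colnames(tab)))
  out
}

#' Morisita-Horn similarity of lineage abundance profiles
#'
#' Compares two samples at the clonal-lineage level: each lineage's abundance
#' in a sample is the summed frequency of its nodes there, and the
#' Morisita-Horn index is applied to the two lineage-abundance vectors.
#'
#' @param cl A [build_cross_lineages()] result.
#' @param sample_a,sample_b Sample identifiers present in `cl$samples`.
#' @return Similarity in `[0, 1]`.
#' @export
lineage_abundance_mhsi <- function(cl, sample_a, sample_b) {
  stopifnot(inherits(cl, "cross_lineages"))
  prof <- function(s) {
    p <- cl$presence[cl$presence$sample_id == s, ]
    if (nrow(p) == 0 || sum(p$abundance) <= 0) {
      abort(sprintf("sample '%s' has no lineage mass", s))
    }
    stats::setNames(p$abundance, as.character(p$lineage_id))
  }
  mhsi(prof(sample_a), prof(sample_b))
}

#' Distribution of lineage sizes
#'
#' Histogram of node counts over lineages, with the fraction of
#' minimum-size lineages at hand; built from a [build_lineages()] network or
#' the pooled network inside a [build_cross_lineages()] result.
#'
#' @param x A `lineage_network` or `cross_lineages` object.
#' @return Tibble with `size`, `n` and `pct` (percent of lineages).
#' @export
node_size_distribution <- function(x) {
  if (inherits(x, "cross_lineages")) x <- x$network
  stopifnot(inherits(x, "lineage_network"))
  lid <- x$nodes$lineage_id[!is.na(x$nodes$lineage_id)]
  if (length(lid) == 0) {
    return(tibble::tibble(size = integer(), n = integer(), pct = numeric()))
  }
  sizes <- table(table(lid))
  tibble::tibble(
    size = as.integer(names(sizes)),
    n = as.integer(sizes),
    pct = 100 * as.integer(sizes) / sum(sizes)
  )
}

#' Wilcoxon comparison of two groups
#'
#' Unpaired groups are compared with the Wilcoxon rank-sum test, paired
#' groups with the signed-rank test, both two-sided; exact p-values are used
#' for small samples without ties (up to n = 25 per group), a normal
#' approximation with continuity correction otherwise. Paired samples whose
#' differences are all zero carry no signal and return p = 1 with a warning.
#'
#' @param a,b Numeric vectors of observations (equal length when paired).
#' @param paired Use the signed-rank test on paired differences.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return List with `statistic`, `p_value`, `significant` and `method`.
#' @examples
#' compare_groups(1:5, 6:10)  # fully separated: p = 2/choose(10,5)
#' @export
compare_groups <- function(a, b, paired = FALSE, alpha = 0.05) {
  if (length(a) < 1 || length(b) < 1) {
    abort("both groups need at least one observation")
  }
  if (paired && length(a) != length(b)) {
    abort("paired comparison requires equal-length groups")
  }
  if (paired && all(a - b == 0)) {
    warn("all paired differences are zero; p-value undefined, reported as 1")
    return(list(statistic = NA_real_, p_value = 1, significant = FALSE,
                method = "Wilcoxon signed rank test"))
  }
  exact <- if (paired) length(a) <= 25 else max(length(a), length(b)) <= 25
  res <- suppressWarnings(
    stats::wilcox.test(a, b, paired = paired, exact = exact, correct = TRUE,
                       alternative = "two.sided")
  )
  list(statistic = unname(res$statistic), p_value = res$p.value,
       significant = res$p.value < alpha, method = res$method)
}
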