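# Tolerance applied before comparing percent identities to a threshold, so
# that e.g. 19/20 compares equal to 95 despite floating point.
IDENTITY_TOL <- 1e-9

#' Collapse clones to CDR3 nt clonotypes and group by V/J/length
#'
#' Clonal-lineage analysis operates on unique CDR3 nucleotide clonotypes
#' grouped by identical V gene, J gene and CDR3 nucleotide length, since
#' somatic hypermutation preserves all three. This helper collapses a clone
#' table to distinct `(v_gene, j_gene, cdr3_nt)` clonotypes (summing counts)
#' and attaches the grouping key.
#'
#' @param clones Clone table with `v_gene`, `j_gene`, `cdr3_nt` and
#'   optionally `count`.
#' @return Tibble of clonotypes with columns `v_gene`, `j_gene`, `cdr3_nt`,
#'   `cdr3_length`, `count` and the group key `vjl`. Groups partition the
#'   clonotypes exhaustively; singleton groups are retained.
#' @export
group_by_vjl <- function(clones) {
  stopifnot(is.data.frame(clones))
  need <- c("v_gene", "j_gene", "cdr3_nt")
  if (!all(need %in% names(clones))) {
    abort("`clones` must have v_gene, j_gene and cdr3_nt columns")
  }
  if (!"count" %in% names(clones)) clones$count <- 1L
  out <- clones |>
    dplyr::group_by(.data$v_gene, .data$j_gene, .data$cdr3_nt) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(
      cdr3_length = nchar(.data$cdr3_nt),
      vjl = paste(.data$v_gene, .data$j_gene, .data$cdr3_length, sep = "|")
    )
  out
}

#' Percent nucleotide identity between equal-length sequences
#'
#' `100 * matching positions / length`, the similarity measure underlying
#' nearest-neighbor calibration and lineage clustering. Comparing sequences
#' of unequal length is an error: under V/J/length grouping such comparisons
#' never arise.
#'
#' @param a,b Character vectors of equal-length nucleotide sequences
#'   (recycled pairwise).
#' @return Numeric vector of identities in `[0, 100]`.
#' @examples
#' identity_pct("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGA")  # 95
#' @export
identity_pct <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b))) {
    abort("sequences must have equal length (identity is undefined across lengths)")
  }
  vapply(seq_len(n), function(i) {
    100 * (1 - str_mismatches(a[i], b[i]) / nchar(a[i]))
  }, numeric(1))
}

# All-pairs identity matrix for equal-length sequences; O(n^2 L) on the
# group sizes that V/J/length partitioning produces.
pairwise_identity <- function(seqs) {
  n <- length(seqs)
  out <- matrix(100, n, n)
  if (n < 2) return(out)
  mat <- seq_matrix(seqs)
  L <- ncol(mat)
  for (i in seq_len(n - 1)) {
    rest <- (i + 1):n
    matches <- rowSums(mat[rest, , drop = FALSE] ==
                         matrix(mat[i, ], length(rest), L, byrow = TRUE))
    out[i, rest] <- out[rest, i] <- 100 * matches / L
  }
  out
}

#' Nearest-neighbor identity within a V/J/length group
#'
#' For each clonotype in a group, the highest percent identity to any other
#' member of the same group (self-comparison excluded). Singleton groups have
#' no neighbors and yield an empty result.
#'
#' @param seqs Character vector of equal-length CDR3 nt sequences (one
#'   group's members; must be distinct clonotypes).
#' @return Named numeric vector mapping each sequence to its best identity;
#'   empty for singleton groups.
#' @export
nearest_neighbor <- function(seqs) {
  if (length(seqs) < 2) return(stats::setNames(numeric(0), character(0)))
  idm <- pairwise_identity(seqs)
  diag(idm) <- -Inf
  stats::setNames(apply(idm, 1L, max), seqs)
}

#' Nearest-neighbor similarity distribution
#'
#' Histogram of clonotype counts over CDR3 nucleotide length and
#' nearest-neighbor identity bins. On real repertoires this 2D distribution
#' shows two hot spots — somatic mutants at >= 95% identity and unrelated
#' background sequences around 55-90% — and motivates the 95% lineage
#' cut-off. Identity bins are `bin_width`%-wide left-closed intervals; the
#' top bin is closed at 100 so exact matches fall in `[100 - bin_width,
#' 100]`. Lengths are exact nucleotide lengths. Only clonotypes with at
#' least one same-group companion contribute.
#'
#' @param clones Clone table (collapsed internally via [group_by_vjl()]).
#' @param bin_width Identity bin width in percent (default 1).
#' @return Tibble with `cdr3_length`, `identity_bin` (lower edge) and `n`.
#' @export
nn_distribution <- function(clones, bin_width = 1) {
  groups <- group_by_vjl(clones)
  if (nrow(groups) == 0) {
    return(tibble::tibble(cdr3_length = integer(), identity_bin = numeric(),
                          n = integer()))
  }
  parts <- split(groups, groups$vjl)
  rows <- lapply(parts, function(g) {
    nn <- nearest_neighbor(g$cdr3_nt)
    if (length(nn) == 0) return(NULL)
    bin <- pmin(floor((nn + IDENTITY_TOL) / bin_width) * bin_width,
                100 - bin_width)
    tibble::tibble(cdr3_length = g$cdr3_length[1], identity_bin = bin)
  })
  dplyr::bind_rows(rows) |>
    dplyr::count(.data$cdr3_length, .data$identity_bin, name = "n") |>
    dplyr::arrange(.data$cdr3_length, .data$identity_bin)
}

#' Build clonal-lineage networks by CDR3 identity clustering
#'
#' Treats each unique CDR3 nucleotide clonotype as a node and draws an edge
#' between two nodes when they share V gene, J gene and CDR3 length and
#' their percent nucleotide identity is at or above `threshold_pct`
#' (inclusive; a pair at exactly 95.0% is linked). Clonal lineages are the
#' connected components with at least `min_nodes` members — membership is by
#' single-linkage transitivity, so two nodes of one lineage need not
#' themselves be within the threshold.
#'
#' @param clones Clone table; collapsed to clonotypes via [group_by_vjl()].
#' @param threshold_pct Identity threshold in percent (default 95).
#' @param min_nodes Minimum component size counted as a lineage (default 2).
#' @return An object of class `lineage_network`: list with `nodes` (tibble:
#'   `node_id`, `v_gene`, `j_gene`, `cdr3_nt`, `cdr3_length`, `count`,
#'   `vjl`, `degree`, `component`, `lineage_id` — `NA` for nodes outside any
#'   lineage), `edges` (tibble: `from`, `to`, `identity_pct`),
#'   `threshold_pct`, `min_nodes` and `n_lineages`. Lineage ids are assigned
#'   in decreasing size order (ties by smallest node id).
#' @examples
#' tab <- tibble::tibble(
#'   v_gene = "V1", j_gene = "J1",
#'   cdr3_nt = c("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGA",
#'               "TTTTGGGGCCCCAAAATTTT"),
#'   cdr3_aa = c("TYVR", "TYVR", "FGPK"), count = 1L)
#' net <- build_lineages(tab)
#' net$n_lineages
#' @export
build_lineages <- function(clones, threshold_pct = 95, min_nodes = 2L) {
  nodes <- group_by_vjl(clones)
  nodes$node_id <- seq_len(nrow(nodes))
  edge_list <- list()
  for (g in split(nodes, nodes$vjl)) {
    if (nrow(g) < 2) next
    idm <- pairwise_identity(g$cdr3_nt)
    pairs <- which(upper.tri(idm) & idm >= threshold_pct - IDENTITY_TOL,
                   arr.ind = TRUE)
    if (nrow(pairs) == 0) next
    edge_list[[g$vjl[1]]] <- tibble::tibble(
      from = g$node_id[pairs[, 1]],
      to = g$node_id[pairs[, 2]],
      identity_pct = idm[pairs]
    )
  }
  edges <- if (length(edge_list)) dplyr::bind_rows(edge_list) else
    tibble::tibble(from = integer(), to = integer(), identity_pct = numeric())

  gr <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  if (nrow(edges) > 0) {
    gr <- igraph::add_edges(gr, rbind(edges$from, edges$to))
  }
  comp <- igraph::components(gr)
  nodes$degree <- igraph::degree(gr)
  nodes$component <- comp$membership

  sizes <- comp$csize
  lineage_comps <- which(sizes >= min_nodes)
  # order lineages by decreasing size, ties by first member node id
  if (length(lineage_comps) > 0) {
    first_node <- vapply(lineage_comps,
                         function(cc) min(which(comp$membership == cc)),
                         integer(1))
    ord <- order(-sizes[lineage_comps], first_node)
    lid <- stats::setNames(seq_along(lineage_comps),
                           lineage_comps[ord])
    nodes$lineage_id <- lid[as.character(nodes$component)]
  } else {
    nodes$lineage_id <- NA_integer_
  }

  structure(
    list(nodes = nodes, edges = edges, threshold_pct = threshold_pct,
         min_nodes = as.integer(min_nodes),
         n_lineages = length(lineage_comps)),
    class = "lineage_network"
  )
}

#' @export
print.lineage_network <- function(x, ...) {
  cat(sprintf(
    "Clonal lineage network: %d clonotypes, %d edges (>= %g%% identity), %d lineages (>= %d nodes)\n",
    nrow(x$nodes), nrow(x$edges), x$threshold_pct, x$n_lineages, x$min_nodes))
  invisible(x)
}

#' Proportion of mutated clonotypes
#'
#' Percentage of clonotypes that belong to any clonal lineage — i.e. that
#' have at least one somatic-mutation counterpart in the repertoire snapshot.
#'
#' @param net A [build_lineages()] network.
#' @param total_clonotypes Denominator; defaults to all nodes in the network.
#' @return Percentage in `[0, 100]`.
#' @export
mutated_ratio <- function(net, total_clonotypes = nrow(net$nodes)) {
  stopifnot(inherits(net, "lineage_network"))
  if (total_clonotypes < 1) abort("`total_clonotypes` must be >= 1")
  100 * sum(!is.na(net$nodes$lineage_id)) / total_clonotypes
}

#' Degree statistics of a lineage network
#'
#' The degree of a clonotype is its number of within-threshold partners
#' (edges), i.e. its direct somatic-mutation counterparts. Returns the degree
#' distribution over lineage members only, with degrees at or above `cap`
#' pooled into one class, plus the maximal degree over all nodes in the
#' sample.
#'
#' @param net A [build_lineages()] network.
#' @param cap Degrees `>= cap` are pooled (default 8).
#' @return List with `degree_dist` (tibble: `degree` — `"1"`..`"7"`, `">=8"`
#'   for the default cap — and `ratio`, summing to 1 when lineages exist)
#'   and `max_degree` (0 when the network has no edges).
#' @export
degree_stats <- function(net, cap = 8L) {
  stopifnot(inherits(net, "lineage_network"))
  cap <- as.integer(cap)
  in_lineage <- !is.na(net$nodes$lineage_id)
  max_degree <- if (nrow(net$nodes) > 0) max(net$nodes$degree) else 0L
  if (!any(in_lineage)) {
    return(list(degree_dist = tibble::tibble(degree = character(),
                                             ratio = numeric()),
                max_degree = 0L))
  }
  d <- net$nodes$degree[in_lineage]
  labels <- c(as.character(seq_len(cap - 1L)), paste0(">=", cap))
  binned <- ifelse(d >= cap, paste0(">=", cap), as.character(d))
  tab <- table(factor(binned, levels = labels))
  list(
    degree_dist = tibble::tibble(degree = labels,
                                 ratio = as.numeric(tab) / sum(tab)),
    max_degree = as.integer(max_degree)
  )
}
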