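#' Clonotype abundance profile of a clone subset
#'
#' Collapses a clone table to a named abundance vector over unique
#' clonotypes. The clonotype key is the CDR3 amino-acid sequence (`"aa"`,
#' the default used for similarity and diversity statistics), the CDR3
#' nucleotide sequence (`"nt"`), or the nucleotide sequence with its V and J
#' context (`"nt_vj"`, the key used for lineage trace-back). Abundances are
#' summed clone counts by default; `weight = "unique"` counts each clone row
#' once.
#'
#' @param clones Clone table with `cdr3_aa`/`cdr3_nt` (and `v_gene`,
#'   `j_gene` for `"nt_vj"`) plus a `count` column.
#' @param level Clonotype definition: `"aa"`, `"nt"` or `"nt_vj"`.
#' @param weight `"count"` (summed clone abundance) or `"unique"` (one per
#'   clone row).
#' @return Named numeric vector of clonotype abundances.
#' @examples
#' tab <- tibble::tibble(cdr3_aa = c("CARW", "CARW", "CASSW"),
#'                       cdr3_nt = c("TGTGCAAGATGG", "TGTGCAAGATGG",
#'                                   "TGTGCAAGTAGTTGG"),
#'                       count = c(2L, 1L, 4L))
#' clonotype_profile(tab)
#' @export
clonotype_profile <- function(clones, level = c("aa", "nt", "nt_vj"),
                              weight = c("count", "unique")) {
  level <- match.arg(level)
  weight <- match.arg(weight)
  stopifnot(is.data.frame(clones))
  if (nrow(clones) == 0) abort("empty clone table: no clonotypes to profile")
  key <- switch(level,
    aa = clones$cdr3_aa,
    nt = clones$cdr3_nt,
    nt_vj = paste(clones$v_gene, clones$j_gene, clones$cdr3_nt, sep = "|")
  )
  w <- if (weight == "count" && "count" %in% names(clones)) {
    as.numeric(clones$count)
  } else {
    rep(1, nrow(clones))
  }
  out <- tapply(w, key, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' V/D/J gene-usage profile
#'
#' Computes, for each segment class (V, D, J), the frequency of every gene in
#' a clone subset. Frequencies are abundance-weighted by clone counts (each
#' clone contributes its `count`); set `weighted = FALSE` to weight every
#' clone row equally. Clones whose CDR3 contains no identifiable D segment
#' are tallied under the explicit gene name `"D-empty"` so that D-segment
#' frequencies still sum to one.
#'
#' @param clones Clone table with `v_gene`, `d_gene`, `j_gene` and `count`.
#' @param weighted Weight genes by clone abundance (default) or count each
#'   clone row once.
#' @return A tibble with columns `segment` (`"V"`, `"D"`, `"J"`), `gene` and
#'   `freq`; frequencies sum to 1 within each segment class.
#' @export
gene_usage <- function(clones, weighted = TRUE) {
  stopifnot(is.data.frame(clones))
  if (nrow(clones) == 0) abort("empty clone table: no gene usage to compute")
  need <- c("v_gene", "d_gene", "j_gene")
  if (!all(need %in% names(clones))) {
    abort("`clones` must have v_gene, d_gene and j_gene columns")
  }
  w <- if (weighted && "count" %in% names(clones)) {
    as.numeric(clones$count)
  } else {
    rep(1, nrow(clones))
  }
  d <- as.character(clones$d_gene)
  d[is.na(d) | !nzchar(d)] <- "D-empty"
  one_segment <- function(genes, seg) {
    f <- tapply(w, genes, sum)
    tibble::tibble(segment = seg, gene = names(f),
                   freq = as.numeric(f) / sum(w))
  }
  dplyr::bind_rows(
    one_segment(as.character(clones$v_gene), "V"),
    one_segment(d, "D"),
    one_segment(as.character(clones$j_gene), "J")
  )
}

#' Pearson correlation of pooled V/D/J gene usage
#'
#' Expresses both profiles over the union of gene names within each segment
#' class (absent genes get frequency 0), concatenates the V, D (including
#' `"D-empty"`) and J frequency vectors, and returns their Pearson
#' product-moment correlation. This pooled index summarizes how consistently
#' two repertoires use the germline gene segments.
#'
#' @param a,b Gene-usage tibbles from [gene_usage()].
#' @return Pearson correlation in `[-1, 1]`.
#' @export
gene_usage_correlation <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b))
  m <- dplyr::full_join(a, b, by = c("segment", "gene"),
                        suffix = c("_a", "_b"))
  m$freq_a[is.na(m$freq_a)] <- 0
  m$freq_b[is.na(m$freq_b)] <- 0
  if (stats::sd(m$freq_a) == 0 || stats::sd(m$freq_b) == 0) {
    abort("degenerate gene-usage profile: zero variance in pooled frequencies")
  }
  stats::cor(m$freq_a, m$freq_b, method = "pearson")
}

#' Morisita-Horn similarity index
#'
#' Abundance-weighted overlap of two clonotype profiles. With frequencies
#' \eqn{p_i} and \eqn{q_i} of clonotype \eqn{i} in each repertoire (over the
#' union of clonotypes),
#' \deqn{MHSI = \frac{2 \sum_i p_i q_i}{\sum_i p_i^2 + \sum_i q_i^2}.}
#' The index is 1 for identical frequency profiles, 0 for disjoint
#' repertoires, symmetric, and invariant to uniform scaling of either
#' abundance vector.
#'
#' @param a,b Named abundance vectors (see [clonotype_profile()]); names
#'   identify clonotypes, values are nonnegative abundances or frequencies.
#' @return Similarity in `[0, 1]`.
#' @examples
#' mhsi(c(x = 2, y = 1), c(x = 1, y = 1))  # 18/19
#' @export
mhsi <- function(a, b) {
  for (v in list(a, b)) {
    if (length(v) == 0 || is.null(names(v)) || sum(v) <= 0) {
      abort("profiles must be nonempty named abundance vectors with positive mass")
    }
  }
  keys <- union(names(a), names(b))
  pa <- stats::setNames(numeric(length(keys)), keys)
  pb <- pa
  pa[names(a)] <- a / sum(a)
  pb[names(b)] <- b / sum(b)
  2 * sum(pa * pb) / (sum(pa^2) + sum(pb^2))
}

#' Normalized Shannon diversity entropy
#'
#' Evenness of a clonotype frequency distribution: Shannon entropy divided by
#' its maximum \eqn{\ln N}, where \eqn{N} is the number of clonotypes,
#' \deqn{NSDE = -\sum_{i=1}^{N} \frac{p_i \ln p_i}{\ln N}.}
#' The index is 1 for a perfectly even repertoire and decreases as single
#' clonotypes dominate. A single-clonotype profile has no evenness and is
#' defined as 0 (with a warning), since \eqn{\ln 1 = 0}.
#'
#' @param x Abundance vector (names optional).
#' @return Evenness in `[0, 1]`.
#' @examples
#' nsde(c(3, 1))  # 0.8113
#' @export
nsde <- function(x) {
  if (!is_count_vector(x)) abort("`x` must be a vector of positive abundances")
  n <- length(x)
  if (n == 1L) {
    warn("single-clonotype profile: evenness defined as 0")
    return(0)
  }
  p <- x / sum(x)
  -sum(p * log(p)) / log(n)
}

#' Chao1 richness estimator
#'
#' Nonparametric lower-bound estimate of clonotype richness from singleton
#' and doubleton counts: with \eqn{S_{obs}} observed clonotypes, \eqn{f_1}
#' singletons and \eqn{f_2} doubletons,
#' \deqn{\hat S = S_{obs} + f_1^2 / (2 f_2)}
#' when \eqn{f_2 > 0}, and the bias-corrected form
#' \eqn{S_{obs} + f_1 (f_1 - 1) / 2} when \eqn{f_2 = 0}. Always at least
#' \eqn{S_{obs}}.
#'
#' @param x Abundance vector of clonotype counts.
#' @return Estimated richness (numeric scalar).
#' @examples
#' chao1(c(A = 1, B = 1, C = 2))  # 5
#' chao1(c(A = 1, B = 1, C = 3))  # 4 (bias-corrected branch)
#' @export
chao1 <- function(x) {
  if (!is_count_vector(x)) abort("`x` must be a vector of positive abundances")
  s_obs <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / 2
  }
}

# Classical variance of the Chao1 estimator (used to scale the uncertainty
# band of extrapolated rarefaction points).
chao1_variance <- function(x) {
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f1 == 0) return(0)
  if (f2 > 0) {
    r <- f1 / f2
    f2 * (r^2 / 2 + r^3 + r^4 / 4)
  } else {
    est <- chao1(x)
    f1 * (f1 - 1) / 2 + f1 * (2 * f1 - 1)^2 / 4 - f1^4 / (4 * est)
  }
}

#' Sequencing coverage of estimated richness
#'
#' Percentage of the Chao1-estimated clonotype richness that was actually
#' observed: `100 * S_obs / chao1(x)`. Values near 100 indicate the
#' sequencing depth nearly exhausted the estimated repertoire.
#'
#' @param x Abundance vector of clonotype counts.
#' @return Coverage percentage in `(0, 100]`.
#' @export
coverage_pct <- function(x) {
  100 * length(x) / chao1(x)
}
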