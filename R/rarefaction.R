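#' Rarefaction and extrapolation of clonotype richness
#'
#' Builds the clonotype-accumulation curve of one repertoire. The
#' interpolated part subsamples the clone pool without replacement at every
#' `increment_pct`% of the total clone count (100 bootstrap replications by
#' default) and records the mean and SEM of the number of distinct clonotypes
#' recovered; `method = "analytic"` instead evaluates the exact
#' hypergeometric expectation (no SEM). The extrapolated part extends the
#' curve up to `extrap_factor` times the observed clone count with the
#' Chao1-based species-accumulation form
#' \deqn{S(n + m) = S_{obs} + \hat f_0 \left[1 - \left(1 -
#'   \frac{f_1}{n \hat f_0 + f_1}\right)^{m}\right],}
#' where \eqn{\hat f_0 = \hat S_{chao} - S_{obs}}. The uncertainty band on
#' extrapolated points scales the analytic Chao1 standard error by the
#' fraction of unseen richness each point has accrued, so it is 0 at the
#' observed endpoint and reaches the full Chao1 SE at the asymptote.
#'
#' @param x Abundance vector of clonotype counts (see
#'   [clonotype_profile()]), or a clone table from which the amino-acid
#'   profile is taken.
#' @param increment_pct Interpolation step as a percentage of the total clone
#'   count (default 1).
#' @param reps Bootstrap replications per interpolation point (default 100).
#' @param extrap_factor Extrapolation endpoint as a multiple of the observed
#'   clone count (default 5).
#' @param seed Optional integer seed making the bootstrap reproducible.
#' @param method `"bootstrap"` (default) or `"analytic"` interior
#'   interpolation.
#' @return An object of class `ighrep_rarefaction`: a list with `curve` (a
#'   tibble of `fraction` — percent of observed clones —, `m` clones drawn,
#'   `clonotypes`, `sem`, `phase` in `{"interpolated", "extrapolated"}`),
#'   `s_obs`, `s_chao`, `coverage_pct` and `n_clones`.
#' @examples
#' prof <- c(table(sample(letters, 200, replace = TRUE)))
#' rc <- rarefaction_curve(prof, reps = 10, seed = 1)
#' rc$coverage_pct
#' @export
rarefaction_curve <- function(x, increment_pct = 1, reps = 100,
                              extrap_factor = 5, seed = NULL,
                              method = c("bootstrap", "analytic")) {
  method <- match.arg(method)
  if (is.data.frame(x)) x <- clonotype_profile(x)
  if (!is_count_vector(x)) abort("`x` must be a vector of positive abundances")
  x <- as.numeric(round(x))
  n <- sum(x)
  s_obs <- length(x)
  step <- floor(n * increment_pct / 100)
  if (step < 1) {
    abort("fewer clones than one increment: decrease `increment_pct` or add data")
  }
  fractions <- seq(increment_pct, 100, by = increment_pct)
  if (fractions[length(fractions)] < 100) fractions <- c(fractions, 100)
  m_interp <- pmin(round(fractions / 100 * n), n)

  if (method == "bootstrap") {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
      set.seed(seed)
    }
    pool <- rep.int(seq_along(x), x)
    draws <- matrix(0, nrow = reps, ncol = length(m_interp))
    for (r in seq_len(reps)) {
      perm <- sample(pool, n, replace = FALSE)
      # position of each clonotype's first appearance in the permutation:
      # the number of distinct clonotypes among the first m clones is the
      # count of first appearances at or before m
      first <- sort(match(seq_along(x), perm))
      draws[r, ] <- findInterval(m_interp, first)
    }
    means <- colMeans(draws)
    sems <- apply(draws, 2, stats::sd) / sqrt(reps)
    # the full sample is deterministic
    means[m_interp == n] <- s_obs
    sems[m_interp == n] <- 0
  } else {
    means <- vapply(m_interp, function(m) {
      # exact expected richness of a without-replacement subsample of size m
      s_obs - sum(exp(lchoose(n - x, m) - lchoose(n, m)))
    }, numeric(1))
    sems <- rep(NA_real_, length(m_interp))
  }
  interp <- tibble::tibble(fraction = fractions, m = m_interp,
                           clonotypes = means, sem = sems,
                           phase = "interpolated")

  s_chao <- chao1(x)
  f0 <- s_chao - s_obs
  f1 <- sum(x == 1)
  m_extra <- setdiff(
    pmin(round(seq(100 + increment_pct, 100 * extrap_factor,
                   by = increment_pct) / 100 * n),
         round(extrap_factor * n)),
    integer(0)
  )
  extrap <- if (length(m_extra) > 0 && extrap_factor > 1) {
    mstar <- m_extra - n
    est <- if (f0 > 0 && f1 > 0) {
      s_obs + f0 * (1 - (1 - f1 / (n * f0 + f1))^mstar)
    } else {
      rep(s_obs, length(mstar))
    }
    chao_se <- sqrt(chao1_variance(x))
    sem_ex <- if (f0 > 0) chao_se * (est - s_obs) / f0 else rep(0, length(est))
    tibble::tibble(fraction = 100 * m_extra / n, m = m_extra,
                   clonotypes = est, sem = sem_ex, phase = "extrapolated")
  } else {
    tibble::tibble(fraction = numeric(), m = integer(),
                   clonotypes = numeric(), sem = numeric(),
                   phase = character())
  }

  structure(
    list(curve = dplyr::bind_rows(interp, extrap),
         s_obs = s_obs, s_chao = s_chao,
         coverage_pct = 100 * s_obs / s_chao, n_clones = n),
    class = "ighrep_rarefaction"
  )
}

#' @export
print.ighrep_rarefaction <- function(x, ...) {
  cat("Clonotype rarefaction curve\n")
  cat(sprintf("  clones: %d   observed clonotypes: %d\n", x$n_clones, x$s_obs))
  cat(sprintf("  Chao1 richness: %.1f   coverage: %.2f%%\n",
              x$s_chao, x$coverage_pct))
  cat(sprintf("  %d interpolated + %d extrapolated points\n",
              sum(x$curve$phase == "interpolated"),
              sum(x$curve$phase == "extrapolated")))
  invisible(x)
}
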