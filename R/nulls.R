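#' Shared-timepoint simulation null for correlated difference scores
#'
#' Acute (3-month minus pre-lesion) and chronic (12-month minus 3-month)
#' changes share the middle scan, so they are negatively correlated by
#' construction (analytically -0.5 for iid equal-variance measurements).
#' This null reproduces that artifact: per simulation, three independent
#' standard-normal pseudo-timepoint vectors of length `n_regions` are drawn,
#' pseudo-acute and pseudo-chronic changes formed, chronic regressed on acute
#' (with intercept), and the slope's t statistic recorded. An observed
#' acute-chronic t statistic is then compared against this distribution with
#' [null_pvalue()].
#'
#' @param n_regions Number of regions per pseudo-timepoint (default 78).
#' @param n_sims Number of simulations (default 1000).
#' @param seed Integer seed; the distribution is reproducible from it.
#' @param tail_alpha Per-tail significance mass (default 0.025).
#' @return A `null_dist` object; `tidy()` gives one row per simulation
#'   (`sim`, `r`, `t`), `glance()` the tail thresholds.
#' @export
shared_timepoint_null <- function(n_regions = 78L, n_sims = 1000L, seed = 1L,
                                  tail_alpha = 0.025) {
  if (n_regions < 3) abort("n_regions must be at least 3")
  local_seed(seed, {
    r <- numeric(n_sims)
    for (s in seq_len(n_sims)) {
      t0 <- rnorm(n_regions)
      t3 <- rnorm(n_regions)
      t12 <- rnorm(n_regions)
      r[s] <- cor(t3 - t0, t12 - t3)
    }
    tt <- r * sqrt((n_regions - 2) / (1 - r^2))
    out <- list(statistics = tibble(sim = seq_len(n_sims), r = r, t = tt),
                n_sims = n_sims, n_regions = n_regions, seed = seed,
                tail_alpha = tail_alpha)
    class(out) <- "null_dist"
    out
  })
}

#' @export
tidy.null_dist <- function(x, ...) x$statistics

#' @export
glance.null_dist <- function(x, ...) {
  tibble(n_sims = x$n_sims, n_regions = x$n_regions,
         mean_r = mean(x$statistics$r),
         t_lower = unname(quantile(x$statistics$t, x$tail_alpha)),
         t_upper = unname(quantile(x$statistics$t, 1 - x$tail_alpha)))
}

#' @export
print.null_dist <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<null_dist> %d sims, %d regions; mean r = %.3f; t thresholds [%.2f, %.2f]\n",
    x$n_sims, x$n_regions, g$mean_r, g$t_lower, g$t_upper))
  invisible(x)
}

#' Empirical two-tailed p-value against a simulation null
#'
#' Rank-based p with a +1 correction so that finite simulation never yields
#' p = 0: `p = 2 * min(#\{T <= t\} + 1, #\{T >= t\} + 1) / (n_sims + 1)`,
#' capped at 1. The observation is flagged significant when it falls within
#' the top or bottom `tail_alpha` of the simulated values.
#'
#' @param observed_t Observed statistic.
#' @param null A `null_dist` (or numeric vector of simulated statistics).
#' @param tail_alpha Per-tail mass; defaults to the null's own setting
#'   (0.025 for a plain vector).
#' @return Tibble with columns `observed`, `p`, `significant`.
#' @export
null_pvalue <- function(observed_t, null, tail_alpha = NULL) {
  sims <- if (inherits(null, "null_dist")) null$statistics$t else as.numeric(null)
  if (!length(sims)) abort("empty null distribution")
  if (is.null(tail_alpha)) {
    tail_alpha <- if (inherits(null, "null_dist")) null$tail_alpha else 0.025
  }
  n <- length(sims)
  lo <- sum(sims <= observed_t)
  hi <- sum(sims >= observed_t)
  p <- min(1, 2 * (min(lo, hi) + 1) / (n + 1))
  significant <- min(lo, hi) / n <= tail_alpha
  tibble(observed = observed_t, p = p, significant = significant)
}

#' Permutation test for regression-coefficient differences between datasets
#'
#' Tests, per predictor, whether the stepwise-regression beta obtained on a
#' subset dataset differs from the full-dataset beta by more than chance.
#' Under the null the two datasets are exchangeable, so on each permutation
#' every region's dependent value is drawn independently from the full or the
#' subset dataset (probability 1/2 each), the stepwise regression is rerun in
#' full on the mixed data, and the difference of its betas from the
#' full-data reference betas is recorded (unselected predictors contribute
#' beta 0). The observed subset-minus-full beta differences are compared
#' two-tailed against this permutation distribution; a predictor is flagged
#' significant when its observed difference falls outside the middle
#' `1 - 2 * tail_alpha` of the permuted differences.
#'
#' @param dv_full,dv_subset Stage changes (or region/value tibbles) over the
#'   same regions, from the full and subset datasets.
#' @param predictors Tibble with `region` plus candidate predictor columns.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param p_enter,p_remove Stepwise thresholds (defaults 0.05 / 0.10).
#' @param tail_alpha Per-tail mass (default 0.025).
#' @return Tibble with one row per predictor: `term`, `beta_full`,
#'   `beta_subset`, `diff`, `p`, `significant`.
#' @export
beta_difference_test <- function(dv_full, dv_subset, predictors,
                                 n_perm = 10000L, seed = 1L,
                                 p_enter = 0.05, p_remove = 0.10,
                                 tail_alpha = 0.025) {
  yf <- as_region_values(dv_full, "dv_full")
  ys <- as_region_values(dv_subset, "dv_subset")
  check_matched_regions(yf, ys, c("dv_full", "dv_subset"))
  stopifnot(is.data.frame(predictors), "region" %in% names(predictors))
  if (!identical(predictors$region, names(yf))) {
    abort("`predictors` and `dv_full` must cover the same regions in the same order")
  }
  terms <- setdiff(names(predictors), "region")
  Xz <- scale(as.matrix(predictors[, terms, drop = FALSE]))
  n <- length(yf)
  fit_betas <- function(y) {
    sel <- stepwise_core(Xz, y, p_enter, p_remove)
    b <- numeric(length(terms))
    if (length(sel)) {
      b[sel] <- ols_fit(Xz[, sel, drop = FALSE], y)$beta[-1]
    }
    b
  }
  beta_full <- fit_betas(yf)
  beta_sub <- fit_betas(ys)
  obs <- beta_sub - beta_full
  local_seed(seed, {
    diffs <- matrix(0, n_perm, length(terms))
    for (b in seq_len(n_perm)) {
      take_sub <- runif(n) < 0.5
      y <- ifelse(take_sub, ys, yf)
      diffs[b, ] <- fit_betas(y) - beta_full
    }
    p <- vapply(seq_along(terms), function(j) {
      lo <- sum(diffs[, j] <= obs[j])
      hi <- sum(diffs[, j] >= obs[j])
      min(1, 2 * (min(lo, hi) + 1) / (n_perm + 1))
    }, numeric(1))
    sig <- vapply(seq_along(terms), function(j) {
      min(sum(diffs[, j] <= obs[j]), sum(diffs[, j] >= obs[j])) / n_perm <=
        tail_alpha
    }, logical(1))
    tibble(term = terms, beta_full = beta_full, beta_subset = beta_sub,
           diff = obs, p = p, significant = sig)
  })
}
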