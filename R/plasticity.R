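stage_levels <- c("acute", "chronic", "chronic_residual")
metric_levels <- c("participation", "within_module_fc", "grey_matter_logjac")

#' Stage change of a per-region metric
#'
#' Elementwise later-minus-earlier difference of a metric between two
#' timepoints: acute is pre-lesion to 3 months, chronic is 3 to 12 months.
#'
#' @param metric_later,metric_earlier Region/value tibbles or named numerics
#'   over the same regions.
#' @param stage One of `"acute"`, `"chronic"`, `"chronic_residual"`.
#' @param metric One of `"participation"`, `"within_module_fc"`,
#'   `"grey_matter_logjac"`.
#' @return A `stage_change` tibble with columns `region`, `delta` and the
#'   stage/metric labels as attributes.
#' @export
stage_change <- function(metric_later, metric_earlier,
                         stage = stage_levels, metric = metric_levels) {
  stage <- match.arg(stage)
  metric <- match.arg(metric)
  later <- as_region_values(metric_later, "metric_later")
  earlier <- as_region_values(metric_earlier, "metric_earlier")
  check_matched_regions(later, earlier, c("metric_later", "metric_earlier"))
  out <- tibble(region = names(later), delta = unname(later - earlier))
  attr(out, "stage") <- stage
  attr(out, "metric") <- metric
  class(out) <- c("stage_change", class(tibble()))
  out
}

#' Residualise chronic changes on acute changes
#'
#' The acute and chronic differences share the middle (3-month) scan, so they
#' are not independent. The chronic changes are regressed on the acute
#' changes (ordinary least squares with intercept) and the residuals are
#' taken as the chronic changes independent of the acute stage.
#'
#' @param chronic,acute `stage_change` objects (or region/delta tibbles) over
#'   the same regions; `acute` must not be constant.
#' @return A `stage_change` with `stage = "chronic_residual"`, same metric
#'   label as `chronic`.
#' @export
residualize_chronic <- function(chronic, acute) {
  y <- as_region_values(chronic, "chronic")
  x <- as_region_values(acute, "acute")
  check_matched_regions(y, x, c("chronic", "acute"))
  if (sd(x) == 0) abort("acute changes are constant; cannot residualise")
  fit <- lm(y ~ x)
  out <- tibble(region = names(y), delta = unname(resid(fit)))
  attr(out, "stage") <- "chronic_residual"
  attr(out, "metric") <- attr(chronic, "metric") %||% metric_levels[1]
  class(out) <- c("stage_change", class(tibble()))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- fast OLS machinery (no lm in hot loops) --------------------------------

# Coefficient t-statistics and p-values for y ~ 1 + X. Returns NULL if the
# design is rank-deficient.
ols_fit <- function(X, y) {
  n <- length(y)
  Xi <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xi)
  XtX <- crossprod(Xi)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  beta <- backsolve(R, forwardsolve(t(R), crossprod(Xi, y)))
  res <- y - Xi %*% beta
  rss <- sum(res^2)
  df <- n - p
  XtXinv <- chol2inv(R)
  se <- sqrt(pmax(diag(XtXinv), 0) * rss / df)
  tt <- drop(beta) / se
  list(beta = drop(beta), se = se, t = tt,
       p = 2 * pt(abs(tt), df, lower.tail = FALSE),
       rss = rss, df = df)
}

# Forward-backward stepwise selection by partial-F (equivalently coefficient
# t) p-values. X: candidate matrix (already scaled), y: response. Starts from
# the intercept-only model; each round adds the candidate with the smallest
# entry p-value if below p_enter (ties broken by candidate order), then
# removes included predictors whose p-value exceeds p_remove (worst first)
# until none does; stops when no candidate enters. Returns indices of the
# selected candidates in candidate order.
stepwise_core <- function(X, y, p_enter = 0.05, p_remove = 0.10) {
  ncand <- ncol(X)
  inc <- integer(0)
  repeat {
    out <- setdiff(seq_len(ncand), inc)
    entered <- FALSE
    if (length(out)) {
      pe <- vapply(out, function(j) {
        f <- ols_fit(X[, c(inc, j), drop = FALSE], y)
        if (is.null(f)) Inf else f$p[length(f$p)]
      }, numeric(1))
      if (min(pe) < p_enter) {
        inc <- c(inc, out[which.min(pe)])
        entered <- TRUE
      }
    }
    repeat {
      if (!length(inc)) break
      f <- ols_fit(X[, inc, drop = FALSE], y)
      pv <- f$p[-1]
      if (max(pv) > p_remove) {
        inc <- inc[-which.max(pv)]
      } else break
    }
    if (!entered) break
  }
  sort(inc)
}

#' Stepwise regression of stage changes on predictors
#'
#' Forward-backward stepwise selection driven by p-value thresholds, starting
#' from the intercept-only model: at each step the candidate with the
#' smallest entry p-value joins if it is below `p_enter`, then any included
#' predictor whose p-value exceeds `p_remove` is dropped (worst first), until
#' a fixed point. Candidate predictors are z-scored before selection so the
#' reported betas are comparable across predictors; the dependent variable is
#' left on its own scale. The final model is refit by OLS; for candidates
#' left out of the final model the reported t and p are add-one-candidate
#' partial statistics relative to the final model.
#'
#' @param predictors Tibble with a `region` column and one numeric column per
#'   candidate predictor (e.g. neuron density, non-neuronal density, hubness,
#'   pre-lesion seed connectivity).
#' @param dv A `stage_change` (or region/value tibble, or named numeric) over
#'   the same regions.
#' @param p_enter Entry threshold (default 0.05). Must be `<= p_remove`.
#' @param p_remove Removal threshold (default 0.10).
#' @return A `stepwise_fit` object; `tidy()` gives one row per candidate
#'   (`term`, `beta`, `t`, `p`, `selected`), `glance()` the model-level
#'   `F`/`df`/`p`/`r2`/`n`. Unselected candidates carry `beta = 0`.
#' @export
stepwise_regression <- function(predictors, dv, p_enter = 0.05,
                                p_remove = 0.10) {
  if (p_enter > p_remove) abort("p_enter must be <= p_remove")
  stopifnot(is.data.frame(predictors), "region" %in% names(predictors))
  y <- as_region_values(dv, "dv")
  if (!identical(predictors$region, names(y))) {
    abort("`predictors` and `dv` must cover the same regions in the same order")
  }
  terms <- setdiff(names(predictors), "region")
  X <- as.matrix(predictors[, terms, drop = FALSE])
  storage.mode(X) <- "double"
  n <- length(y)
  if (n <= length(terms) + 2) {
    abort("need more regions than candidate predictors + 2")
  }
  if (qr(cbind(1, scale(X)))$rank < ncol(X) + 1) {
    abort(paste0("perfectly collinear candidate set: ",
                 paste(terms, collapse = ", ")))
  }
  Xz <- scale(X)
  sel <- stepwise_core(Xz, y, p_enter, p_remove)
  fit <- ols_fit(Xz[, sel, drop = FALSE], y)
  beta <- setNames(numeric(length(terms)), terms)
  tt <- pp <- setNames(rep(NA_real_, length(terms)), terms)
  if (length(sel)) {
    beta[sel] <- fit$beta[-1]
    tt[sel] <- fit$t[-1]
    pp[sel] <- fit$p[-1]
  }
  for (j in setdiff(seq_along(terms), sel)) {
    f <- ols_fit(Xz[, c(sel, j), drop = FALSE], y)
    tt[j] <- f$t[length(f$t)]
    pp[j] <- f$p[length(f$p)]
  }
  # model-level statistics of the final fit
  tss <- sum((y - mean(y))^2)
  r2 <- if (length(sel)) 1 - fit$rss / tss else 0
  df1 <- length(sel)
  df2 <- n - df1 - 1
  Fstat <- if (df1 > 0) (r2 / df1) / ((1 - r2) / df2) else NA_real_
  p_model <- if (df1 > 0) pf(Fstat, df1, df2, lower.tail = FALSE) else NA_real_
  out <- list(
    selected = terms[sel],
    coefficients = tibble(term = terms, beta = unname(beta), t = unname(tt),
                          p = unname(pp),
                          selected = seq_along(terms) %in% sel),
    F = Fstat, df = c(df1, df2), p_model = p_model, r2 = r2, n = n,
    p_enter = p_enter, p_remove = p_remove,
    stage = attr(dv, "stage"), metric = attr(dv, "metric")
  )
  class(out) <- "stepwise_fit"
  out
}

#' @export
tidy.stepwise_fit <- function(x, ...) x$coefficients

#' @export
glance.stepwise_fit <- function(x, ...) {
  tibble(F = x$F, df1 = x$df[1], df2 = x$df[2], p = x$p_model,
         r2 = x$r2, n = x$n, n_selected = length(x$selected))
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("<stepwise_fit> F(%d,%d) = %.3f, p = %.3g, r2 = %.3f, n = %d\n",
              x$df[1], x$df[2], x$F, x$p_model, x$r2, x$n))
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  print(x$coefficients)
  invisible(x)
}

#' One-way ANOVA of stage changes across modules
#'
#' Tests whether module membership explains differences in per-region stage
#' changes (module dispersion). Classic one-way ANOVA of `delta` grouped by
#' module label.
#'
#' @param change A `stage_change` (or region/delta tibble).
#' @param partition A [module_partition()] over the same regions.
#' @return Tibble with columns `F`, `df1`, `df2`, `p`.
#' @export
module_dispersion_anova <- function(change, partition) {
  d <- as_region_values(change, "change")
  lab <- partition_labels(partition)
  if (is.data.frame(partition) &&
      !identical(partition$region, names(d))) {
    abort("`change` and `partition` must cover the same regions in the same order")
  }
  if (length(lab) != length(d)) {
    abort("`change` and `partition` must cover the same regions")
  }
  sizes <- table(lab)
  if (any(sizes < 2)) {
    abort(paste0("module(s) with fewer than 2 regions: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  if (length(sizes) < 2) abort("need at least 2 modules")
  a <- anova(lm(d ~ factor(lab)))
  tibble(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
         p = a$`Pr(>F)`[1])
}

#' Map donor-area cell densities onto atlas regions
#'
#' Cell-density measurements published on a finer (or simply different)
#' parcellation are carried onto the analysis atlas through a crosswalk
#' table; when several donor areas map to one target region, their densities
#' are averaged (a simple unweighted mean).
#'
#' @param densities Tibble with columns `area`, `value` (donor parcellation).
#' @param crosswalk Tibble with columns `area`, `region` mapping donor areas
#'   to atlas regions (one row per pair; a region may receive several areas).
#' @return Tibble with columns `region`, `value`; regions absent from the
#'   crosswalk are absent from the output.
#' @export
map_cell_densities <- function(densities, crosswalk) {
  stopifnot(all(c("area", "value") %in% names(densities)),
            all(c("area", "region") %in% names(crosswalk)))
  missing_areas <- setdiff(crosswalk$area, densities$area)
  if (length(missing_areas)) {
    abort(paste0("crosswalk references unknown donor area(s): ",
                 paste(missing_areas, collapse = ", ")))
  }
  crosswalk |>
    left_join(densities, by = "area") |>
    group_by(.data$region) |>
    summarise(value = mean(.data$value), .groups = "drop")
}
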