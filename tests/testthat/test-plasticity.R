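make_regions <- function(n) sprintf("r%02d", seq_len(n))

test_that("stage_change is elementwise later minus earlier", {
  r <- make_regions(6)
  a <- setNames(c(1, 2, 3, 4, 5, 6), r)
  expect_equal(stage_change(a, a, "acute", "participation")$delta, rep(0, 6))
  expect_equal(stage_change(a + 0.3, a, "acute", "participation")$delta,
               rep(0.3, 6))
  b <- setNames(c(0.2, -1, 4, 2.5, 0, 9), r)
  sc <- stage_change(b, a, "chronic", "within_module_fc")
  expect_equal(sc$delta, unname(b - a))
  expect_equal(attr(sc, "stage"), "chronic")
  expect_equal(attr(sc, "metric"), "within_module_fc")
  names(b)[1] <- "zz"
  expect_error(stage_change(b, a), "same regions")
})

test_that("residualize_chronic matches closed-form simple regression", {
  r <- make_regions(10)
  x <- setNames(c(0.5, 1.2, -0.3, 2.0, 0.1, -1.1, 0.8, 1.5, -0.6, 0.3), r)
  # chronic exactly affine in acute -> zero residuals
  y_affine <- 2 * x - 1
  res <- residualize_chronic(
    stage_change(y_affine, setNames(rep(0, 10), r), "chronic", "participation"),
    stage_change(x, setNames(rep(0, 10), r), "acute", "participation"))
  expect_equal(res$delta, rep(0, 10), tolerance = 1e-12)
  expect_equal(attr(res, "stage"), "chronic_residual")

  # mean-centred orthogonal chronic passes through unchanged
  xc <- x - mean(x)
  y_orth <- setNames(rnorm(10), r)
  y_orth <- y_orth - mean(y_orth)
  y_orth <- setNames(y_orth - sum(y_orth * xc) / sum(xc^2) * xc, r)
  res2 <- residualize_chronic(y_orth, x)
  expect_equal(res2$delta, unname(y_orth), tolerance = 1e-10)

  # closed-form OLS oracle on fixed vectors
  y <- setNames(c(1.1, 0.4, -0.2, 2.5, 0.3, -0.9, 1.0, 2.2, -0.1, 0.6), r)
  res3 <- residualize_chronic(y, x)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  expect_equal(res3$delta, unname(y - b0 - b1 * x), tolerance = 1e-12)
  # residual properties
  expect_lt(abs(mean(res3$delta)), 1e-10)
  expect_lt(abs(cor(res3$delta, x)), 1e-10)

  expect_error(residualize_chronic(y, setNames(rep(1, 10), r)), "constant")
})

sim_predictors <- function(n, k = 4) {
  X <- matrix(rnorm(n * k), n, k)
  colnames(X) <- paste0("x", seq_len(k))
  dplyr::bind_cols(tibble::tibble(region = make_regions(n)),
                   tibble::as_tibble(X))
}

test_that("stepwise recovers a noiseless signal exactly", {
  set.seed(101)
  preds <- sim_predictors(40)
  dv <- setNames(2 * preds$x1, preds$region)
  fit <- stepwise_regression(preds, dv)
  expect_equal(fit$selected, "x1")
  # beta on z-scored predictor: 2 * sd(x1)
  expect_equal(tidy(fit)$beta[1], 2 * sd(preds$x1), tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
})

# independent oracle: forward-backward stepwise via lm()/anova partial F
stepwise_lm_oracle <- function(preds, dv, p_enter = 0.05, p_remove = 0.10) {
  terms <- setdiff(names(preds), "region")
  df <- as.data.frame(scale(preds[, terms]))
  df$y <- unname(dv)
  inc <- character(0)
  repeat {
    remaining <- setdiff(terms, inc)
    entered <- FALSE
    if (length(remaining)) {
      pvals <- sapply(remaining, function(tm) {
        f0 <- lm(stats::reformulate(c("1", inc), "y"), data = df)
        f1 <- lm(stats::reformulate(c("1", inc, tm), "y"), data = df)
        anova(f0, f1)$`Pr(>F)`[2]
      })
      if (min(pvals) < p_enter) {
        inc <- c(inc, remaining[which.min(pvals)])
        entered <- TRUE
      }
    }
    repeat {
      if (!length(inc)) break
      fit <- lm(stats::reformulate(c("1", inc), "y"), data = df)
      pv <- summary(fit)$coefficients[-1, 4]
      if (max(pv) > p_remove) inc <- inc[-which.max(pv)] else break
    }
    if (!entered) break
  }
  sort(inc)
}

test_that("stepwise agrees with an lm-based forward-backward oracle", {
  set.seed(103)
  for (rep in 1:20) {
    n <- 78
    preds <- sim_predictors(n)
    beta <- c(0.5, 0, -0.5, 0)
    dv <- setNames(drop(scale(as.matrix(preds[, -1])) %*% beta) +
                     rnorm(n, 0, runif(1, 0.3, 2)), preds$region)
    fit <- stepwise_regression(preds, dv)
    expect_equal(sort(fit$selected), stepwise_lm_oracle(preds, dv))
  }
})

test_that("stepwise reporting matches final-model and add-one statistics", {
  set.seed(107)
  preds <- sim_predictors(78)
  dv <- setNames(drop(scale(as.matrix(preds[, -1])) %*% c(0.6, 0, 0, 0.4)) +
                   rnorm(78, 0, 0.5), preds$region)
  fit <- stepwise_regression(preds, dv)
  td <- tidy(fit)
  df <- as.data.frame(scale(preds[, -1]))
  df$y <- unname(dv)
  final <- lm(stats::reformulate(c("1", fit$selected), "y"), data = df)
  sm <- summary(final)$coefficients
  for (tm in fit$selected) {
    expect_equal(td$beta[td$term == tm], unname(sm[tm, 1]), tolerance = 1e-10)
    expect_equal(td$t[td$term == tm], unname(sm[tm, 3]), tolerance = 1e-10)
  }
  for (tm in setdiff(td$term, fit$selected)) {
    aug <- lm(stats::reformulate(c("1", fit$selected, tm), "y"), data = df)
    expect_equal(td$t[td$term == tm],
                 unname(summary(aug)$coefficients[tm, 3]), tolerance = 1e-10)
    expect_equal(td$beta[td$term == tm], 0)
  }
  gl <- glance(fit)
  expect_equal(gl$F, summary(final)$fstatistic[["value"]], tolerance = 1e-10)
  expect_equal(gl$r2, summary(final)$r.squared, tolerance = 1e-10)
})

test_that("stepwise is invariant to candidate order and rejects collinearity", {
  set.seed(109)
  preds <- sim_predictors(60)
  dv <- setNames(drop(scale(as.matrix(preds[, -1])) %*% c(0.8, -0.6, 0, 0)) +
                   rnorm(60, 0, 0.7), preds$region)
  fit1 <- stepwise_regression(preds, dv)
  preds_rev <- preds[, c("region", rev(paste0("x", 1:4)))]
  fit2 <- stepwise_regression(preds_rev, dv)
  expect_setequal(fit1$selected, fit2$selected)
  b1 <- setNames(tidy(fit1)$beta, tidy(fit1)$term)
  b2 <- setNames(tidy(fit2)$beta, tidy(fit2)$term)
  expect_equal(b1[sort(names(b1))], b2[sort(names(b2))], tolerance = 1e-10)

  bad <- preds
  bad$x4 <- 2 * bad$x1 - bad$x2
  expect_error(stepwise_regression(bad, dv), "collinear")
  expect_error(stepwise_regression(preds, dv, p_enter = 0.2, p_remove = 0.1),
               "p_enter")
})

test_that("final-model R2 is monotone in p_enter on generated cases", {
  set.seed(113)
  for (rep in 1:10) {
    preds <- sim_predictors(78)
    dv <- setNames(drop(scale(as.matrix(preds[, -1])) %*%
                          runif(4, -0.4, 0.4)) + rnorm(78), preds$region)
    r2 <- sapply(c(0.01, 0.05, 0.15, 0.5),
                 function(pe) stepwise_regression(preds, dv, p_enter = pe,
                                                  p_remove = pe)$r2)
    expect_true(all(diff(r2) >= -1e-12))
  }
})

test_that("planted-coefficient confidence intervals cover at nominal rate", {
  set.seed(127)
  n_rep <- 300
  covered <- matrix(NA, n_rep, 2)
  beta_true <- c(0.6, -0.6)
  for (r in seq_len(n_rep)) {
    preds <- sim_predictors(78)
    Xz <- scale(as.matrix(preds[, -1]))
    dv <- setNames(drop(Xz %*% c(beta_true, 0, 0)) + rnorm(78, 0, 0.5),
                   preds$region)
    fit <- stepwise_regression(preds, dv)
    df <- as.data.frame(Xz)
    df$y <- unname(dv)
    if (!all(c("x1", "x2") %in% fit$selected)) next
    final <- lm(stats::reformulate(c("1", fit$selected), "y"), data = df)
    ci <- confint(final)
    covered[r, ] <- c(
      beta_true[1] >= ci["x1", 1] && beta_true[1] <= ci["x1", 2],
      beta_true[2] >= ci["x2", 1] && beta_true[2] <= ci["x2", 2])
  }
  rates <- colMeans(covered, na.rm = TRUE)
  expect_true(all(rates >= 0.95 - 0.04))
})

test_that("module dispersion ANOVA matches a hand-computed oracle", {
  regions <- make_regions(9)
  d <- setNames(c(1.1, 0.9, 1.0, 2.1, 2.0, 2.2, 0.2, 0.1, 0.0), regions)
  lab <- rep(1:3, each = 3)
  res <- module_dispersion_anova(d, lab)
  # textbook one-way ANOVA sums of squares
  grand <- mean(d)
  ssb <- sum(3 * (tapply(d, lab, mean) - grand)^2)
  ssw <- sum((d - tapply(d, lab, mean)[lab])^2)
  F_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(res$F, F_hand, tolerance = 1e-12)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 6)
  expect_equal(res$p, pf(F_hand, 2, 6, lower.tail = FALSE), tolerance = 1e-12)

  # location invariance and within-group exchangeability
  expect_equal(module_dispersion_anova(d + 5, lab)$F, res$F)
  perm <- c(2, 3, 1, 5, 6, 4, 8, 9, 7)   # permute within groups
  expect_equal(module_dispersion_anova(setNames(d[perm], regions), lab)$F,
               res$F)

  expect_error(module_dispersion_anova(d, c(rep(1, 8), 2)), "fewer than 2")
})

test_that("cell-density crosswalk averages donor areas per region", {
  dens <- tibble::tibble(area = c("a1", "a2", "a3"), value = c(10, 20, 60))
  cw <- tibble::tibble(area = c("a1", "a2", "a3"),
                       region = c("R1", "R1", "R2"))
  out <- map_cell_densities(dens, cw)
  expect_equal(out$value[out$region == "R1"], 15)
  expect_equal(out$value[out$region == "R2"], 60)
  cw_bad <- dplyr::bind_rows(cw, tibble::tibble(area = "zz", region = "R3"))
  expect_error(map_cell_densities(dens, cw_bad), "unknown donor")
})
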