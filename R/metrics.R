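#' Node strength
#'
#' Sum of a region's connection weights, diagonal excluded. By default the
#' signed sum over the unthresholded matrix; `weights = "positive"` sums the
#' positive part only.
#'
#' @param W Symmetric numeric matrix (region-named).
#' @param weights `"signed"` (default) or `"positive"`.
#' @return Tibble with columns `region`, `value`.
#' @export
node_strength <- function(W, weights = c("signed", "positive")) {
  weights <- match.arg(weights)
  check_symmetric(W)
  M <- if (weights == "positive") positive_part(W) else {
    M0 <- W; diag(M0) <- 0; M0
  }
  ids <- rownames(W)
  if (is.null(ids)) ids <- paste0("R", seq_len(nrow(W)))
  tibble(region = ids, value = unname(rowSums(M)))
}

#' Participation coefficient
#'
#' How evenly a region's connections are distributed across modules:
#' \deqn{P_i = 1 - \sum_s \left(\frac{\kappa_{is}}{k_i}\right)^2,}
#' where \eqn{\kappa_{is}} is the weight from region i to module s and
#' \eqn{k_i} its total strength, computed on the positive part of the matrix
#' with the diagonal zeroed. A region whose weight falls entirely inside one
#' module scores 0; evenly spread connector hubs approach
#' \eqn{1 - 1/n_{modules}}. Regions with zero positive strength score 0.
#'
#' @param W Symmetric numeric matrix.
#' @param partition A [module_partition()] or integer label vector covering
#'   every region.
#' @return Tibble with columns `region`, `value` (each in `[0, 1]`).
#' @export
participation_coefficient <- function(W, partition) {
  check_symmetric(W)
  lab <- partition_labels(partition, W)
  Wp <- positive_part(W)
  k <- rowSums(Wp)
  # kappa: region x module weight totals
  kappa <- t(rowsum(t(Wp), lab))
  frac <- kappa / ifelse(k == 0, 1, k)
  p <- 1 - rowSums(frac^2)
  p[k == 0] <- 0
  ids <- rownames(W)
  if (is.null(ids)) ids <- paste0("R", seq_len(nrow(W)))
  tibble(region = ids, value = unname(p))
}

#' Within-module functional connectivity
#'
#' Per region, the mean signed weight to the other regions of its own module
#' (self excluded). Regions alone in their module have no within-module
#' neighbours and get `NA`.
#'
#' @inheritParams participation_coefficient
#' @return Tibble with columns `region`, `value`.
#' @export
within_module_connectivity <- function(W, partition) {
  check_symmetric(W)
  lab <- partition_labels(partition, W)
  W0 <- W
  diag(W0) <- 0
  same <- outer(lab, lab, "==")
  diag(same) <- FALSE
  nmate <- rowSums(same)
  v <- ifelse(nmate > 0, rowSums(W0 * same) / pmax(nmate, 1), NA_real_)
  ids <- rownames(W)
  if (is.null(ids)) ids <- paste0("R", seq_len(nrow(W)))
  tibble(region = ids, value = unname(v))
}

#' Hubness: first principal component of strength and participation
#'
#' Both high strength and high participation mark network hubs, and the two
#' are positively correlated in typical connectomes. Hubness is each region's
#' score on the first principal component of the z-scored
#' (regions x 2) strength/participation matrix, obtained from the
#' eigendecomposition of the 2 x 2 correlation matrix. Scores are signed so
#' that hubness correlates positively with strength; the percentage of
#' variance the component explains is reported alongside.
#'
#' @param strength,participation Region/value tibbles (as returned by
#'   [node_strength()] and [participation_coefficient()]) or named numerics
#'   over the same regions. Neither may be constant.
#' @return An object of class `hubness_pca`: use `tidy()` for the per-region
#'   scores and `glance()` for the variance explained.
#' @export
hubness_scores <- function(strength, participation) {
  s <- as_region_values(strength, "strength")
  p <- as_region_values(participation, "participation")
  check_matched_regions(s, p, c("strength", "participation"))
  if (sd(s) == 0 || sd(p) == 0) {
    abort("strength and participation must both be non-constant")
  }
  Z <- cbind(strength = (s - mean(s)) / sd(s),
             participation = (p - mean(p)) / sd(p))
  C <- cor(Z)
  eig <- eigen(C, symmetric = TRUE)
  v1 <- eig$vectors[, 1]
  scores <- drop(Z %*% v1)
  if (cor(scores, s) < 0) {
    scores <- -scores
    v1 <- -v1
  }
  out <- list(
    scores = tibble(region = names(s), hubness = unname(scores)),
    pc1_variance_explained = 100 * eig$values[1] / sum(eig$values),
    loadings = setNames(v1, c("strength", "participation")),
    cor_strength_participation = C[1, 2]
  )
  class(out) <- "hubness_pca"
  out
}

#' @export
tidy.hubness_pca <- function(x, ...) x$scores

#' @export
glance.hubness_pca <- function(x, ...) {
  tibble(pc1_variance_explained = x$pc1_variance_explained,
         cor_strength_participation = x$cor_strength_participation)
}

#' @export
print.hubness_pca <- function(x, ...) {
  cat(sprintf("<hubness_pca> %d regions; PC1 explains %.2f%% of variance\n",
              nrow(x$scores), x$pc1_variance_explained))
  invisible(x)
}

#' All per-region node metrics in one table
#'
#' Convenience wrapper computing strength, participation coefficient,
#' within-module connectivity and hubness against one partition.
#'
#' @inheritParams participation_coefficient
#' @return Tibble with columns `region`, `strength`, `participation`,
#'   `within_module_fc`, `hubness`; the PC1 variance explained is attached as
#'   attribute `"pc1_variance_explained"`.
#' @export
node_metric_table <- function(W, partition) {
  s <- node_strength(W)
  p <- participation_coefficient(W, partition)
  w <- within_module_connectivity(W, partition)
  h <- hubness_scores(s, p)
  out <- tibble(region = s$region, strength = s$value,
                participation = p$value, within_module_fc = w$value,
                hubness = h$scores$hubness)
  attr(out, "pc1_variance_explained") <- h$pc1_variance_explained
  out
}
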