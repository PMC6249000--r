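#' Pearson functional-connectivity matrix from regional timecourses
#'
#' Computes the region-by-region Pearson correlation matrix from a
#' region-by-time matrix of signal values. The matrix is kept continuous,
#' unthresholded and signed; the diagonal is 1.
#'
#' @param tc Numeric matrix, regions in rows (rownames are region ids),
#'   timepoints in columns. At least 3 timepoints; no constant rows.
#' @return Symmetric correlation matrix with unit diagonal, region-named.
#' @examples
#' tc <- rbind(a = sin(1:20), b = cos(1:20), c = sin(1:20) + rnorm(20, 0, .1))
#' compute_fc_matrix(tc)
#' @export
compute_fc_matrix <- function(tc) {
  stopifnot(is.matrix(tc), is.numeric(tc))
  if (is.null(rownames(tc))) rownames(tc) <- paste0("R", seq_len(nrow(tc)))
  if (ncol(tc) < 3) {
    abort(sprintf("need at least 3 timepoints, got %d", ncol(tc)))
  }
  sds <- apply(tc, 1, sd)
  if (any(sds == 0)) {
    abort(paste0("constant (zero-variance) timecourse for region(s): ",
                 paste(rownames(tc)[sds == 0], collapse = ", ")))
  }
  W <- cor(t(tc))
  diag(W) <- 1
  (W + t(W)) / 2
}

#' Average connectivity matrices across subjects
#'
#' Element-wise mean of a list of region-matched connectivity matrices
#' (`method = "raw"`, the default), or the Fisher-z alternative: mean of
#' atanh-transformed off-diagonal weights, back-transformed with tanh
#' (the diagonal is averaged untransformed).
#'
#' @param matrices List of named square matrices with identical region ids.
#' @param method `"raw"` or `"fisher_z"`.
#' @return A single averaged matrix.
#' @export
average_fc_matrices <- function(matrices, method = c("raw", "fisher_z")) {
  method <- match.arg(method)
  if (!is.list(matrices) || length(matrices) == 0) {
    abort("`matrices` must be a non-empty list of matrices")
  }
  ids <- rownames(matrices[[1]])
  ok <- vapply(matrices, function(m) {
    is.matrix(m) && identical(rownames(m), ids) && identical(colnames(m), ids)
  }, logical(1))
  if (!all(ok)) abort("all matrices must share identical region ids")
  if (method == "raw") {
    return(Reduce(`+`, matrices) / length(matrices))
  }
  d <- diag(Reduce(`+`, matrices) / length(matrices))
  Z <- Reduce(`+`, lapply(matrices, atanh)) / length(matrices)
  out <- tanh(Z)
  diag(out) <- d
  dimnames(out) <- dimnames(matrices[[1]])
  out
}

#' Lesioned-region (seed) connectivity profile
#'
#' Extracts the mean of the left- and right-hemisphere seed rows of a full
#' connectivity matrix (one that still contains the excluded regions),
#' restricted to the atlas's network regions. This is the pre-lesion
#' hippocampal connectivity profile when the seed is `"HC"`.
#'
#' @param fc_full Square named matrix over all atlas regions (both
#'   hemispheres of the seed included).
#' @param atlas A `region_atlas`.
#' @param seed_abbrev Abbreviation of the seed region (default `"HC"`).
#' @return Tibble with columns `region`, `value`, one row per network region
#'   in atlas order. Excluded regions (the seed itself and any other
#'   `in_network = FALSE` region) are absent.
#' @export
seed_connectivity_profile <- function(fc_full, atlas, seed_abbrev = "HC") {
  seeds <- paste0(seed_abbrev, c("_L", "_R"))
  missing_rows <- setdiff(seeds, rownames(fc_full))
  if (length(missing_rows)) {
    abort(paste0("seed row(s) absent from matrix: ",
                 paste(missing_rows, collapse = ", ")))
  }
  keep <- intersect(network_regions(atlas), colnames(fc_full))
  if (!identical(keep, network_regions(atlas))) {
    abort("full matrix does not contain every network region of the atlas")
  }
  prof <- colMeans(fc_full[seeds, keep, drop = FALSE])
  tibble(region = keep, value = unname(prof))
}

#' Correlate a connectivity profile with tract-tracing weights
#'
#' Pearson correlation between a functional seed profile and anatomical
#' (tract-tracing) connectivity over matched regions, with the two-tailed p
#' from the t-transform on n - 2 degrees of freedom. Pairs with a missing
#' value in either vector are dropped (pairwise deletion); the number dropped
#' is reported.
#'
#' @param fc_profile,tracing Region/value data frames or named numerics over
#'   the same regions.
#' @return Tibble with columns `r`, `p`, `n_used`, `n_dropped`.
#' @export
correlate_with_tracing <- function(fc_profile, tracing) {
  a <- as_region_values(fc_profile, "fc_profile")
  b <- as_region_values(tracing, "tracing")
  check_matched_regions(a, b, c("fc_profile", "tracing"))
  ok <- !is.na(a) & !is.na(b)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    inform(sprintf("correlate_with_tracing: dropped %d incomplete pair(s)",
                   n_dropped))
  }
  if (sum(ok) < 3) abort("fewer than 3 complete pairs")
  ct <- cor.test(a[ok], b[ok], method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value,
         n_used = sum(ok), n_dropped = n_dropped)
}
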