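#' Read and write connectivity matrices
#'
#' Connectivity matrices are stored as tab-delimited text: the first column
#' and the header row both carry region ids, and the body is the square
#' numeric weight matrix. Matrices are stored unthresholded and signed.
#' On read, near-symmetric input (maximum asymmetry at most `tol`) is
#' symmetrised by averaging with its transpose; larger asymmetry is an error.
#'
#' Writing uses 17 significant digits so that a write/read round trip
#' preserves weights to better than 1e-12.
#'
#' @param path File path.
#' @param atlas Optional `region_atlas`; if supplied, the file's regions must
#'   match the atlas's network regions in order.
#' @param tol Maximum tolerated asymmetry before erroring (default `1e-8`).
#' @return `read_fc_matrix()` returns a named symmetric numeric matrix;
#'   `write_fc_matrix()` returns `path` invisibly.
#' @examples
#' W <- matrix(c(1, .5, .5, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' f <- tempfile(fileext = ".tsv")
#' write_fc_matrix(W, f)
#' all.equal(read_fc_matrix(f), W)
#' @export
read_fc_matrix <- function(path, atlas = NULL, tol = 1e-8) {
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(x[[1]])
  W <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(W)) abort("connectivity matrix contains non-numeric cells")
  rownames(W) <- ids
  if (nrow(W) != ncol(W)) {
    abort(sprintf("connectivity matrix is not square: %d rows, %d columns",
                  nrow(W), ncol(W)))
  }
  if (!identical(ids, colnames(W))) {
    abort("row labels and column labels of the connectivity matrix differ")
  }
  if (!is.null(atlas)) {
    want <- network_regions(atlas)
    if (!identical(ids, want)) {
      abort(sprintf(
        "matrix regions do not match the atlas's %d network regions (in order)",
        length(want)))
    }
  }
  asym <- max(abs(W - t(W)))
  if (asym > tol) {
    abort(sprintf("matrix asymmetry %.3g exceeds tolerance %.3g", asym, tol))
  }
  (W + t(W)) / 2
}

#' @rdname read_fc_matrix
#' @param W A named square numeric matrix.
#' @export
write_fc_matrix <- function(W, path) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  ids <- rownames(W)
  if (is.null(ids)) abort("matrix must have region row/column names")
  lines <- c(
    paste(c("region", ids), collapse = "\t"),
    vapply(seq_len(nrow(W)), function(i) {
      paste(c(ids[i], sprintf("%.17g", W[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read and write per-region vectors
#'
#' Per-region scalars (cell densities, tract-tracing weights, log-Jacobian
#' volume changes, metric changes) travel as two-column tab-delimited text,
#' `region` and `value`. Missing values are written as `NA`.
#'
#' @param path File path.
#' @param atlas Optional `region_atlas`; if supplied, regions must match the
#'   atlas's network regions in order.
#' @return `read_region_vector()` returns a tibble with columns `region`,
#'   `value`; `write_region_vector()` returns `path` invisibly.
#' @export
read_region_vector <- function(path, atlas = NULL) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    region = readr::col_character(),
    value = readr::col_double()
  ))
  if (!is.null(atlas)) {
    want <- network_regions(atlas)
    if (!identical(x$region, want)) {
      abort("vector regions do not match the atlas's network regions (in order)")
    }
  }
  x
}

#' @rdname read_region_vector
#' @param x A data frame with columns `region` and `value`.
#' @export
write_region_vector <- function(x, path) {
  stopifnot(all(c("region", "value") %in% names(x)))
  lines <- c("region\tvalue",
             paste(x$region, sprintf("%.17g", x$value), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# Coerce a region-vector argument (tibble region/value, tibble region/delta,
# or named numeric) to a named numeric vector.
as_region_values <- function(x, arg = "x") {
  if (is.data.frame(x)) {
    vcol <- intersect(c("value", "delta"), names(x))[1]
    if (!("region" %in% names(x)) || is.na(vcol)) {
      abort(sprintf("`%s` must have columns region and value (or delta)", arg))
    }
    return(setNames(as.numeric(x[[vcol]]), x$region))
  }
  if (is.numeric(x)) {
    if (is.null(names(x))) abort(sprintf("`%s` must be named by region", arg))
    return(x)
  }
  abort(sprintf("`%s` must be a region/value data frame or a named numeric", arg))
}

# Check two named region vectors cover the same regions in the same order.
check_matched_regions <- function(a, b, what = c("x", "y")) {
  if (!identical(names(a), names(b))) {
    abort(sprintf("`%s` and `%s` must cover the same regions in the same order",
                  what[1], what[2]))
  }
  invisible(TRUE)
}
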