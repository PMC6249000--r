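#' Module partitions
#'
#' A `module_partition` is a tibble with columns `region` and `module`
#' (contiguous integer labels starting at 1), carrying the resolution
#' parameter `gamma`, the modularity `Q` of the labelling on the source
#' matrix, and `n_modules` as attributes.
#'
#' @param region Character region ids.
#' @param module Integer module labels (any coding; relabelled contiguous in
#'   order of first appearance).
#' @param gamma Resolution parameter.
#' @param Q Modularity of the labelling.
#' @param seed Seed the labelling was produced under (or `NA`).
#' @return A `module_partition` tibble.
#' @export
module_partition <- function(region, module, gamma = 1, Q = NA_real_,
                             seed = NA_integer_) {
  module <- as.integer(factor(module, levels = unique(module)))
  out <- tibble(region = region, module = module)
  attr(out, "gamma") <- gamma
  attr(out, "Q") <- Q
  attr(out, "n_modules") <- max(module)
  attr(out, "seed") <- seed
  class(out) <- c("module_partition", class(tibble()))
  out
}

# Extract an integer label vector from a partition argument.
partition_labels <- function(partition, W = NULL) {
  lab <- if (is.data.frame(partition)) {
    if (!is.null(W) && !is.null(rownames(W))) {
      if (!identical(partition$region, rownames(W))) {
        abort("partition regions do not match matrix regions (in order)")
      }
    }
    partition$module
  } else {
    as.integer(partition)
  }
  if (!is.null(W) && length(lab) != nrow(W)) {
    abort("partition does not label every region of the matrix")
  }
  if (anyNA(lab)) abort("partition contains unlabelled regions")
  as.integer(lab)
}

# Positive part of a connectivity matrix with zeroed diagonal, the canvas for
# community detection and participation (negative weights are dropped, not
# thresholded by magnitude).
positive_part <- function(W) {
  Wp <- pmax(W, 0)
  diag(Wp) <- 0
  Wp
}

check_symmetric <- function(W, tol = 1e-8) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (max(abs(W - t(W))) > tol) abort("matrix is not symmetric")
  invisible(TRUE)
}

# One pass of greedy single-node moves (Louvain phase 1) on weight matrix Wc
# (nonnegative; diagonal may carry aggregated self-loops), starting from
# community vector `comm`. Nodes are visited in seeded-random order; a node
# moves to the community with the largest modularity gain, considering every
# current community plus isolation; ties go to the lowest community id; moves
# happen only on a strict improvement. Sweeps repeat until a full sweep makes
# no move. `m2` is the total weight of the *original* graph.
sweep_moves <- function(Wc, comm, gamma, m2) {
  n <- nrow(Wc)
  k <- rowSums(Wc)
  comm <- as.integer(comm)
  eps <- 1e-12
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      ci <- comm[i]
      agg_w <- rowsum(Wc[, i], comm)
      ids <- as.integer(rownames(agg_w))
      wtc <- agg_w[, 1]
      tot <- rowsum(k, comm)[, 1]
      sel <- which(ids == ci)
      wtc[sel] <- wtc[sel] - Wc[i, i]
      tot[sel] <- tot[sel] - k[i]
      gain <- wtc - gamma * k[i] * tot / m2
      base <- gain[sel]
      if (sum(comm == ci) > 1L) {        # isolation into a fresh community
        gain <- c(gain, 0)
        ids <- c(ids, max(comm) + 1L)
      }
      best <- max(gain)
      if (best > base + eps) {
        tgt <- min(ids[gain >= best - eps])
        if (tgt != ci) {
          comm[i] <- tgt
          moved <- TRUE
        }
      }
    }
    if (!moved) return(comm)
  }
}

# Full two-phase Louvain on a nonnegative zero-diagonal matrix, followed by a
# flat single-node refinement pass on the original graph (guards against
# aggregation locking in suboptimal merges). `init` optionally seeds phase 1
# with a starting partition. Uses the current RNG stream.
louvain_once <- function(W, gamma, init = NULL) {
  n0 <- nrow(W)
  m2 <- sum(W)
  node2row <- seq_len(n0)
  Wc <- W
  cur <- if (is.null(init)) seq_len(n0) else as.integer(factor(init))
  repeat {
    res <- as.integer(factor(sweep_moves(Wc, cur, gamma, m2)))
    if (identical(res, as.integer(factor(cur)))) break
    nc <- max(res)
    M <- matrix(0, nrow(Wc), nc)
    M[cbind(seq_len(nrow(Wc)), res)] <- 1
    Wc <- crossprod(M, Wc %*% M)
    node2row <- res[node2row]
    cur <- seq_len(nc)
    if (nc == 1L) break
  }
  lab <- as.integer(factor(node2row))
  lab <- sweep_moves(W, lab, gamma, m2)
  # canonical labelling: modules numbered by first appearance
  match(lab, unique(lab))
}

# One seeded restart. Odd restarts start from singletons (classical Louvain);
# even restarts start from a random partition, which diversifies the search.
louvain_restart <- function(Wp, gamma, seed, restart) {
  set.seed(seed)
  init <- if (restart %% 2L == 1L) {
    NULL
  } else {
    sample.int(sample.int(nrow(Wp), 1), nrow(Wp), replace = TRUE)
  }
  louvain_once(Wp, gamma, init)
}

#' Louvain community detection on a weighted connectivity matrix
#'
#' Greedy two-phase Louvain maximisation of Newman-Girvan modularity at
#' resolution `gamma`, run on the positive part of the (signed, unthresholded)
#' matrix with the diagonal zeroed. Deterministic given `seed`. With
#' `n_restarts > 1` the algorithm is restarted with derived seeds
#' (alternating singleton and random initial partitions) and the
#' highest-modularity labelling is returned.
#'
#' @param W Symmetric numeric matrix (region-named).
#' @param gamma Resolution parameter; larger values favour smaller modules
#'   (default 1).
#' @param seed Integer seed (restart `r` uses `seed + r - 1`).
#' @param n_restarts Number of seeded restarts (default 1).
#' @return A [module_partition()] with the modularity `Q` of the returned
#'   labelling as an attribute.
#' @examples
#' W <- matrix(0, 8, 8)
#' W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; diag(W) <- 0
#' rownames(W) <- colnames(W) <- paste0("R", 1:8)
#' louvain_partition(W, gamma = 1, seed = 7)
#' @export
louvain_partition <- function(W, gamma = 1, seed = 1L, n_restarts = 1L) {
  check_symmetric(W)
  ids <- rownames(W)
  if (is.null(ids)) ids <- paste0("R", seq_len(nrow(W)))
  Wp <- positive_part(W)
  if (sum(Wp) <= 0) {
    warn("positive part of the matrix is all zero; returning a single module")
    return(module_partition(ids, rep(1L, nrow(W)), gamma = gamma, Q = 0,
                            seed = seed))
  }
  local_seed(seed, {
    best <- NULL
    best_q <- -Inf
    for (r in seq_len(n_restarts)) {
      lab <- louvain_restart(Wp, gamma, seed + r - 1L, r)
      q <- modularity_score(W, lab, gamma)
      if (q > best_q) {
        best_q <- q
        best <- lab
      }
    }
    module_partition(ids, best, gamma = gamma, Q = best_q, seed = seed)
  })
}

#' Modularity of a partition
#'
#' Newman-Girvan modularity with resolution `gamma`,
#' \deqn{Q = \frac{1}{2m}\sum_{i \ne j}\left[W_{ij} -
#'   \gamma\frac{k_i k_j}{2m}\right]\delta(c_i, c_j),}
#' computed on the positive part of `W` with the diagonal excluded
#' (`weights = "positive"`, the default). The signed variant reports the
#' asymmetric combination \eqn{Q^+ - \frac{m^-}{m^+ + m^-} Q^-}, where
#' \eqn{Q^-} is the same quantity on the magnitude of the negative part.
#'
#' @param W Symmetric numeric matrix.
#' @param partition A [module_partition()] or integer label vector.
#' @param gamma Resolution parameter.
#' @param weights `"positive"` or `"signed"`.
#' @return Modularity score (scalar).
#' @export
modularity_score <- function(W, partition, gamma = 1,
                             weights = c("positive", "signed")) {
  weights <- match.arg(weights)
  lab <- partition_labels(partition, W)
  # self-weights are zeroed, but the diagonal null-model term is kept, as in
  # the standard Newman-Girvan formulation (so a single module at gamma = 1
  # scores exactly 0)
  q_part <- function(Wpart) {
    k <- rowSums(Wpart)
    m2 <- sum(Wpart)
    B <- Wpart - gamma * outer(k, k) / m2
    sum(B[outer(lab, lab, "==")]) / m2
  }
  Wp <- positive_part(W)
  vp <- sum(Wp)
  if (weights == "positive") {
    if (vp <= 0) abort("zero total positive weight; modularity undefined")
    return(q_part(Wp))
  }
  Wn <- pmax(-W, 0)
  diag(Wn) <- 0
  vn <- sum(Wn)
  if (vp + vn <= 0) abort("zero total weight; modularity undefined")
  qp <- if (vp > 0) q_part(Wp) else 0
  qn <- if (vn > 0) q_part(Wn) else 0
  qp - vn / (vp + vn) * qn
}

#' Consensus partition over stochastic Louvain runs
#'
#' Runs Louvain `n_reps` times with derived seeds, builds the region-by-region
#' co-assignment frequency matrix, and iteratively re-clusters it
#' (thresholding entries below `tau` to zero each round) until every run
#' returns the same partition, i.e. the co-assignment matrix is block-binary.
#' This is the agreement-matrix consensus of Lancichinetti & Fortunato,
#' extracting the most consistent modules from many stochastic partitions.
#'
#' @inheritParams louvain_partition
#' @param n_reps Number of stochastic runs per round (default 100).
#' @param tau Agreement threshold in (0, 1) (default 0.5).
#' @param max_iter Maximum consensus rounds before erroring (default 50).
#' @return A [module_partition()]; its `Q` is the modularity of the consensus
#'   labelling on the original matrix at `gamma`. The final co-assignment
#'   matrix is attached as attribute `"coassignment"`.
#' @export
consensus_partition <- function(W, gamma = 1, n_reps = 100L, seed = 1L,
                                tau = 0.5, max_iter = 50L) {
  check_symmetric(W)
  stopifnot(n_reps >= 1, tau > 0, tau < 1)
  ids <- rownames(W)
  if (is.null(ids)) ids <- paste0("R", seq_len(nrow(W)))
  n <- nrow(W)
  Wp <- positive_part(W)
  if (sum(Wp) <= 0) {
    warn("positive part of the matrix is all zero; returning a single module")
    return(module_partition(ids, rep(1L, n), gamma = gamma, Q = 0, seed = seed))
  }
  run_batch <- function(M, g, seed0) {
    lapply(seq_len(n_reps), function(r) louvain_restart(M, g, seed0 + r - 1L, r))
  }
  coassign <- function(runs) {
    D <- matrix(0, n, n)
    for (lab in runs) D <- D + outer(lab, lab, "==")
    D / length(runs)
  }
  local_seed(seed, {
    runs <- run_batch(Wp, gamma, seed)
    D <- coassign(runs)
    iter <- 0L
    while (!all(vapply(runs, identical, logical(1), runs[[1]]))) {
      iter <- iter + 1L
      if (iter > max_iter) {
        abort(sprintf(
          "consensus did not converge in %d rounds (mean off-diagonal agreement %.3f)",
          max_iter, mean(D[row(D) != col(D)])))
      }
      Dt <- D
      Dt[Dt < tau] <- 0
      diag(Dt) <- 0
      if (all(Dt == 0)) {
        warn("no pair of regions co-assigned above tau; returning singletons")
        runs <- list(seq_len(n))
        break
      }
      runs <- run_batch(Dt, 1, seed + iter * (n_reps + 1L))
      D <- coassign(runs)
    }
    lab <- runs[[1]]
    out <- module_partition(ids, lab, gamma = gamma,
                            Q = modularity_score(W, lab, gamma), seed = seed)
    dimnames(D) <- list(ids, ids)
    attr(out, "coassignment") <- D
    attr(out, "n_reps") <- n_reps
    attr(out, "tau") <- tau
    attr(out, "iterations") <- iter
    out
  })
}

#' Write a partition as two-column TSV (`region`, `module`)
#' @param partition A [module_partition()].
#' @param path File path.
#' @export
write_partition <- function(partition, path) {
  readr::write_tsv(tibble(region = partition$region,
                          module = partition$module), path)
  invisible(path)
}

#' @export
tidy.module_partition <- function(x, ...) {
  tibble(region = x$region, module = x$module)
}

#' @export
glance.module_partition <- function(x, ...) {
  tibble(gamma = attr(x, "gamma"), Q = attr(x, "Q"),
         n_modules = attr(x, "n_modules"), n_regions = nrow(x))
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d regions, %d modules, gamma = %g, Q = %.4f\n",
              nrow(x), attr(x, "n_modules"), attr(x, "gamma"), attr(x, "Q")))
  sizes <- table(x$module)
  cat("module sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}
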