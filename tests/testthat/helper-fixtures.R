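# shared fixture builders; everything is generated in code, nothing on disk

# random symmetric weight matrix with zero diagonal, weights in [lo, hi]
random_sym_matrix <- function(n, lo = 0, hi = 1, names = TRUE) {
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- runif(n * (n - 1) / 2, lo, hi)
  W <- W + t(W)
  if (names) rownames(W) <- colnames(W) <- sprintf("R%02d", seq_len(n))
  W
}

# two disconnected k-cliques with unit weights
two_cliques <- function(k = 4) {
  n <- 2 * k
  W <- matrix(0, n, n)
  W[seq_len(k), seq_len(k)] <- 1
  W[(k + 1):n, (k + 1):n] <- 1
  diag(W) <- 0
  rownames(W) <- colnames(W) <- sprintf("R%02d", seq_len(n))
  W
}

# planted-block matrix at the standard SNR used throughout the suite
planted_block_matrix <- function(sizes = c(20, 20, 19, 19), within = 0.6,
                                 between = 0.1, noise_sd = 0.05) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  W <- ifelse(outer(lab, lab, "=="), within, between)
  E <- matrix(rnorm(n * n, 0, noise_sd), n, n)
  E[lower.tri(E)] <- t(E)[lower.tri(E)]
  W <- W + E
  diag(W) <- 0
  rownames(W) <- colnames(W) <- sprintf("R%02d", seq_len(n))
  list(W = W, labels = lab)
}

# independent naive modularity oracle: direct double sum over region pairs
modularity_oracle <- function(W, lab, gamma = 1) {
  Wp <- pmax(W, 0)
  diag(Wp) <- 0
  k <- rowSums(Wp)
  m2 <- sum(Wp)
  q <- 0
  n <- nrow(W)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (lab[i] == lab[j]) {
        w <- if (i == j) 0 else Wp[i, j]
        q <- q + w - gamma * k[i] * k[j] / m2
      }
    }
  }
  unname(q / m2)
}

# independent participation oracle: per-module summation, one region at a time
participation_oracle <- function(W, lab) {
  Wp <- pmax(W, 0)
  diag(Wp) <- 0
  vapply(seq_len(nrow(W)), function(i) {
    k <- sum(Wp[i, ])
    if (k == 0) return(0)
    1 - sum(vapply(unique(lab), function(s) {
      (sum(Wp[i, lab == s]) / k)^2
    }, numeric(1)))
  }, numeric(1))
}

# all set partitions of n elements as restricted-growth strings
# (rows of the returned matrix); 877 rows for n = 7, 4140 for n = 8
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(labels, maxl) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (l in seq_len(maxl + 1L)) rec(c(labels, l), max(maxl, l))
  }
  rec(1L, 1L)
  do.call(rbind, out)
}

# adjusted Rand index between two labelings (independent of mclust, used
# where mclust is the cross-check)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# tiny labelled atlas for seed-profile tests
toy_atlas <- function() {
  region_atlas(tibble::tibble(
    abbrev = c("A", "B", "C", "D", "HC", "HC"),
    name = c("a", "b", "c", "d", "Hippocampus", "Hippocampus"),
    hemisphere = c("left", "left", "right", "right", "left", "right"),
    in_network = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  ))
}
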