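test_that("node strength matches row sums, signed and positive", {
  W <- matrix(1, 4, 4)
  diag(W) <- 0
  rownames(W) <- colnames(W) <- paste0("R", 1:4)
  expect_equal(node_strength(W)$value, rep(3, 4))
  expect_equal(node_strength(matrix(0, 3, 3))$value, rep(0, 3))

  set.seed(71)
  Wr <- random_sym_matrix(9, -0.5, 1)
  expect_equal(node_strength(Wr)$value, unname(rowSums(Wr)))
  Wp <- pmax(Wr, 0)
  expect_equal(node_strength(Wr, weights = "positive")$value,
               unname(rowSums(Wp)))
})

test_that("participation coefficient: provincial, split and oracle cases", {
  # all weight inside own module -> 0
  W <- two_cliques(4)
  lab <- rep(1:2, each = 4)
  expect_equal(participation_coefficient(W, lab)$value, rep(0, 8))

  # weight split equally over exactly two modules -> 1 - 2*(1/2)^2 = 0.5
  W2 <- matrix(0, 3, 3)
  W2[1, 2] <- W2[2, 1] <- 0.4
  W2[1, 3] <- W2[3, 1] <- 0.4
  expect_equal(participation_coefficient(W2, c(1, 2, 3))$value[1], 0.5)

  set.seed(73)
  for (rep in 1:5) {
    Wr <- random_sym_matrix(10, -0.3, 1)
    labr <- sample(1:3, 10, replace = TRUE)
    p <- participation_coefficient(Wr, labr)$value
    expect_equal(p, participation_oracle(Wr, labr), tolerance = 1e-12)
    expect_true(all(p >= 0 & p <= 1))
    # upper bound 1 - 1/n_modules
    expect_true(all(p <= 1 - 1 / length(unique(labr)) + 1e-12))
  }

  # zero-strength region scores 0
  W0 <- matrix(0, 4, 4)
  W0[1, 2] <- W0[2, 1] <- 1
  expect_equal(participation_coefficient(W0, c(1, 2, 1, 2))$value[3:4],
               c(0, 0))
})

test_that("within/between weight sums account for total positive strength", {
  set.seed(79)
  Wr <- random_sym_matrix(12, 0, 1)
  labr <- sample(1:3, 12, replace = TRUE)
  Wp <- pmax(Wr, 0)
  diag(Wp) <- 0
  same <- outer(labr, labr, "==")
  diag(same) <- FALSE
  within_sum <- rowSums(Wp * same)
  between_sum <- rowSums(Wp * !same) - diag(Wp)
  expect_equal(within_sum + between_sum,
               node_strength(Wr, "positive")$value, ignore_attr = TRUE)
})

test_that("within-module connectivity: constant, singleton and masked mean", {
  W <- matrix(0, 5, 5)
  W[1, 2:4] <- W[2:4, 1] <- 0.6
  W[2, 3] <- W[3, 2] <- 0.6
  W[2, 4] <- W[4, 2] <- 0.6
  W[3, 4] <- W[4, 3] <- 0.6
  lab <- c(1, 1, 1, 1, 2)
  v <- within_module_connectivity(W, lab)$value
  expect_equal(v[1], 0.6)
  expect_true(is.na(v[5]))   # singleton module

  set.seed(83)
  Wr <- random_sym_matrix(10, -1, 1)
  labr <- c(sample(1:3, 9, replace = TRUE), 4)
  vr <- within_module_connectivity(Wr, labr)$value
  for (i in 1:10) {
    mates <- which(labr == labr[i])
    mates <- setdiff(mates, i)
    if (length(mates) == 0) {
      expect_true(is.na(vr[i]))
    } else {
      expect_equal(vr[i], mean(Wr[i, mates]), tolerance = 1e-12)
    }
  }
})

test_that("hubness PCA: collinear, isotropic and eigen-oracle cases", {
  regions <- paste0("r", 1:6)
  s <- setNames(c(1, 2, 3, 4, 5, 6), regions)
  p_affine <- 0.1 * s + 0.05
  h <- hubness_scores(s, p_affine)
  expect_equal(h$pc1_variance_explained, 100)
  zs <- (s - mean(s)) / sd(s)
  expect_equal(cor(h$scores$hubness, zs), 1, tolerance = 1e-12)
  expect_gt(cor(h$scores$hubness, s), 0)

  # exactly uncorrelated columns -> 50%
  a <- setNames(c(-1, 1, -1, 1), paste0("q", 1:4))
  b <- setNames(c(-1, -1, 1, 1), paste0("q", 1:4))
  expect_equal(hubness_scores(a, b)$pc1_variance_explained, 50)

  # fixed 5-region pairs against prcomp as the independent oracle
  s5 <- setNames(c(2.3, 1.1, 4.0, 3.2, 0.7), paste0("x", 1:5))
  p5 <- setNames(c(0.4, 0.2, 0.9, 0.5, 0.3), paste0("x", 1:5))
  h5 <- hubness_scores(s5, p5)
  pc <- prcomp(cbind(scale(s5), scale(p5)), center = FALSE, scale. = FALSE)
  ve <- 100 * pc$sdev[1]^2 / sum(pc$sdev^2)
  expect_equal(h5$pc1_variance_explained, ve, tolerance = 1e-10)
  scores_oracle <- pc$x[, 1]
  if (cor(scores_oracle, s5) < 0) scores_oracle <- -scores_oracle
  expect_equal(h5$scores$hubness, unname(scores_oracle), tolerance = 1e-10)

  expect_error(hubness_scores(setNames(rep(1, 5), paste0("x", 1:5)), p5),
               "non-constant")
})

test_that("hubness is invariant to affine rescaling of inputs", {
  set.seed(89)
  regions <- paste0("r", 1:20)
  s <- setNames(rnorm(20), regions)
  p <- setNames(0.4 * s + rnorm(20, 0, 0.5), regions)
  h1 <- hubness_scores(s, p)
  h2 <- hubness_scores(100 + 7 * s, 0.01 * p - 3)
  expect_equal(h1$scores$hubness, h2$scores$hubness, tolerance = 1e-10)
  expect_equal(h1$pc1_variance_explained, h2$pc1_variance_explained)
})

test_that("node_metric_table binds all metrics in atlas order", {
  set.seed(97)
  pb <- planted_block_matrix(sizes = c(5, 5, 5))
  part <- louvain_partition(pb$W, seed = 1, n_restarts = 4)
  m <- node_metric_table(pb$W, part)
  expect_equal(m$region, rownames(pb$W))
  expect_equal(m$strength, node_strength(pb$W)$value)
  expect_equal(m$participation,
               participation_coefficient(pb$W, part)$value)
  expect_true(is.numeric(attr(m, "pc1_variance_explained")))
})
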