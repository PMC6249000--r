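test_that("generator is deterministic and respects domain constraints", {
  cfg <- synth_config(seed = 42)
  p1 <- generate_predictors(cfg)
  p2 <- generate_predictors(cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 78)
  expect_true(all(p1$neuron_density > 0))
  expect_true(all(p1$nonneuronal_density > 0))

  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$fc_group, s2$fc_group)
  expect_identical(s1$logjac, s2$logjac)

  for (G in s1$fc_group) {
    expect_equal(G, t(G))
    expect_equal(unname(diag(G)), rep(1, 78))
    expect_true(all(G >= -1 & G <= 1))
  }
  for (W in s1$fc$t3) {
    expect_equal(W, t(W))
    expect_true(all(W >= -1 & W <= 1))
  }
})

test_that("predictor correlation structure is calibrated", {
  # mean sample corr(neuron, hubness) across replicates near the 0.4 target
  cors <- vapply(1:80, function(s) {
    p <- generate_predictors(synth_config(seed = 1000 + s))
    cor(p$neuron_density, p$hubness)
  }, numeric(1))
  expect_lt(abs(mean(cors) - 0.4), 0.05)
  # planted negative association of non-neuronal density with hubness
  cors_nn <- vapply(1:80, function(s) {
    p <- generate_predictors(synth_config(seed = 1000 + s))
    cor(p$nonneuronal_density, p$hubness)
  }, numeric(1))
  expect_lt(abs(mean(cors_nn) + 0.3), 0.05)
})

test_that("null study has identical expected matrices at all timepoints", {
  zero_eff <- lapply(synth_default_effects(), function(x) x * 0)
  cfg <- synth_config(seed = 9, effects = zero_eff, noise_sd = 0)
  st <- generate_study(cfg)
  expect_equal(st$fc_group$t0, st$fc_group$t3)
  expect_equal(st$fc_group$t3, st$fc_group$t12)
  expect_equal(st$logjac$t0$value, st$logjac$t12$value)
})

test_that("planted within-module and log-Jacobian changes are exact", {
  st <- generate_study(synth_config(seed = 77))
  lab <- st$ground_truth$partition$module
  w0 <- within_module_connectivity(st$fc_group$t0, lab)$value
  w3 <- within_module_connectivity(st$fc_group$t3, lab)$value
  w12 <- within_module_connectivity(st$fc_group$t12, lab)$value
  expect_equal(w3 - w0,
               st$ground_truth$deltas$acute_within_module_fc$delta,
               tolerance = 1e-10)
  expect_equal(w12 - w3,
               st$ground_truth$deltas$chronic_within_module_fc$delta,
               tolerance = 1e-10)
  expect_equal(st$logjac$t3$value - st$logjac$t0$value,
               st$ground_truth$deltas$acute_grey_matter_logjac$delta,
               tolerance = 1e-12)
})

test_that("participation injection moves the metric in the planted direction", {
  st <- generate_study(synth_config(seed = 78))
  lab <- st$ground_truth$partition$module
  p0 <- participation_coefficient(st$fc_group$t0, lab)$value
  p3 <- participation_coefficient(st$fc_group$t3, lab)$value
  d_true <- st$ground_truth$deltas$acute_participation$delta
  expect_gt(cor(p3 - p0, d_true), 0.5)
})

test_that("consensus on a zero-noise planted study recovers the partition", {
  cfg <- synth_config(seed = 13, weight_noise_sd = 0, subject_noise_sd = 0)
  st <- generate_study(cfg)
  cons <- consensus_partition(st$fc_group$t0, n_reps = 20, seed = 4)
  expect_equal(ari(cons$module, st$ground_truth$partition$module), 1)
})

test_that("raising the hub multiplier raises hub-metric correspondence", {
  rank_cor <- vapply(c(1, 1.5, 2.2), function(mult) {
    st <- generate_study(synth_config(seed = 55, hub_multiplier = mult))
    part <- st$ground_truth$partition$module
    m <- node_metric_table(st$fc_group$t0, part)
    cor(m$hubness, as.numeric(st$ground_truth$hubs$is_hub),
        method = "spearman")
  }, numeric(1))
  expect_true(all(diff(rank_cor) > 0))
})

test_that("timecourse mode emits correlation matrices near the planted ones", {
  cfg <- synth_config(seed = 3, n_regions = 30, n_subjects = 2,
                      block_sizes = c(10, 10, 10), n_timepoints_ts = 988)
  st <- generate_study(cfg, mode = "timecourse")
  W <- st$fc$t0[[1]]
  expect_equal(W, t(W))
  expect_equal(unname(diag(W)), rep(1, 30))
  # sampling noise at 988 samples keeps matrices close to the group matrix
  expect_lt(max(abs(W - st$fc_group$t0)), 0.2)
  expect_gt(cor(W[upper.tri(W)], st$fc_group$t0[upper.tri(W)]), 0.95)
})

test_that("ground-truth manifest round-trips and regenerates the study", {
  cfg <- synth_config(seed = 21)
  st <- generate_study(cfg)
  man <- ground_truth_report(st)
  expect_equal(as.integer(table(man$partition$module)), cfg$block_sizes)
  f <- withr::local_tempfile(fileext = ".json")
  write_manifest(man, f)
  back <- read_manifest(f)
  expect_equal(back$seed, man$seed)
  expect_equal(back$partition$module, man$partition$module)
  expect_equal(back$betas$beta_units, man$betas$beta_units, tolerance = 1e-14)
  expect_equal(back$seed_profile$value, man$seed_profile$value,
               tolerance = 1e-14)
  # regenerating from the manifest seed reproduces the study exactly
  st2 <- generate_study(synth_config(seed = back$seed))
  expect_identical(st$fc_group, st2$fc_group)
})

test_that("config validation names the offending field", {
  expect_error(synth_config(block_sizes = c(10, 10)), "sum to n_regions")
  expect_error(synth_config(n_regions = 8, block_sizes = c(6, 2)),
               "at least 3")
  bad_corr <- diag(4)
  bad_corr[1, 2] <- bad_corr[2, 1] <- 1.5
  expect_error(synth_config(predictor_corr = bad_corr), "positive definite")
  expect_error(synth_config(effects = list(a = 1)), "missing")
  expect_error(synth_config(noise_sd = -1), ">= 0")
  # effect sizes that push systematic weights out of correlation range
  expect_error(generate_study(synth_config(seed = 1, change_scale = 1)),
               "outside \\[-0.99, 0.99\\]")
})
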