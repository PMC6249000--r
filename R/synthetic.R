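#' Configuration for a synthetic lesion-plasticity study
#'
#' Collects every knob of the synthetic-study generator. The defaults emulate
#' the statistical structure the analysis pipeline assumes: 78 network
#' regions observed in 5 subjects at three timepoints (pre-lesion, 3 months,
#' 12 months), four planted functional modules, a hub-enriched weight
#' structure, four smooth correlated predictor gradients, and stage changes
#' that are linear in the (z-scored) predictors plus Gaussian noise.
#'
#' Planted effects are specified in standardized units (change in dv standard
#' deviations per 1 sd of predictor); `change_scale` converts them to
#' correlation units for the functional-connectivity metrics and
#' `logjac_scale` to log-Jacobian units, keeping matrix weights inside
#' `[-1, 1]`. Selection rates and relative beta recovery are invariant to
#' these scales.
#'
#' @param n_regions Number of network regions (default 78; when 78 the
#'   bundled Regional Map atlas provides region ids).
#' @param n_subjects Subjects per timepoint (default 5).
#' @param n_timepoints_ts Timecourse samples per scan for
#'   `mode = "timecourse"` (default 988, one resting-state run).
#' @param block_sizes Planted module sizes; must sum to `n_regions` and each
#'   be at least 3 (default `c(20, 20, 19, 19)`).
#' @param within_mean,between_mean Mean weight inside / between planted
#'   modules (defaults 0.6 / 0.1).
#' @param weight_noise_sd SD of the symmetric weight noise frozen into the
#'   pre-lesion matrix (default 0.05).
#' @param subject_noise_sd SD of per-subject, per-scan weight noise
#'   (default 0.02).
#' @param hub_fraction Fraction of regions planted as hubs (default 0.15);
#'   hubs are the regions with the highest hubness-gradient values.
#' @param hub_multiplier Multiplier applied to hubs' between-module weights
#'   (default 1.5), raising both their strength and their participation.
#' @param predictor_corr 4x4 target correlation among the predictor
#'   gradients, ordered neuron density, non-neuronal density, hubness,
#'   seed FC. Default plants the positive neuron-hubness and negative
#'   non-neuronal-hubness associations. Must be positive definite.
#' @param effects Named list of standardized planted coefficient vectors
#'   (length 4, ordered as the predictors) for each
#'   `<stage>_<metric>` combination; see `synth_default_effects()`.
#' @param noise_sd SD of the standardized change noise (default 0.5).
#' @param change_scale Correlation units per standardized change unit for FC
#'   metrics (default 0.05).
#' @param logjac_scale Log-Jacobian units per standardized change unit
#'   (default 0.02).
#' @param seed Integer seed; every random draw derives from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_regions = 78L, n_subjects = 5L,
                         n_timepoints_ts = 988L,
                         block_sizes = c(20L, 20L, 19L, 19L),
                         within_mean = 0.6, between_mean = 0.1,
                         weight_noise_sd = 0.05, subject_noise_sd = 0.02,
                         hub_fraction = 0.15, hub_multiplier = 1.5,
                         predictor_corr = synth_default_predictor_corr(),
                         effects = synth_default_effects(),
                         noise_sd = 0.5, change_scale = 0.05,
                         logjac_scale = 0.02, seed = 1L) {
  if (sum(block_sizes) != n_regions) {
    abort("block_sizes must sum to n_regions")
  }
  if (any(block_sizes < 3)) {
    abort("every planted module needs at least 3 regions")
  }
  for (s in c(weight_noise_sd, subject_noise_sd, noise_sd)) {
    if (s < 0) abort("noise standard deviations must be >= 0")
  }
  stopifnot(is.matrix(predictor_corr), nrow(predictor_corr) == 4,
            ncol(predictor_corr) == 4)
  if (max(abs(predictor_corr - t(predictor_corr))) > 1e-12) {
    abort("predictor_corr must be symmetric")
  }
  if (inherits(tryCatch(chol(predictor_corr), error = identity), "error")) {
    abort("predictor_corr must be positive definite")
  }
  keys <- as.vector(outer(c("acute", "chronic"), metric_levels, paste, sep = "_"))
  missing_keys <- setdiff(keys, names(effects))
  if (length(missing_keys)) {
    abort(paste0("effects is missing: ", paste(missing_keys, collapse = ", ")))
  }
  if (!all(vapply(effects, length, 1L) == 4L)) {
    abort("each effects entry must have 4 coefficients")
  }
  out <- list(n_regions = as.integer(n_regions),
              n_subjects = as.integer(n_subjects),
              n_timepoints_ts = as.integer(n_timepoints_ts),
              block_sizes = as.integer(block_sizes),
              within_mean = within_mean, between_mean = between_mean,
              weight_noise_sd = weight_noise_sd,
              subject_noise_sd = subject_noise_sd,
              hub_fraction = hub_fraction, hub_multiplier = hub_multiplier,
              predictor_corr = predictor_corr, effects = effects,
              noise_sd = noise_sd, change_scale = change_scale,
              logjac_scale = logjac_scale, seed = as.integer(seed))
  class(out) <- "synth_config"
  out
}

#' @rdname synth_config
#' @export
synth_default_predictor_corr <- function() {
  terms <- c("neuron_density", "nonneuronal_density", "hubness", "seed_fc")
  C <- diag(4)
  dimnames(C) <- list(terms, terms)
  C["neuron_density", "hubness"] <- C["hubness", "neuron_density"] <- 0.4
  C["nonneuronal_density", "hubness"] <-
    C["hubness", "nonneuronal_density"] <- -0.3
  C["neuron_density", "nonneuronal_density"] <-
    C["nonneuronal_density", "neuron_density"] <- 0.2
  C
}

#' @rdname synth_config
#' @export
synth_default_effects <- function() {
  # directions mirror the observed plasticity pattern: hubs and strongly
  # seed-connected regions drop participation acutely; non-neuronal density
  # drives the chronic participation rise; neuron density predicts chronic
  # within-module loss while seed connectivity predicts a within-module rise;
  # seed connectivity predicts chronic grey-matter loss
  list(
    acute_participation        = c(0, 0, -0.5, -0.5),
    chronic_participation      = c(0, 0.5, -0.5, 0),
    acute_within_module_fc     = c(0, 0, -0.5, 0),
    chronic_within_module_fc   = c(-0.5, 0, 0, 0.5),
    acute_grey_matter_logjac   = c(0, 0, 0, 0),
    chronic_grey_matter_logjac = c(0, 0, 0, -0.5)
  )
}

# moving-average smoothing with reflected edges; preserves cross-column
# correlation structure while imposing a smooth spatial gradient
smooth_gradient <- function(x, window = 5L) {
  half <- window %/% 2L
  xp <- c(rev(x[seq_len(half)]), x, rev(x[length(x) - seq_len(half) + 1L]))
  out <- stats::filter(xp, rep(1 / window, window), sides = 2)
  as.numeric(out[(half + 1):(half + length(x))])
}

synth_region_ids <- function(n_regions) {
  if (n_regions == 78L) network_regions(regional_map_atlas())
  else sprintf("R%03d_L", seq_len(n_regions))
}

#' Generate the four predictor gradients
#'
#' Draws four smooth per-region gradients with the configured target
#' correlation structure (Gaussian draws with the target covariance,
#' moving-average smoothed along the region index, re-standardized), then
#' maps them to their natural scales: strictly positive neuron and
#' non-neuronal cell densities, a unit-scale hubness gradient, and a seed
#' (pre-lesion hippocampal) connectivity profile in correlation units.
#'
#' @param config A [synth_config()].
#' @return Tibble with columns `region`, `neuron_density`,
#'   `nonneuronal_density`, `hubness`, `seed_fc`.
#' @export
generate_predictors <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_regions
  local_seed(config$seed + 1L, {
    Z <- matrix(rnorm(n * 4), n, 4) %*% chol(config$predictor_corr)
    Z <- apply(Z, 2, smooth_gradient)
    Z <- scale(Z)
    positive <- function(mu, s, z) {
      v <- mu + s * z
      if (any(v <= 0)) v <- v - min(v) + 0.05 * mu
      v
    }
    tibble(
      region = synth_region_ids(n),
      neuron_density = positive(60000, 15000, Z[, 1]),
      nonneuronal_density = positive(40000, 8000, Z[, 2]),
      hubness = as.numeric(Z[, 3]),
      seed_fc = 0.15 + 0.15 * Z[, 4]
    )
  })
}

# Exact within-module change injection: adds a_i + a_j to every same-module
# edge so that each region's mean within-module weight changes by exactly
# d_i. Closed form requires module size >= 3.
inject_within <- function(W, lab, d) {
  for (m in unique(lab)) {
    idx <- which(lab == m)
    s <- length(idx)
    dd <- d[idx]
    S <- sum(dd) / 2
    a <- (dd - S / (s - 1)) * (s - 1) / (s - 2)
    bump <- outer(a, rep(1, s)) + outer(rep(1, s), a)
    diag(bump) <- 0
    W[idx, idx] <- W[idx, idx] + bump
  }
  W
}

# Approximate participation injection: shifts region i's between-module
# edges by (d_i + d_j)/2. Raises (d > 0) or lowers between-module weight,
# moving participation in the requested direction; the participation change
# itself is nonlinear in edge weights, so magnitudes are approximate.
inject_between <- function(W, lab, d) {
  diffm <- outer(lab, lab, "!=")
  bump <- (outer(d, rep(1, length(d))) + outer(rep(1, length(d)), d)) / 2
  W + bump * diffm
}

sym_noise <- function(n, sd) {
  E <- matrix(rnorm(n * n, 0, sd), n, n)
  E[lower.tri(E)] <- t(E)[lower.tri(E)]
  diag(E) <- 0
  E
}

clip_fc <- function(W) {
  W <- pmin(pmax(W, -0.999), 0.999)
  diag(W) <- 1
  W
}

#' Generate a complete synthetic lesion-plasticity study
#'
#' Builds a three-timepoint, multi-subject synthetic study with full ground
#' truth: a planted module partition with hub-enriched between-module
#' weights; per-subject connectivity matrices at pre-lesion, 3-month and
#' 12-month timepoints; a full pre-lesion matrix that still contains the
#' seed (hippocampus) and excluded (amygdala) rows; four predictor
#' gradients; and per-timepoint regional log-Jacobian volume series. True
#' stage changes equal `effects x z-scored predictors + noise`: exactly so
#' for within-module connectivity (closed-form edge perturbation) and
#' log-Jacobian volumes (direct vector series), directionally for the
#' participation coefficient (between-module edge perturbation; the metric
#' is nonlinear in edge weights).
#'
#' @param config A [synth_config()].
#' @param mode `"fast"` emits the planted matrices directly; `"timecourse"`
#'   samples `n_timepoints_ts` Gaussian timecourses from each planted
#'   correlation structure and correlates them, adding realistic sampling
#'   noise.
#' @return A `synthetic_study` list: `fc` (per timepoint, list of subject
#'   matrices), `fc_group` (noise-free group matrices), `fc_full_pre`,
#'   `predictors`, `logjac` (per-timepoint region/value tibbles), `atlas`,
#'   `ground_truth`, `config`.
#' @export
generate_study <- function(config, mode = c("fast", "timecourse")) {
  stopifnot(inherits(config, "synth_config"))
  mode <- match.arg(mode)
  n <- config$n_regions
  ids <- synth_region_ids(n)
  predictors <- generate_predictors(config)
  terms <- c("neuron_density", "nonneuronal_density", "hubness", "seed_fc")
  Xz <- scale(as.matrix(predictors[, terms]))
  lab <- rep(seq_along(config$block_sizes), config$block_sizes)
  n_hub <- max(1L, round(config$hub_fraction * n))
  hub_idx <- order(predictors$hubness, decreasing = TRUE)[seq_len(n_hub)]
  is_hub <- seq_len(n) %in% hub_idx

  local_seed(config$seed + 2L, {
    # deterministic base structure: block means, hub-boosted between weights
    same <- outer(lab, lab, "==")
    B <- ifelse(same, config$within_mean, config$between_mean)
    mult <- ifelse(is_hub, sqrt(config$hub_multiplier), 1)
    boost <- outer(mult, mult)
    B <- ifelse(same, B, B * boost)
    diag(B) <- 1

    # planted stage changes (standardized, then scaled to metric units)
    keys <- names(config$effects)
    deltas_std <- lapply(keys, function(key) {
      beta <- config$effects[[key]]
      drop(Xz %*% beta) + rnorm(n, 0, config$noise_sd)
    })
    names(deltas_std) <- keys
    unit_scale <- function(key) {
      if (grepl("logjac", key)) config$logjac_scale else config$change_scale
    }
    deltas <- lapply(keys, function(key) unit_scale(key) * deltas_std[[key]])
    names(deltas) <- keys

    # range guard on the systematic structure: block means plus the
    # noise-free part of the planted effects (noise tails are saturated by
    # clip_fc instead)
    deltas_sys <- lapply(keys, function(key) {
      unit_scale(key) * drop(Xz %*% config$effects[[key]])
    })
    names(deltas_sys) <- keys
    S3 <- inject_within(B, lab, deltas_sys$acute_within_module_fc)
    S3 <- inject_between(S3, lab, deltas_sys$acute_participation)
    S12 <- inject_within(S3, lab, deltas_sys$chronic_within_module_fc)
    S12 <- inject_between(S12, lab, deltas_sys$chronic_participation)
    for (S in list(B, S3, S12)) {
      bad <- abs(S) > 0.99 & row(S) != col(S)
      if (any(bad)) {
        abort(sprintf(
          "planted effects push %d systematic weight(s) outside [-0.99, 0.99] (max |w| = %.3f); reduce change_scale or block means",
          sum(bad) / 2, max(abs(S[bad]))))
      }
    }

    base_noise <- sym_noise(n, config$weight_noise_sd)
    G0 <- B + base_noise
    diag(G0) <- 1
    G3 <- inject_within(G0, lab, deltas$acute_within_module_fc)
    G3 <- inject_between(G3, lab, deltas$acute_participation)
    G12 <- inject_within(G3, lab, deltas$chronic_within_module_fc)
    G12 <- inject_between(G12, lab, deltas$chronic_participation)
    dimnames(G0) <- dimnames(G3) <- dimnames(G12) <- list(ids, ids)

    emit_subject <- function(G) {
      W <- clip_fc(G + sym_noise(n, config$subject_noise_sd))
      if (mode == "timecourse") {
        # sample timecourses from the nearest PSD correlation structure
        eig <- eigen(W, symmetric = TRUE)
        vals <- pmax(eig$values, 1e-6)
        R <- eig$vectors %*% diag(sqrt(vals))
        ts <- matrix(rnorm(config$n_timepoints_ts * n),
                     config$n_timepoints_ts, n) %*% t(R)
        W <- cor(ts)
        dimnames(W) <- list(ids, ids)
      }
      W
    }
    fc <- lapply(list(t0 = clip_fc(G0), t3 = clip_fc(G3), t12 = clip_fc(G12)),
                 function(G) lapply(seq_len(config$n_subjects),
                                    function(s) emit_subject(G)))

    # full pre-lesion matrix with seed + excluded rows appended
    if (n == 78L) {
      atlas <- regional_map_atlas()
      extra <- c("HC_L", "HC_R", "Amyg_L", "Amyg_R")
    } else {
      atlas <- region_atlas(tibble(
        abbrev = c(sub("_L$", "", ids), "SEED", "SEED"),
        name = c(ids, "Seed region", "Seed region"),
        hemisphere = c(rep("left", n), "left", "right"),
        in_network = c(rep(TRUE, n), FALSE, FALSE)))
      stopifnot(identical(atlas$region[atlas$in_network], ids))
      extra <- c("SEED_L", "SEED_R")
    }
    n_extra <- length(extra)
    full_ids <- c(ids, extra)
    Wfull <- matrix(0.3, n + n_extra, n + n_extra,
                    dimnames = list(full_ids, full_ids))
    Wfull[seq_len(n), seq_len(n)] <- clip_fc(G0)
    seed_rows <- extra[1:2]
    for (sr in seed_rows) {
      Wfull[sr, seq_len(n)] <- predictors$seed_fc + rnorm(n, 0, 0.02)
      Wfull[seq_len(n), sr] <- Wfull[sr, seq_len(n)]
    }
    if (n_extra == 4) {
      for (ar in extra[3:4]) {
        Wfull[ar, seq_len(n)] <- 0.2 + rnorm(n, 0, 0.05)
        Wfull[seq_len(n), ar] <- Wfull[ar, seq_len(n)]
      }
    }
    Wfull <- (Wfull + t(Wfull)) / 2
    diag(Wfull) <- 1

    lj0 <- rnorm(n, 0, 0.05)
    logjac <- list(
      t0 = tibble(region = ids, value = lj0),
      t3 = tibble(region = ids,
                  value = lj0 + deltas$acute_grey_matter_logjac),
      t12 = tibble(region = ids,
                   value = lj0 + deltas$acute_grey_matter_logjac +
                     deltas$chronic_grey_matter_logjac))

    betas <- purrr::map_dfr(keys, function(k) {
      tibble(key = k, term = terms, beta_std = config$effects[[k]],
             beta_units = config$effects[[k]] * unit_scale(k))
    })
    ground_truth <- list(
      partition = tibble(region = ids, module = lab),
      hubs = tibble(region = ids, is_hub = is_hub),
      betas = betas,
      deltas = lapply(deltas, function(d) tibble(region = ids, delta = d)),
      deltas_std = lapply(deltas_std, function(d) tibble(region = ids,
                                                         delta = d)),
      seed_profile = tibble(region = ids, value = predictors$seed_fc),
      seed = config$seed
    )
    out <- list(fc = fc,
                fc_group = list(t0 = clip_fc(G0), t3 = clip_fc(G3),
                                t12 = clip_fc(G12)),
                fc_full_pre = Wfull, predictors = predictors,
                logjac = logjac, atlas = atlas,
                ground_truth = ground_truth, config = config)
    class(out) <- "synthetic_study"
    out
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d regions, %d subjects, 3 timepoints, %d planted modules\n",
    x$config$n_regions, x$config$n_subjects, length(x$config$block_sizes)))
  invisible(x)
}

#' Ground-truth manifest of a synthetic study
#'
#' A machine-readable record of everything planted into a synthetic study:
#' the partition, hub flags, standardized and unit-scale betas, the seed
#' connectivity profile, and the master seed. Regenerating with the
#' manifest's seed reproduces the study element-for-element.
#'
#' @param study A `synthetic_study`.
#' @return A `ground_truth_manifest` list.
#' @export
ground_truth_report <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  gt <- study$ground_truth
  out <- list(
    seed = gt$seed,
    n_regions = study$config$n_regions,
    block_sizes = study$config$block_sizes,
    partition = gt$partition,
    hub_regions = gt$hubs$region[gt$hubs$is_hub],
    betas = gt$betas,
    seed_profile = gt$seed_profile
  )
  class(out) <- "ground_truth_manifest"
  out
}

#' @rdname ground_truth_report
#' @param manifest A `ground_truth_manifest`.
#' @param path File path for the JSON manifest.
#' @export
write_manifest <- function(manifest, path) {
  x <- unclass(manifest)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname ground_truth_report
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$partition <- as_tibble(x$partition)
  x$betas <- as_tibble(x$betas)
  x$seed_profile <- as_tibble(x$seed_profile)
  class(x) <- "ground_truth_manifest"
  x
}
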