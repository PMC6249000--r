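#' Read and validate a pipeline configuration
#'
#' Pipeline configurations are YAML with three blocks: a data source
#' (`synthetic:` with a seed and optional [synth_config()] overrides, or
#' `inputs:` with file paths), an optional `analysis:` block (gamma, gamma
#' grid, consensus repetitions, stepwise thresholds, null simulation count),
#' and `seed` / `out_dir` at top level. Every violation is reported by field
#' name.
#'
#' @param path Path to a YAML file.
#' @return A validated `pipeline_config` list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  validate_pipeline_config(yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config A raw config list.
#' @export
validate_pipeline_config <- function(config) {
  if (!is.list(config)) abort("config must be a mapping")
  has_syn <- !is.null(config$synthetic)
  has_inp <- !is.null(config$inputs)
  if (has_syn == has_inp) {
    abort("config must contain exactly one of `synthetic` or `inputs`")
  }
  if (is.null(config$seed)) abort("config field missing: seed")
  if (is.null(config$out_dir)) abort("config field missing: out_dir")
  if (has_inp) {
    inp <- config$inputs
    for (f in c("region_table", "fc_matrices", "fc_full_pre", "predictors")) {
      if (is.null(inp[[f]])) abort(paste0("config field missing: inputs$", f))
    }
    for (t in c("t0", "t3", "t12")) {
      if (is.null(inp$fc_matrices[[t]])) {
        abort(paste0("config field missing: inputs$fc_matrices$", t))
      }
    }
    for (p in c("neuron_density", "nonneuronal_density")) {
      if (is.null(inp$predictors[[p]])) {
        abort(paste0("config field missing: inputs$predictors$", p))
      }
    }
    paths <- c(inp$region_table, unlist(inp$fc_matrices), inp$fc_full_pre,
               unlist(inp$predictors), unlist(inp$logjac))
    missing_files <- paths[!file.exists(paths)]
    if (length(missing_files)) {
      abort(paste0("input file(s) not found: ",
                   paste(missing_files, collapse = ", ")))
    }
  }
  ana <- config$analysis %||% list()
  defaults <- list(gamma = 1, gamma_grid = seq(0.8, 1.4, by = 0.1),
                   consensus_reps = 100L, p_enter = 0.05, p_remove = 0.10,
                   null_sims = 1000L, louvain_restarts = 10L)
  for (f in names(defaults)) ana[[f]] <- ana[[f]] %||% defaults[[f]]
  if (ana$p_enter > ana$p_remove) {
    abort("config field invalid: analysis$p_enter must be <= analysis$p_remove")
  }
  config$analysis <- ana
  class(config) <- "pipeline_config"
  config
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    syn$seed <- syn$seed %||% config$seed
    cfg <- do.call(synth_config, syn)
    study <- generate_study(cfg)
    return(list(atlas = study$atlas, fc = study$fc,
                fc_full_pre = study$fc_full_pre,
                neuron = study$predictors[, c("region", "neuron_density")],
                nonneuronal = study$predictors[, c("region",
                                                   "nonneuronal_density")],
                logjac = study$logjac, study = study))
  }
  inp <- config$inputs
  atlas <- read_region_table(inp$region_table)
  fc <- lapply(inp$fc_matrices, function(paths) {
    lapply(paths, read_fc_matrix, atlas = atlas)
  })
  lj <- if (!is.null(inp$logjac)) {
    lapply(inp$logjac, read_region_vector, atlas = atlas)
  }
  nd <- read_region_vector(inp$predictors$neuron_density, atlas)
  nn <- read_region_vector(inp$predictors$nonneuronal_density, atlas)
  list(atlas = atlas, fc = fc,
       fc_full_pre = read_fc_matrix(inp$fc_full_pre),
       neuron = rename(nd, neuron_density = "value"),
       nonneuronal = rename(nn, nonneuronal_density = "value"),
       logjac = lj, study = NULL)
}

#' Run the full lesion-plasticity analysis pipeline
#'
#' Orchestrates the analysis end to end: per-timepoint group-mean
#' connectivity; consensus modules from the pre-lesion matrix (modules are
#' defined once, pre-lesion, and held fixed across timepoints); per-timepoint
#' node metrics; hubness and the seed connectivity profile as predictors;
#' acute and chronic stage changes with chronic residualisation and the
#' shared-timepoint-null correction of the acute-chronic dependence; stepwise
#' regressions per stage and metric; module-dispersion ANOVAs; a modularity
#' trajectory across timepoints; and a gamma-sweep robustness table. Results
#' are written to `out_dir` as TSV tables plus a deterministic
#' `summary.json` and a `run_log.txt` recording seeds and versions.
#'
#' @param config A `pipeline_config` (from [read_pipeline_config()] or
#'   [validate_pipeline_config()]).
#' @param out_dir Output directory (defaults to the config's `out_dir`).
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    config <- validate_pipeline_config(config)
  }
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ana <- config$analysis
  seed <- as.integer(config$seed)
  dat <- load_pipeline_inputs(config)
  atlas <- dat$atlas

  fc_group <- lapply(dat$fc, average_fc_matrices)
  tps <- names(fc_group)

  partition <- consensus_partition(fc_group$t0, gamma = ana$gamma,
                                   n_reps = ana$consensus_reps,
                                   seed = seed + 11L)
  metrics <- lapply(fc_group, node_metric_table, partition = partition)
  hub <- hubness_scores(
    node_strength(fc_group$t0),
    participation_coefficient(fc_group$t0, partition))
  seed_profile <- seed_connectivity_profile(
    dat$fc_full_pre, atlas,
    seed_abbrev = if ("HC_L" %in% rownames(dat$fc_full_pre)) "HC" else "SEED")

  predictors <- dat$neuron |>
    left_join(dat$nonneuronal, by = "region") |>
    left_join(rename(hub$scores, hubness = "hubness"), by = "region") |>
    left_join(rename(seed_profile, seed_fc = "value"), by = "region")

  metric_cols <- c(participation = "participation",
                   within_module_fc = "within_module_fc")
  get_vec <- function(tp, metric) {
    setNames(metrics[[tp]][[metric_cols[metric]]], metrics[[tp]]$region)
  }
  null_dist <- shared_timepoint_null(n_regions = nrow(partition),
                                     n_sims = ana$null_sims,
                                     seed = seed + 23L)

  changes <- list()
  fits <- list()
  dependence <- list()
  analyse_metric <- function(metric, v0, v3, v12) {
    acute <- stage_change(v3, v0, "acute", metric)
    chronic <- stage_change(v12, v3, "chronic", metric)
    dep_fit <- lm(chronic$delta ~ acute$delta)
    t_obs <- summary(dep_fit)$coefficients[2, "t value"]
    dependence[[metric]] <<- mutate(null_pvalue(t_obs, null_dist),
                                    metric = metric)
    resid_chronic <- residualize_chronic(chronic, acute)
    changes[[metric]] <<- list(acute = acute, chronic = chronic,
                               chronic_residual = resid_chronic)
    for (st in c("acute", "chronic_residual")) {
      fits[[paste(st, metric, sep = "_")]] <<-
        stepwise_regression(predictors, changes[[metric]][[st]],
                            p_enter = ana$p_enter, p_remove = ana$p_remove)
    }
  }
  for (m in names(metric_cols)) {
    analyse_metric(m, get_vec("t0", m), get_vec("t3", m), get_vec("t12", m))
  }
  if (!is.null(dat$logjac)) {
    lj <- lapply(dat$logjac, function(x) setNames(x$value, x$region))
    analyse_metric("grey_matter_logjac", lj$t0, lj$t3, lj$t12)
  }

  anovas <- purrr::map_dfr(c("acute", "chronic"), function(st) {
    module_dispersion_anova(changes$within_module_fc[[st]], partition) |>
      mutate(stage = st)
  })

  modularity_by_tp <- purrr::map_dfr(tps, function(tp) {
    part_t <- louvain_partition(fc_group[[tp]], gamma = ana$gamma,
                                seed = seed + 31L,
                                n_restarts = ana$louvain_restarts)
    tibble(timepoint = tp, Q = attr(part_t, "Q"),
           n_modules = attr(part_t, "n_modules"))
  })

  gamma_sweep <- purrr::map_dfr(ana$gamma_grid, function(g) {
    part_g <- louvain_partition(fc_group$t0, gamma = g, seed = seed + 41L,
                                n_restarts = ana$louvain_restarts)
    tibble(gamma = g, Q = attr(part_g, "Q"),
           n_modules = attr(part_g, "n_modules"))
  })

  # ---- write report bundle --------------------------------------------------
  tsv <- function(x, name) readr::write_tsv(x, file.path(out_dir, name))
  write_partition(partition, file.path(out_dir, "partition.tsv"))
  for (tp in tps) tsv(metrics[[tp]], paste0("node_metrics_", tp, ".tsv"))
  changes_long <- purrr::map_dfr(names(changes), function(m) {
    purrr::map_dfr(names(changes[[m]]), function(st) {
      mutate(as_tibble(changes[[m]][[st]]), metric = m, stage = st)
    })
  })
  tsv(changes_long, "stage_changes.tsv")
  reg_table <- purrr::map_dfr(names(fits), function(key) {
    mutate(tidy(fits[[key]]), model = key)
  })
  tsv(reg_table, "regressions.tsv")
  tsv(anovas, "dispersion_anova.tsv")
  tsv(modularity_by_tp, "modularity_by_timepoint.tsv")
  tsv(gamma_sweep, "gamma_sweep.tsv")

  summary <- list(
    seed = seed,
    gamma = ana$gamma,
    consensus = list(Q = attr(partition, "Q"),
                     n_modules = attr(partition, "n_modules"),
                     n_reps = attr(partition, "n_reps")),
    pc1_variance_explained = hub$pc1_variance_explained,
    acute_chronic_dependence = purrr::map(dependence, function(d) {
      list(metric = d$metric, t = d$observed, p_corrected = d$p,
           significant = d$significant)
    }),
    regressions = purrr::map(fits, function(f) {
      list(selected = f$selected, F = f$F, df = f$df, p = f$p_model,
           r2 = f$r2,
           beta = setNames(as.list(f$coefficients$beta),
                           f$coefficients$term))
    }),
    dispersion_anova = purrr::transpose(anovas),
    modularity_by_timepoint = purrr::transpose(modularity_by_tp),
    gamma_sweep = purrr::transpose(gamma_sweep)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    sprintf("plastnet %s on R %s", as.character(utils::packageVersion("plastnet")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("master seed: %d", seed),
    sprintf("derived seeds: consensus %d, null %d, modularity %d, sweep %d",
            seed + 11L, seed + 23L, seed + 31L, seed + 41L),
    sprintf("gamma: %g; consensus reps: %d; stepwise p_enter/p_remove: %g/%g",
            ana$gamma, ana$consensus_reps, ana$p_enter, ana$p_remove),
    sprintf("timepoints: %s", paste(tps, collapse = ", "))
  ), file.path(out_dir, "run_log.txt"))

  invisible(list(partition = partition, metrics = metrics, hubness = hub,
                 predictors = predictors, changes = changes, fits = fits,
                 dependence = dependence, anova = anovas,
                 modularity_by_timepoint = modularity_by_tp,
                 gamma_sweep = gamma_sweep, summary = summary,
                 out_dir = out_dir))
}
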