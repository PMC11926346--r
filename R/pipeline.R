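default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "reservoirMC-run",
    stages = list(simulate = TRUE, capacity = TRUE, stats = TRUE,
                  predict = FALSE),
    cohort = list(n_subjects = 20, age_min = 18, age_max = 88,
                  n_regions = 94, base_density = 0.35,
                  attenuation_rate = 0.025, weak_edge_bias = 3,
                  edge_noise_sd = 1, cognition_coupling = 0.5,
                  cognition_noise_sd = 1, input_dir = NULL),
    reservoir = list(T = 20000, washout_fraction = 0.05,
                     tau_curve_max = 35, tau_mc_min = 6, tau_mc_max = 35,
                     n_trials = 10),
    # the CoV consistency filter is opt-in here: at its classical 0.10
    # percentile it retains too few edges to reach the upper end of the
    # default density grid
    capacity = list(grid_min = 1, grid_max = 30, regional = FALSE,
                    consistency_percentile = 1.0),
    stats = list(n_perm = 10000, split_age = 53, fdr_q = 0.05,
                 n_lv = 5),
    predict = list(task = "regression", epochs = 100, n_folds = 10,
                   hidden_sizes = c(256, 512, 512, 256),
                   dropout_rate = 0.10, learning_rate = 5e-4,
                   batch_size = 64)
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills in defaults for missing keys,
#' rejects unknown keys, checks types and cross-field invariants, and
#' reports all problems at once.
#'
#' @param config path to a YAML file, or a named list
#' @return normalized configuration list of class `run_config`
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- default_run_config()
  problems <- character()
  merged <- defaults
  for (section in names(config)) {
    if (!section %in% names(defaults)) {
      problems <- c(problems, sprintf("unknown key '%s'", section))
      next
    }
    if (is.list(defaults[[section]])) {
      for (key in names(config[[section]])) {
        if (!key %in% names(defaults[[section]])) {
          problems <- c(problems,
                        sprintf("unknown key '%s.%s'", section, key))
        } else {
          expected <- defaults[[section]][[key]]
          value <- config[[section]][[key]]
          if (!is.null(expected) && is.numeric(expected) &&
              !is.numeric(value)) {
            problems <- c(problems,
                          sprintf("'%s.%s' must be numeric", section, key))
          } else {
            merged[[section]][[key]] <- value
          }
        }
      }
    } else {
      merged[[section]] <- config[[section]]
    }
  }
  r <- merged$reservoir
  if (floor(r$washout_fraction * r$T) < r$tau_curve_max) {
    problems <- c(problems, sprintf(
      "washout (%d steps) smaller than the maximum delay (%d)",
      floor(r$washout_fraction * r$T), r$tau_curve_max))
  }
  if (merged$capacity$grid_min < 1 || merged$capacity$grid_max > 100 ||
      merged$capacity$grid_min > merged$capacity$grid_max) {
    problems <- c(problems, "invalid capacity grid")
  }
  if (isTRUE(merged$stages$capacity) && !isTRUE(merged$stages$simulate) &&
      is.null(merged$cohort$input_dir)) {
    problems <- c(problems,
                  "capacity stage enabled without simulate stage or cohort.input_dir")
  }
  if (!is.null(merged$cohort$input_dir) &&
      !dir.exists(merged$cohort$input_dir)) {
    problems <- c(problems,
                  sprintf("cohort.input_dir does not exist: %s",
                          merged$cohort$input_dir))
  }
  if (length(problems)) {
    stopf("invalid configuration:\n  - %s", paste(problems, collapse = "\n  - "))
  }
  class(merged) <- "run_config"
  merged
}

#' Run the full pipeline: simulate, capacity, stats, prediction
#'
#' Executes the enabled stages in order, writing each stage's outputs under
#' `out_dir` and returning a manifest with seeds, the parameter set and
#' per-file MD5 checksums, sufficient to reproduce every deterministic
#' output.
#'
#' @param config a `run_config` from [validate_config()] (or anything it
#'   accepts)
#' @return manifest list (also written to `out_dir/manifest.yaml`)
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      marker <- file.path(config$out_dir, paste0(name, ".failed"))
      writeLines(conditionMessage(e), marker)
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  cohort <- NULL
  if (isTRUE(config$stages$simulate)) {
    cohort <- run_stage("simulate", function() {
      p <- config$cohort
      params <- aging_model_params(
        n_regions = p$n_regions, base_density = p$base_density,
        attenuation_rate = p$attenuation_rate,
        weak_edge_bias = p$weak_edge_bias, edge_noise_sd = p$edge_noise_sd,
        cognition_coupling = p$cognition_coupling,
        cognition_noise_sd = p$cognition_noise_sd,
        seed = substream_seed(config$seed, "cohort"))
      co <- generate_cohort(p$n_subjects, c(p$age_min, p$age_max), params)
      dir <- file.path(config$out_dir, "cohort")
      write_cohort(co, dir)
      outputs <<- c(outputs, file.path(dir, "cohort.tsv"))
      co
    })
  } else if (!is.null(config$cohort$input_dir)) {
    cohort <- read_cohort(config$cohort$input_dir)
  }

  profiles <- NULL
  if (isTRUE(config$stages$capacity)) {
    profiles <- run_stage("capacity", function() {
      r <- config$reservoir
      protocol <- reservoir_protocol(
        T = r$T, washout_fraction = r$washout_fraction,
        tau_curve = seq_len(r$tau_curve_max),
        tau_mc = r$tau_mc_min:r$tau_mc_max, n_trials = r$n_trials,
        master_seed = substream_seed(config$seed, "reservoir"))
      mask <- consistency_filter(cohort$connectomes,
                                 config$capacity$consistency_percentile)
      grid <- config$capacity$grid_min:config$capacity$grid_max
      prof <- cohort_capacity_profiles(cohort$connectomes, protocol, grid,
                                       regional = config$capacity$regional,
                                       mask = mask)
      path <- file.path(config$out_dir, "profiles.tsv")
      write.table(capacity_long_table(prof), path, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      feat <- capacity_feature_table(prof)
      fpath <- file.path(config$out_dir, "features.tsv")
      write.table(feat, fpath, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <<- c(outputs, path, fpath)
      prof
    })
  }

  if (isTRUE(config$stages$stats) && !is.null(profiles)) {
    run_stage("stats", function() {
      meta <- cohort$metadata
      groups <- ifelse(meta$age <= config$stats$split_age, "young", "old")
      res <- list()
      if (length(unique(groups)) == 2) {
        dd <- density_difference_curve(
          profiles, factor(groups, levels = c("old", "young")),
          n_perm = config$stats$n_perm,
          seed = substream_seed(config$seed, "perm"))
        path <- file.path(config$out_dir, "density_differences.tsv")
        write.table(dd, path, sep = "\t", quote = FALSE, row.names = FALSE)
        outputs <<- c(outputs, path)
      }
      feat <- capacity_feature_table(profiles)
      fit <- auc_linear_model(feat$auc_high, meta$age, meta$sex)
      lm_path <- file.path(config$out_dir, "auc_models.tsv")
      write.table(
        data.frame(band = "high",
                   explained_variance_pct = fit$explained_variance_pct,
                   p_age = fit$p_age),
        lm_path, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <<- c(outputs, lm_path)
      if (!is.null(profiles[[1]]$regional_mc)) {
        reg <- t(vapply(profiles, function(p) {
          rowMeans(p$regional_mc[, match(density_bands()$high, p$densities),
                                 drop = FALSE])
        }, numeric(nrow(profiles[[1]]$regional_mc))))
        assoc <- regional_age_association(reg, meta$age, meta$sex,
                                          q = config$stats$fdr_q)
        rpath <- file.path(config$out_dir, "regional_associations.tsv")
        write.table(assoc, rpath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        outputs <<- c(outputs, rpath)
      }
      res
    })
  }

  if (isTRUE(config$stages$predict) && !is.null(profiles)) {
    run_stage("predict", function() {
      p <- config$predict
      feat <- capacity_feature_table(profiles)
      features <- as.matrix(feat[, setdiff(colnames(feat), "subject_id")])
      cfg <- predictor_config(
        hidden_sizes = p$hidden_sizes, dropout_rate = p$dropout_rate,
        task = p$task, learning_rate = p$learning_rate,
        batch_size = p$batch_size, epochs = p$epochs, n_folds = p$n_folds,
        seed = substream_seed(config$seed, "mlp"))
      targets <- if (p$task == "regression") cohort$metadata$age else
        as.integer(cohort$metadata$age > config$stats$split_age)
      cv <- cross_validate_predictor(features, targets, cfg)
      path <- file.path(config$out_dir, "prediction_metrics.tsv")
      write.table(
        data.frame(metric = cv$metric, mean = cv$summary["mean"],
                   sd = cv$summary["sd"]),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <<- c(outputs, path)
      cv
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("reservoirMC")),
    seed = config$seed,
    parameter_hash = substream_seed(paste(deparse(unclass(config)),
                                          collapse = "")),
    outputs = lapply(outputs, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  manifest
}
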