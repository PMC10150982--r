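#' Default end-to-end run configuration
#'
#' All analysis defaults in one nested list: 0.1-day maturity bins with a
#' 30-rendition floor, 0.6-day overnight gap rule, 5-minute query grid with
#' a 30-minute / 30-rendition support window, percentile levels
#' 1/5/25/50/75/95/99, 80/20 evaluation split, Adam learning rate 0.001 and
#' 1000 permutations (overridable per block). The `synthetic` block takes
#' any [ground_truth_params()] argument.
#'
#' @param seed master seed for the run.
#' @param out_dir output directory for stage artifacts.
#' @return Nested configuration list (class `run_config`).
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("songdev_run_")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = c("synthetic", "maturity", "devmodel", "entropy", "simulate",
               "shifts"),
    syllables = NULL,                     # NULL = all
    dataset_path = NULL,                  # alternative to the synthetic stage
    synthetic = list(),
    split = list(eval_fraction = 0.2),
    features = list(variance_threshold = 0.99),
    maturity = list(architecture = "pyramid", n_permutations = 1000),
    devmodel = list(architecture = "narrow64", lr = 1e-3),
    entropy = list(interval_min = 5, window_min = 30, min_count = 30),
    shifts = list(bin_width = 0.1, levels = c(1, 5, 25, 50, 75, 95, 99),
                  min_n = 30, max_gap = 0.6)
  ), class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config a `run_config` list.
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config` that round-trips
#'   `write_run_config` unchanged.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  out <- utils::modifyList(unclass(base), cfg)
  class(out) <- "run_config"
  out
}

stage_deps <- list(
  synthetic = character(0),
  maturity = "data",
  devmodel = "data",
  entropy = "devmodel",
  simulate = c("devmodel", "entropy"),
  shifts = c("maturity", "simulate")
)

#' Run the full analysis pipeline
#'
#' Executes the selected stages in dependency order for every syllable:
#' synthetic generation (or dataset loading), 80/20 split, maturity-model
#' training and prediction, density-model training, entropy trajectories,
#' baseline and fixed-entropy simulations, and overnight-shift extraction
#' with the pooled mixed-effects analyses. Stage tables are written as CSV
#' under `config$out_dir` and a manifest records checksums, timings and
#' warnings.
#'
#' @param config a [default_run_config()]-style list.
#' @return Object of class `run_manifest`; results are attached as the
#'   `results` element (dataset, per-syllable models, entropy samples, shift
#'   records, fitted LMMs).
#' @export
run_pipeline <- function(config = default_run_config()) {
  cfg <- utils::modifyList(unclass(default_run_config()), unclass(config))
  stages <- cfg$stages
  known <- names(stage_deps)
  if (length(setdiff(stages, known)) > 0)
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  have_data <- "synthetic" %in% stages || !is.null(cfg$dataset_path)
  for (st in stages) {
    deps <- stage_deps[[st]]
    deps <- replace(deps, deps == "data", if (have_data) st else "a data source")
    missing <- setdiff(deps, c(stages, st))
    if (length(missing) > 0)
      stop(sprintf("stage '%s' requires missing stage(s): %s", st,
                   paste(missing, collapse = ", ")))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  timings <- numeric(0)
  results <- list()
  run_stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- withCallingHandlers(
      tryCatch(force(code), error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)),
      warning = function(w) {
        warnings_log <<- c(warnings_log, sprintf("[%s] %s", name,
                                                 conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  dataset <- run_stage("data", {
    if (!is.null(cfg$dataset_path)) read_dataset(cfg$dataset_path)
    else {
      pars <- do.call(ground_truth_params,
                      utils::modifyList(list(seed = cfg$seed), cfg$synthetic))
      generate_dataset(pars)
    }
  })
  results$dataset <- dataset
  if ("synthetic" %in% stages)
    write_dataset(dataset, file.path(cfg$out_dir, "renditions.csv"))

  syl_ids <- cfg$syllables %||% dataset$syllables$syllable_id
  results$syllables <- list()
  entropy_samples <- list(); pred_real <- list(); pred_sim <- list()
  for (sid in syl_ids) {
    syl <- syllable_renditions(dataset, sid)
    parts <- run_stage("split",
                       split_dataset(syl, cfg$split$eval_fraction, cfg$seed))
    # per-syllable principal axes at effective dimensionality (training side)
    feats <- run_stage("features",
      fit_pca_features(latent_matrix(parts$train),
                       cfg$features$variance_threshold))
    parts$train <- pca_project_renditions(feats, parts$train)
    parts$eval <- pca_project_renditions(feats, parts$eval)
    res <- list(split = parts, features = feats)
    if ("maturity" %in% stages) {
      res$maturity <- run_stage("maturity",
        train_age_net(parts$train, architecture = cfg$maturity$architecture,
                      seed = cfg$seed))
      pe <- parts$eval
      pe$predicted_age <- predict_age(res$maturity, pe)
      pred_real[[sid]] <- pe
    }
    if ("devmodel" %in% stages) {
      res$devmodel <- run_stage("devmodel",
        train_dev_model(parts$train, architecture = cfg$devmodel$architecture,
                        seed = cfg$seed, lr = cfg$devmodel$lr))
    }
    if ("entropy" %in% stages) {
      dw <- if (!is.null(dataset$params)) dataset$params$day_window else
        range(syl$time_of_day_h)
      res$query_times <- run_stage("entropy",
        sample_query_times(parts$train, day_window = dw,
                           interval_min = cfg$entropy$interval_min,
                           window_min = cfg$entropy$window_min,
                           min_count = cfg$entropy$min_count))
      res$entropy <- run_stage("entropy",
        entropy_trajectory(res$devmodel, res$query_times))
      entropy_samples[[sid]] <- res$entropy
    }
    if ("simulate" %in% stages) {
      res$targets <- run_stage("simulate",
        daily_min_det(res$devmodel, res$query_times))
      for (mode in c("baseline", "fixed_entropy")) {
        sim <- run_stage("simulate",
          simulate_development(res$devmodel, parts$eval, mode = mode,
                               seed = cfg$seed, targets = res$targets))
        sim$predicted_age <- predict_age(res$maturity, sim)
        pred_sim[[paste(sid, mode)]] <- sim
      }
    }
    results$syllables[[sid]] <- res
  }

  if ("entropy" %in% stages && length(entropy_samples) > 0) {
    samples <- do.call(rbind, entropy_samples)
    write.csv(samples, file.path(cfg$out_dir, "entropy_samples.csv"),
              row.names = FALSE)
    results$entropy_samples <- samples
    results$entropy_lmm <- run_stage("entropy",
                                     fit_entropy_lmm(samples, "tod_only"))
  }
  if ("shifts" %in% stages) {
    sh <- cfg$shifts
    if (length(pred_real) > 0) {
      real <- do.call(rbind, pred_real)
      bins <- run_stage("shifts",
        bin_and_quantile(real, sh$bin_width, sh$levels, sh$min_n))
      results$real_shifts <- run_stage("shifts",
                                       overnight_shifts(bins, sh$max_gap))
      if (nrow(results$real_shifts) > 0)
        results$real_shift_lmm <- run_stage("shifts",
          fit_shift_lmm(results$real_shifts))
    }
    if (length(pred_sim) > 0) {
      cols <- Reduce(intersect, lapply(pred_sim, names))
      sim <- do.call(rbind, lapply(pred_sim, function(d) d[cols]))
      bins <- run_stage("shifts",
        bin_and_quantile(sim, sh$bin_width, sh$levels, sh$min_n))
      results$sim_shifts <- run_stage("shifts",
                                      overnight_shifts(bins, sh$max_gap))
      write.csv(results$sim_shifts,
                file.path(cfg$out_dir, "sim_shift_records.csv"),
                row.names = FALSE)
      if (length(unique(results$sim_shifts$condition)) == 2)
        results$sim_shift_lmm <- run_stage("shifts",
          fit_shift_lmm(results$sim_shifts, with_condition = TRUE))
    }
  }

  cfg_path <- file.path(cfg$out_dir, "run_config.yaml")
  write_run_config(structure(cfg, class = "run_config"), cfg_path)
  files <- list.files(cfg$out_dir, full.names = TRUE)
  manifest <- structure(list(
    config = cfg,
    config_hash = unname(tools::md5sum(cfg_path)),
    version = as.character(utils::packageVersion("songdev")),
    checksums = tools::md5sum(files[!grepl("run_config", files)]),
    timings = timings,
    warnings = warnings_log,
    results = results
  ), class = "run_manifest")
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> songdev %s, config %s\n", x$version,
              substr(x$config_hash, 1, 8)))
  cat(sprintf("  stages timed: %s\n",
              paste(sprintf("%s %.1fs", names(x$timings), x$timings),
                    collapse = ", ")))
  if (length(x$warnings) > 0)
    cat("  warnings:\n", paste("   -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' Validate a rendition dataset
#'
#' Checks the flat-table schema (required columns, finite latents,
#' time-of-day range, day/age consistency, constant latent dimensionality
#' within each syllable) and summarises per-syllable counts and age ranges.
#'
#' @param x a `songdev_dataset`, a rendition data frame, or a CSV path.
#' @return Object of class `dataset_report`: `ok` flag, `issues` (character,
#'   with offending row numbers) and a per-syllable `summary` data frame.
#' @export
validate_dataset <- function(x) {
  df <- if (is.character(x)) read_dataset(x)$renditions
        else if (inherits(x, "songdev_dataset")) x$renditions
        else x
  issues <- character(0)
  required <- c("bird_id", "syllable_id", "age_dph", "time_of_day_h",
                "day_index")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    issues <- c(issues, paste("missing column(s):",
                              paste(missing, collapse = ", ")))
  if (length(missing) == 0) {
    bad_tod <- which(df$time_of_day_h < 0 | df$time_of_day_h >= 24)
    if (length(bad_tod) > 0)
      issues <- c(issues, paste("time_of_day_h outside [0, 24) at row(s):",
                                paste(head(bad_tod, 5), collapse = ", ")))
    bad_day <- which(floor(df$age_dph) != df$day_index)
    if (length(bad_day) > 0)
      issues <- c(issues, paste("floor(age_dph) != day_index at row(s):",
                                paste(head(bad_day, 5), collapse = ", ")))
    zc <- latent_cols(df)
    if (length(zc) == 0) issues <- c(issues, "no latent columns z1..zk")
  }
  summary_df <- NULL
  if (length(issues) == 0) {
    per <- split(df, df$syllable_id)
    summary_df <- do.call(rbind, lapply(per, function(d) {
      z <- as.matrix(d[latent_cols(d)])
      filled <- colSums(!is.na(z)) > 0
      kk <- sum(filled)
      partial <- any(colSums(is.na(z[, filled, drop = FALSE])) %% nrow(z) != 0)
      if (partial)
        issues <<- c(issues, paste("mixed latent dimensionality within",
                                   d$syllable_id[1]))
      if (any(!is.finite(z[, filled])) && !partial)
        issues <<- c(issues, paste("non-finite latents in", d$syllable_id[1]))
      data.frame(bird_id = d$bird_id[1], syllable_id = d$syllable_id[1],
                 n = nrow(d), k = kk,
                 age_min = min(d$age_dph), age_max = max(d$age_dph))
    }))
    rownames(summary_df) <- NULL
  }
  structure(list(ok = length(issues) == 0, issues = issues,
                 summary = summary_df),
            class = "dataset_report")
}

#' @export
print.dataset_report <- function(x, ...) {
  if (x$ok) {
    cat("<dataset_report> OK\n")
    print(x$summary, row.names = FALSE)
  } else {
    cat("<dataset_report> FAILED\n", paste(" -", x$issues, collapse = "\n"),
        "\n")
  }
  invisible(x)
}
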