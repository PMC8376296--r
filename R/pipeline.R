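#' Analysis configuration
#'
#' @param ... overrides for any default field: `seed` (mixture fit),
#'   `front_led`, `half_window` (LI), `stillness_window`,
#'   `stillness_fraction`, `run_length` (bout detection), `windows` (named
#'   list of response windows, ms), `baseline_window`, `detect_window`,
#'   `excitation_method`, `regressors` (character vector used for the GLM),
#'   `select_regressors` (if TRUE, derive movement regressors by SMC
#'   filtering + factor analysis instead of using the fixed list),
#'   `min_response_ratio` (session inclusion, default 0.8),
#'   `min_trials_glm`, `epoch_windows`, `epoch_length_s`.
#' @return named list of class `vp_analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    seed = 1L, front_led = "red", half_window = 4L,
    stillness_window = 30L, stillness_fraction = 0.7, run_length = 4L,
    windows = list(overall = c(40, 400), early = c(40, 180),
                   late = c(180, 400)),
    baseline_window = c(-1000, 0), detect_window = c(40, 180),
    excitation_method = "normal",
    regressors = c("radial_velocity_max", "move_duration_s",
                   "angular_velocity_sd", "path_efficiency",
                   "net_heading_change_rad", "turn_efficiency",
                   "movement_onset_latency_s", "lever_distance_mm",
                   "time_since_reward_s", "time_since_cue_s"),
    select_regressors = FALSE, smc_tolerance = 0.8,
    strong_loading = 0.6, independent_loading = 0.4,
    min_response_ratio = 0.8, min_trials_glm = 10L,
    epoch_windows = list(early = c(40, 180), late = c(180, 400)),
    epoch_length_s = 2700, min_epoch_trials = 10L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown analysis_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "vp_analysis_config")
}

#' Behavioral session summary
#'
#' Response ratios (responded / presented) per cue type, with mean and SD of
#' the movement-onset latency and of the mean approach speed over responded
#' trials.
#'
#' @param trials data frame from [classify_trials()].
#' @param features optional feature table from [trial_features()] supplying
#'   `speed_mean`.
#' @return data frame with one row per cue type present: `cue_type`,
#'   `n_presented`, `n_responded`, `response_ratio`, `latency_mean_s`,
#'   `latency_sd_s`, `speed_mean_mm_s`, `speed_sd_mm_s`.
#' @export
summarize_behavior <- function(trials, features = NULL) {
  rows <- lapply(c("DS", "NS"), function(tp) {
    sel <- trials$cue_type == tp
    if (!any(sel)) return(NULL)
    resp <- sel & trials$responded %in% TRUE
    lat <- trials$movement_onset_latency_s[resp]
    lat <- lat[!is.na(lat)]
    sp <- if (!is.null(features)) {
      v <- features$speed_mean[features$cue_type == tp &
                                 features$responded %in% TRUE]
      v[!is.na(v)]
    } else numeric(0)
    data.frame(cue_type = tp, n_presented = sum(sel),
               n_responded = sum(resp),
               response_ratio = sum(resp) / sum(sel),
               latency_mean_s = if (length(lat)) mean(lat) else NA_real_,
               latency_sd_s = if (length(lat) > 1L) sd(lat) else NA_real_,
               speed_mean_mm_s = if (length(sp)) mean(sp) else NA_real_,
               speed_sd_mm_s = if (length(sp) > 1L) sd(sp) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

subset_counts <- function(counts, rows) {
  structure(list(counts = counts$counts[rows, , drop = FALSE],
                 bin_edges_ms = counts$bin_edges_ms,
                 align_times = counts$align_times[rows],
                 bin_ms = counts$bin_ms),
            class = "vp_counts")
}

#' Full single-session analysis
#'
#' Runs the complete pipeline on one session: head pose, locomotor index,
#' mixture thresholds, movement bouts, trial classification, trial features,
#' behavioral summary, per-neuron excitation detection (on still-at-cue DS
#' trials), per-neuron Poisson GLMs with IDR Firing Differences for each
#' response window (cue-excited neurons only, correct still-at-cue DS
#' trials), population tests with Holm correction, and — when the manifest
#' carries an infusion time — the Q2-on-Q1 epoch regression. Sessions whose
#' DS response ratio falls below `min_response_ratio` are excluded from the
#' GLM stage (tables returned empty, reason recorded).
#'
#' @param bundle `vp_session`.
#' @param config `vp_analysis_config` (default `analysis_config()`).
#' @param out_dir optional directory; when given, every stage's table is
#'   persisted as CSV/JSON.
#' @return list of class `vp_results`: `thresholds`, `bouts`, `trials`,
#'   `features`, `summary`, `excitation`, `selection` (NULL unless
#'   `select_regressors`), `regressors`, `glm_effects`, `population`,
#'   `epochs` (or NULL), `excluded_reason` (NA or why the GLM stage was
#'   skipped), `config`.
#' @export
analyze_session <- function(bundle, config = analysis_config(),
                            out_dir = NULL) {
  fr <- bundle$manifest$frame_rate_hz
  lever <- as.numeric(unlist(bundle$manifest$lever_xy_mm))
  pose <- head_pose(bundle, front_led = config$front_led)
  li <- locomotor_index(pose, half_window = config$half_window)
  thr <- fit_li_mixture(li, seed = config$seed)
  bouts <- detect_bouts(li, thr, stillness_window = config$stillness_window,
                        stillness_fraction = config$stillness_fraction,
                        run_length = config$run_length, frame_rate = fr)
  trials <- classify_trials(bouts, bundle$events, li, thr, frame_rate = fr)
  features <- trial_features(trials, pose, bundle$events, lever)
  summary_tab <- summarize_behavior(trials, features)
  spikes_by_neuron <- split(bundle$spikes$time_s, bundle$spikes$neuron_id)
  ids <- names(spikes_by_neuron)
  align_all <- features$cue_onset_s
  counts_by_neuron <- lapply(spikes_by_neuron, align_counts,
                             align_times = align_all, window = c(-1000, 400))
  still_ds <- which(features$cue_type == "DS" & features$still_at_cue %in% TRUE)
  excitation <- do.call(rbind, lapply(ids, function(id) {
    cts <- subset_counts(counts_by_neuron[[id]], still_ds)
    if (nrow(cts$counts) < 10L)
      return(data.frame(neuron_id = id, excited = NA, onset_ms = NA_real_,
                        baseline_mean_hz = NA_real_, baseline_sd_hz = NA_real_,
                        z_early = NA_real_, z_late = NA_real_,
                        rate_overall_hz = NA_real_, stringsAsFactors = FALSE))
    ex <- detect_excitation(cts, baseline_window = config$baseline_window,
                            detect_window = config$detect_window,
                            method = config$excitation_method)
    data.frame(neuron_id = id, excited = ex$excited,
               onset_ms = ex$onset_bin_ms,
               baseline_mean_hz = ex$baseline_mean_hz,
               baseline_sd_hz = ex$baseline_sd_hz,
               z_early = ex$z_early, z_late = ex$z_late,
               rate_overall_hz = ex$rate_overall_hz, stringsAsFactors = FALSE)
  }))

  ds_row <- summary_tab[summary_tab$cue_type == "DS", , drop = FALSE]
  excluded <- NA_character_
  if (nrow(ds_row) == 0L || ds_row$response_ratio < config$min_response_ratio)
    excluded <- sprintf("DS response ratio %.2f below %.2f",
                        if (nrow(ds_row)) ds_row$response_ratio else NA,
                        config$min_response_ratio)

  selection <- NULL
  regressors <- config$regressors
  if (is.na(excluded) && isTRUE(config$select_regressors)) {
    movement_vars <- c("radial_velocity_mean", "radial_velocity_max",
                       "radial_velocity_sd", "speed_mean", "speed_sd",
                       "speed_max", "move_duration_s", "path_length_mm",
                       "latency_max_speed_s", "latency_max_accel_s",
                       "max_path_deviation_mm", "turn_efficiency",
                       "angular_velocity_sd", "angular_velocity_max",
                       "angular_velocity_mean", "net_heading_change_rad",
                       "path_efficiency", "movement_onset_latency_s")
    ana <- features[features$cue_type == "DS" &
                      features$still_at_cue %in% TRUE &
                      features$responded %in% TRUE, movement_vars,
                    drop = FALSE]
    ana <- ana[stats::complete.cases(ana), , drop = FALSE]
    flt <- filter_multicollinear(ana, tolerance = config$smc_tolerance)
    kept <- ana[, flt$retained, drop = FALSE]
    pk <- pca_factor_count(kept)
    fm <- factor_model(kept, max(2L, pk$n_factors))
    sel_tab <- select_regressors(fm, strong = config$strong_loading,
                                 independent = config$independent_loading)
    selection <- list(filter = flt, eigenvalues = pk$eigenvalues,
                      n_factors = pk$n_factors, model = fm, table = sel_tab)
    regressors <- c(sel_tab$variable,
                    c("lever_distance_mm", "time_since_reward_s",
                      "time_since_cue_s"))
  }

  glm_effects <- NULL
  population <- NULL
  if (is.na(excluded)) {
    excited_ids <- excitation$neuron_id[excitation$excited %in% TRUE]
    eff_rows <- list()
    for (wname in names(config$windows)) {
      win <- config$windows[[wname]]
      ifd_mat <- NULL
      for (id in excited_ids) {
        des <- build_design(features, counts_by_neuron[[id]], win, regressors)
        if (!des$fittable) next
        fit <- tryCatch(fit_poisson_glm(des), error = function(e) NULL)
        if (is.null(fit) || !fit$converged) next
        eff <- fit$effects[fit$effects$term != "(Intercept)", , drop = FALSE]
        eff$neuron_id <- id
        eff$window <- wname
        eff_rows[[length(eff_rows) + 1L]] <- eff
        v <- setNames(eff$ifd_percent, eff$term)
        ifd_mat <- rbind(ifd_mat, v[regressors])
      }
      if (!is.null(ifd_mat) && nrow(ifd_mat) >= 3L) {
        colnames(ifd_mat) <- regressors
        population <- rbind(population,
                            population_ifd_tests(ifd_mat, window = wname))
      }
    }
    glm_effects <- if (length(eff_rows)) do.call(rbind, eff_rows) else NULL
  }

  epochs <- NULL
  t_inf <- bundle$manifest$infusion_time_s
  if (!is.null(t_inf) && !is.na(t_inf)) {
    epochs <- do.call(rbind, lapply(names(config$epoch_windows), function(wn) {
      prs <- epoch_pairs(bundle, window = config$epoch_windows[[wn]],
                         epoch_length_s = config$epoch_length_s,
                         min_trials = config$min_epoch_trials)
      prs <- prs[prs$neuron_id %in%
                   excitation$neuron_id[excitation$excited %in% TRUE], ,
                 drop = FALSE]
      if (nrow(prs) < 5L) return(NULL)
      reg <- paired_epoch_regression(
        prs, condition = bundle$manifest$infusion_condition %||% "unknown")
      data.frame(window = wn, condition = reg$condition, n = reg$n,
                 slope = reg$slope, slope_se = reg$slope_se,
                 intercept = reg$intercept, intercept_se = reg$intercept_se,
                 p_intercept0 = reg$p_intercept0, p_slope0 = reg$p_slope0,
                 p_slope1 = reg$p_slope1, stringsAsFactors = FALSE)
    }))
  }

  res <- structure(list(thresholds = thr, bouts = bouts, trials = trials,
                        features = features, summary = summary_tab,
                        excitation = excitation, selection = selection,
                        regressors = regressors, glm_effects = glm_effects,
                        population = population, epochs = epochs,
                        excluded_reason = excluded, config = config),
                   class = "vp_results")
  if (!is.null(out_dir)) persist_results(res, out_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

persist_results <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wr <- function(df, name) if (!is.null(df))
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wr(res$bouts, "bouts.csv")
  wr(res$trials, "trials.csv")
  wr(res$features, "features.csv")
  wr(res$summary, "summary.csv")
  wr(res$excitation, "excitation.csv")
  wr(res$glm_effects, "glm_effects.csv")
  wr(res$population, "population.csv")
  wr(res$epochs, "epoch_regression.csv")
  meta <- list(regressors = res$regressors,
               excluded_reason = res$excluded_reason,
               onset_threshold = res$thresholds$onset_threshold,
               offset_threshold = res$thresholds$offset_threshold,
               windows = res$config$windows,
               seed = res$config$seed)
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.vp_results <- function(x, ...) {
  cat("<vp_results>\n")
  cat(sprintf("  %d bouts, %d trials, %d neurons (%d excited)\n",
              nrow(x$bouts), nrow(x$trials), nrow(x$excitation),
              sum(x$excitation$excited %in% TRUE)))
  if (!is.na(x$excluded_reason))
    cat("  GLM stage skipped:", x$excluded_reason, "\n")
  if (!is.null(x$population)) {
    cat("  population tests:\n")
    print(x$population[, c("regressor", "window", "mean_ifd", "t", "p_holm",
                           "significant")], digits = 3)
  }
  invisible(x)
}
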