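#' Epoch-restricted response Z-score for one neuron
#'
#' Z-score of the response-window firing rate relative to the 1-s pre-cue
#' baseline (same statistic as [response_zscore()]), computed from the DS
#' trials whose cue onsets fall inside the given epoch.
#'
#' @param spike_times numeric spike times (s) or data frame with `time_s`.
#' @param events event-log data frame.
#' @param epoch length-2 numeric, epoch interval in seconds `[lo, hi)`.
#' @param window ms pair, response window (e.g. `c(40, 180)`).
#' @param min_trials minimum DS trials required (default 10).
#' @return list with `z`, `n_trials`, `ok` (FALSE when too few trials or a
#'   degenerate baseline).
#' @export
epoch_response_zscores <- function(spike_times, events, epoch, window,
                                   min_trials = 10L) {
  cues <- cue_table(events)
  on_t <- cues$onset_s[cues$cue_type == "DS" &
                         cues$onset_s >= epoch[1L] & cues$onset_s < epoch[2L]]
  if (length(on_t) < min_trials)
    return(list(z = NA_real_, n_trials = length(on_t), ok = FALSE))
  counts <- align_counts(spike_times, on_t, window = c(-1000, 400))
  z <- response_zscore(counts, window)
  list(z = as.numeric(z), n_trials = length(on_t),
       ok = is.finite(z))
}

#' Build pre/post-infusion epoch pairs for all neurons
#'
#' Q1 is the 45 minutes before the infusion marker and Q2 the 45 minutes
#' after it; each neuron with enough DS trials and a valid Z-score in both
#' epochs contributes one pair per response window.
#'
#' @param bundle `vp_session` whose manifest carries `infusion_time_s`.
#' @param window ms pair.
#' @param epoch_length_s epoch length (default 2700 s = 45 min).
#' @param min_trials per-epoch minimum DS trials (default 10).
#' @return data frame `neuron_id`, `z_q1`, `z_q2`, `n_q1`, `n_q2`.
#' @export
epoch_pairs <- function(bundle, window = c(40, 180), epoch_length_s = 2700,
                        min_trials = 10L) {
  t_inf <- bundle$manifest$infusion_time_s
  if (is.null(t_inf) || is.na(t_inf))
    stop("manifest has no infusion_time_s; epochs undefined")
  q1 <- c(t_inf - epoch_length_s, t_inf)
  q2 <- c(t_inf, t_inf + epoch_length_s)
  by_neuron <- split(bundle$spikes$time_s, bundle$spikes$neuron_id)
  rows <- lapply(names(by_neuron), function(id) {
    st <- by_neuron[[id]]
    a <- epoch_response_zscores(st, bundle$events, q1, window, min_trials)
    b <- epoch_response_zscores(st, bundle$events, q2, window, min_trials)
    if (!a$ok || !b$ok) return(NULL)
    data.frame(neuron_id = id, z_q1 = a$z, z_q2 = b$z,
               n_q1 = a$n_trials, n_q2 = b$n_trials,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(neuron_id = character(), z_q1 = numeric(),
                      z_q2 = numeric(), n_q1 = integer(), n_q2 = integer(),
                      stringsAsFactors = FALSE)
  out
}

#' Regression of post-infusion on pre-infusion Z-scores
#'
#' Ordinary least squares of each neuron's post-infusion Z-score (Q2) on its
#' pre-infusion Z-score (Q1), with t tests for intercept = 0, slope = 0 and
#' slope = 1 (all with df = n - 2). A slope significantly below 1 indicates
#' attenuation of cue-evoked responses after the infusion.
#'
#' @param pairs data frame from [epoch_pairs()] (columns `z_q1`, `z_q2`).
#' @param condition label recorded in the output.
#' @return object of class `vp_epoch_regression`: list with `slope`,
#'   `slope_se`, `intercept`, `intercept_se`, `n`, `df`, `t_intercept0`,
#'   `p_intercept0`, `t_slope0`, `p_slope0`, `t_slope1`, `p_slope1`,
#'   `condition`, `degenerate` (TRUE when residual variance is zero).
#' @export
paired_epoch_regression <- function(pairs, condition = "unspecified") {
  stopifnot(nrow(pairs) >= 5L)
  if (stats::var(pairs$z_q1) == 0)
    stop("zero variance in pre-infusion Z-scores; slope undefined")
  fit <- lm(z_q2 ~ z_q1, data = pairs)
  n <- nrow(pairs)
  sm <- summary(fit)$coefficients
  b0 <- sm[1L, 1L]; se0 <- sm[1L, 2L]
  b1 <- sm[2L, 1L]; se1 <- sm[2L, 2L]
  degenerate <- sum(fit$residuals^2) < 1e-20
  tstat <- function(est, se, null) {
    if (degenerate || se == 0) {
      # a perfect fit has no residual scale: the comparison is exact
      if (abs(est - null) < 1e-9) return(0)
      return(Inf * sign(est - null))
    }
    (est - null) / se
  }
  t0 <- tstat(b0, se0, 0)
  t1 <- tstat(b1, se1, 0)
  tv1 <- tstat(b1, se1, 1)
  pfun <- function(t) {
    if (!is.finite(t)) return(0)
    2 * pt(-abs(t), df = n - 2L)
  }
  structure(list(slope = b1, slope_se = se1, intercept = b0,
                 intercept_se = se0, n = n, df = n - 2L,
                 t_intercept0 = t0, p_intercept0 = pfun(t0),
                 t_slope0 = t1, p_slope0 = pfun(t1),
                 t_slope1 = tv1, p_slope1 = pfun(tv1),
                 condition = condition, degenerate = degenerate),
            class = "vp_epoch_regression")
}

#' @export
print.vp_epoch_regression <- function(x, ...) {
  cat(sprintf("<vp_epoch_regression> %s: slope %.3f +/- %.3f (n = %d)\n",
              x$condition, x$slope, x$slope_se, x$n))
  cat(sprintf("  intercept %.3f +/- %.3f; p(slope=1) = %.4g\n",
              x$intercept, x$intercept_se, x$p_slope1))
  invisible(x)
}
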