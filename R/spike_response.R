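#' Bin spikes around alignment events
#'
#' Counts spikes in consecutive half-open bins `[lo, hi)` of `bin_ms`
#' milliseconds relative to each alignment time (cue onset or movement
#' onset).
#'
#' @param spike_times numeric vector of spike times (s), strictly increasing,
#'   or a data frame with a `time_s` column.
#' @param align_times alignment times (s).
#' @param window length-2 numeric, window bounds in ms relative to alignment
#'   (must be multiples of `bin_ms`).
#' @param bin_ms bin width in ms (default 20).
#' @return object of class `vp_counts`: list with `counts` (trial x bin
#'   integer matrix), `bin_edges_ms` (length nbin + 1), `align_times`,
#'   `bin_ms`.
#' @export
align_counts <- function(spike_times, align_times, window = c(-1000, 400),
                         bin_ms = 20) {
  if (is.data.frame(spike_times)) spike_times <- spike_times$time_s
  stopifnot(length(window) == 2L, window[1L] < window[2L])
  if (any(abs(window / bin_ms - round(window / bin_ms)) > 1e-9))
    stop("window bounds must be multiples of bin_ms")
  nbin <- as.integer(round((window[2L] - window[1L]) / bin_ms))
  edges <- window[1L] + bin_ms * (0:nbin)
  ntr <- length(align_times)
  counts <- matrix(0L, nrow = ntr, ncol = nbin)
  s <- sort(spike_times)
  # locate each trial's window in the sorted train, then bin only those
  lo_t <- align_times + window[1L] / 1000
  hi_t <- align_times + window[2L] / 1000
  i_from <- findInterval(lo_t, s, left.open = TRUE) + 1L  # first spike >= lo
  i_to <- findInterval(hi_t, s, left.open = TRUE)         # last spike < hi
  for (i in seq_len(ntr)) {
    if (i_to[i] < i_from[i]) next
    rel_ms <- (s[i_from[i]:i_to[i]] - align_times[i]) * 1000
    b <- floor((rel_ms - window[1L]) / bin_ms) + 1
    b <- b[b >= 1L & b <= nbin]  # guard float edge effects
    counts[i, ] <- tabulate(b, nbins = nbin)
  }
  structure(list(counts = counts, bin_edges_ms = edges,
                 align_times = align_times, bin_ms = bin_ms),
            class = "vp_counts")
}

bin_centers <- function(x) (x$bin_edges_ms[-1L] + x$bin_edges_ms[-length(x$bin_edges_ms)]) / 2

baseline_stats <- function(counts, baseline_window) {
  sel <- which(counts$bin_edges_ms[-length(counts$bin_edges_ms)] >=
                 baseline_window[1L] &
               counts$bin_edges_ms[-1L] <= baseline_window[2L])
  rate <- colMeans(counts$counts[, sel, drop = FALSE]) / (counts$bin_ms / 1000)
  list(mean = mean(rate), sd = sd(rate), bin_rates = rate, bins = sel)
}

window_rate <- function(counts, window) {
  sel <- which(counts$bin_edges_ms[-length(counts$bin_edges_ms)] >=
                 window[1L] &
               counts$bin_edges_ms[-1L] <= window[2L])
  mean(colMeans(counts$counts[, sel, drop = FALSE])) / (counts$bin_ms / 1000)
}

#' Detect a cue-evoked excitation
#'
#' A neuron counts as cue-excited when at least `run` consecutive 20-ms bins
#' within the detection window (default 40-180 ms after cue onset) have a
#' trial-averaged firing rate above the upper bound of a 99.9% confidence
#' criterion derived from the 1-s pre-cue baseline. Two criterion
#' constructions are available: `"normal"` (default) uses baseline mean +
#' `qnorm(0.9995)` times the SD of the trial-averaged baseline bin rates;
#' `"poisson"` uses the 0.9995 quantile of the Poisson distribution of summed
#' baseline counts per bin. Response-onset latency is reported as the first
#' post-cue bin exceeding the criterion, whether or not it belongs to the
#' qualifying run.
#'
#' @param counts `vp_counts` whose window spans the baseline and detection
#'   windows.
#' @param baseline_window ms pair, default `c(-1000, 0)`.
#' @param detect_window ms pair, default `c(40, 180)`.
#' @param run consecutive supra-criterion bins required (default 3).
#' @param method `"normal"` or `"poisson"` criterion construction.
#' @return object of class `vp_excitation`: list with `excited`,
#'   `onset_bin_ms`, `baseline_mean_hz`, `baseline_sd_hz`, `ci_upper_hz`,
#'   `rate_early_hz` (40-180), `rate_late_hz` (180-400), `rate_overall_hz`
#'   (40-400), `z_early`, `z_late`, `degenerate` (TRUE when the baseline SD
#'   is zero).
#' @export
detect_excitation <- function(counts, baseline_window = c(-1000, 0),
                              detect_window = c(40, 180), run = 3L,
                              method = c("normal", "poisson")) {
  method <- match.arg(method)
  if (nrow(counts$counts) < 10L)
    stop("excitation detection requires at least 10 trials")
  bs <- baseline_stats(counts, baseline_window)
  ntr <- nrow(counts$counts)
  binw_s <- counts$bin_ms / 1000
  degenerate <- bs$sd == 0
  ci <- if (method == "normal") {
    bs$mean + qnorm(0.9995) * bs$sd
  } else {
    qpois(0.9995, lambda = max(bs$mean, 1e-12) * binw_s * ntr) / (binw_s * ntr)
  }
  lo_edges <- counts$bin_edges_ms[-length(counts$bin_edges_ms)]
  hi_edges <- counts$bin_edges_ms[-1L]
  rates <- colMeans(counts$counts) / binw_s
  det <- which(lo_edges >= detect_window[1L] & hi_edges <= detect_window[2L])
  over_det <- rates[det] > ci
  if (degenerate) over_det <- rates[det] > 0
  excited <- FALSE
  if (length(det) >= run) {
    r <- rle(over_det)
    excited <- any(r$values & r$lengths >= run)
  }
  post <- which(lo_edges >= 0)
  over_post <- if (degenerate) rates[post] > 0 else rates[post] > ci
  onset <- if (any(over_post)) lo_edges[post[which(over_post)[1L]]] else NA_real_
  r_early <- window_rate(counts, c(40, 180))
  r_late <- window_rate(counts, c(180, 400))
  r_all <- window_rate(counts, c(40, 400))
  structure(list(excited = excited, onset_bin_ms = onset,
                 baseline_mean_hz = bs$mean, baseline_sd_hz = bs$sd,
                 ci_upper_hz = ci,
                 rate_early_hz = r_early, rate_late_hz = r_late,
                 rate_overall_hz = r_all,
                 z_early = if (degenerate) NA_real_ else (r_early - bs$mean) / bs$sd,
                 z_late = if (degenerate) NA_real_ else (r_late - bs$mean) / bs$sd,
                 degenerate = degenerate, method = method),
            class = "vp_excitation")
}

#' Z-scored response rate relative to the pre-cue baseline
#'
#' Z = (mean response-window rate - baseline mean) / baseline SD, where the
#' baseline statistics are computed from the trial-averaged 20-ms bin rates
#' of the 1-s pre-cue window — the same statistics used by
#' [detect_excitation()].
#'
#' @param counts `vp_counts`.
#' @param response_window ms pair.
#' @param baseline_window ms pair, default `c(-1000, 0)`.
#' @return numeric Z (NA with a warning attribute when the baseline SD is 0).
#' @export
response_zscore <- function(counts, response_window,
                            baseline_window = c(-1000, 0)) {
  bs <- baseline_stats(counts, baseline_window)
  if (bs$sd == 0) return(structure(NA_real_, degenerate = TRUE))
  (window_rate(counts, response_window) - bs$mean) / bs$sd
}

#' Paired comparison of cue-evoked responses
#'
#' Wilcoxon signed-rank test for paired per-neuron response measures (e.g.
#' DS-evoked versus NS-evoked rate). Exact p values are used for n <= 25
#' when there are no ties or zero differences; otherwise the normal
#' approximation with continuity correction.
#'
#' @param ds_values,ns_values equal-length numeric vectors (n >= 5).
#' @return list with `V`, `p`, `n`, `exact`.
#' @export
compare_cue_responses <- function(ds_values, ns_values) {
  stopifnot(length(ds_values) == length(ns_values), length(ds_values) >= 5L)
  d <- ds_values - ns_values
  if (all(d == 0)) return(list(V = 0, p = 1, n = length(d), exact = TRUE))
  nz <- d[d != 0]
  ties <- any(duplicated(abs(nz)))
  use_exact <- length(nz) <= 25L && !ties && all(d != 0)
  wt <- suppressWarnings(
    wilcox.test(ds_values, ns_values, paired = TRUE, exact = use_exact,
                correct = TRUE))
  list(V = unname(wt$statistic), p = wt$p.value, n = length(d),
       exact = use_exact)
}

#' Quartile split of trials by movement-onset latency
#'
#' Utility for descriptive analyses that contrast short- versus long-latency
#' trials (first vs fourth latency quartile), optionally requiring a minimum
#' separation between cue onset and movement onset so that cue-aligned and
#' movement-aligned firing can be distinguished.
#'
#' @param trials data frame from [classify_trials()].
#' @param min_separation_s minimum cue-to-movement separation (default 0.2).
#' @return `trials` with rows failing the separation filter removed and a
#'   `latency_quartile` column (1-4) added.
#' @export
split_by_latency_quartile <- function(trials, min_separation_s = 0.2) {
  keep <- !is.na(trials$movement_onset_latency_s) &
    trials$movement_onset_latency_s > min_separation_s
  out <- trials[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    out$latency_quartile <- integer(0)
    return(out)
  }
  q <- quantile(out$movement_onset_latency_s, probs = c(0.25, 0.5, 0.75))
  out$latency_quartile <- 1L + (out$movement_onset_latency_s > q[1L]) +
    (out$movement_onset_latency_s > q[2L]) +
    (out$movement_onset_latency_s > q[3L])
  out
}
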