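#' @importFrom mclust Mclust mclustBIC me meV unmap
NULL

#' Locomotor index
#'
#' The locomotor index (LI) at frame `t` is the sample standard deviation of
#' the `2 * half_window + 1` consecutive head displacements
#' `d[t - half_window], ..., d[t + half_window]`, where `d[A]` is the
#' Euclidean distance between the head positions at frames `A` and `A - 1`.
#' It is near zero both at rest and during perfectly uniform translation, and
#' grows with the irregular accelerations that characterize spontaneous
#' locomotion, which makes it a robust movement-detection signal for head
#' tracking data.
#'
#' Frames whose displacement window touches a tracking gap or the series edge
#' are flagged invalid (`NA` in `li`).
#'
#' @param pose a `vp_pose` from [head_pose()], or any list with `position`
#'   (n x 2 matrix, mm) and `valid` (logical length n).
#' @param half_window window half-width in frames (default 4, i.e. 9
#'   displacements).
#' @return object of class `vp_li`: list with `li` (mm, `NA` where invalid),
#'   `valid` and `half_window`.
#' @export
locomotor_index <- function(pose, half_window = 4L) {
  stopifnot(half_window >= 1L)
  pos <- pose$position
  n <- nrow(pos)
  w <- 2L * half_window + 1L
  li <- rep(NA_real_, n)
  if (n >= w + 1L) {
    p <- pos
    p[!pose$valid, ] <- NA_real_
    d <- c(NA_real_, sqrt(rowSums((p[-1L, , drop = FALSE] -
                                     p[-n, , drop = FALSE])^2)))
    # centered rolling sample SD via rolling sums; stats::filter propagates
    # NA through any window that touches a gap or an edge
    k <- rep(1, w)
    s1 <- stats::filter(d, k, sides = 2L)
    s2 <- stats::filter(d^2, k, sides = 2L)
    var <- (s2 - s1^2 / w) / (w - 1)
    var[!is.na(var) & var < 0] <- 0  # guard tiny negative rounding
    li <- sqrt(as.numeric(var))
  }
  structure(list(li = li, valid = !is.na(li), half_window = half_window),
            class = "vp_li")
}

#' Equal-density point of two Gaussian mixture components
#'
#' Solves for the point between two component means where the weighted normal
#' densities are equal (a root of a quadratic in x). When no root lies in the
#' open interval between the means (e.g. one component dominates throughout),
#' falls back to the point in the interval where the absolute density
#' difference is smallest, and flags the result.
#'
#' @param lo,hi numeric vectors `c(weight, mean, sd)` with `lo[2] < hi[2]`.
#' @return numeric threshold with attribute `flagged` (TRUE when the fallback
#'   rule was used).
#' @export
gaussian_intersection <- function(lo, hi) {
  w1 <- lo[1]; m1 <- lo[2]; s1 <- lo[3]
  w2 <- hi[1]; m2 <- hi[2]; s2 <- hi[3]
  stopifnot(m1 < m2, s1 > 0, s2 > 0)
  if (isTRUE(all.equal(c(w1, m1, s1), c(w2, m2, s2))))
    stop("identical components have no unique intersection")
  # w1 phi((x-m1)/s1)/s1 = w2 phi((x-m2)/s2)/s2, log both sides:
  # a x^2 + b x + c = 0
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log(w1 / w2) + log(s2 / s1)
  roots <- if (abs(a) < 1e-14) {
    if (abs(b) < 1e-14) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0)
    else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > m1 & roots < m2]
  if (length(inside) >= 1L) {
    x <- inside[which.min(abs(inside - (m1 + m2) / 2))]
    return(structure(x, flagged = FALSE))
  }
  grid <- seq(m1, m2, length.out = 2001L)[-c(1L, 2001L)]
  dd <- abs(w1 * dnorm(grid, m1, s1) - w2 * dnorm(grid, m2, s2))
  structure(grid[which.min(dd)], flagged = TRUE)
}

#' Fit a 3-Gaussian mixture to locomotor-index values
#'
#' Movement-onset and -offset thresholds are derived from a three-component
#' Gaussian mixture fitted to the session's distribution of locomotor-index
#' values: the lowest component captures tracking noise at rest, the middle
#' component slow repositioning, and the highest component locomotion. The
#' onset threshold is the density intersection of the second and third
#' components and the offset threshold the intersection of the first and
#' second, so that onsets demand clear locomotion while offsets only require
#' a return toward stillness.
#'
#' Values are subsampled to at most `max_values` before fitting; EM
#' (unequal-variance univariate mixture, [mclust::me()]) is seeded from
#' k-means centers and is deterministic for a given `seed`.
#'
#' @param li_values numeric vector of valid LI values (mm), or a `vp_li`.
#' @param seed integer RNG seed controlling subsampling/initialization.
#' @param max_values subsample cap (default 100000).
#' @param restarts number of EM initialization subsets tried (default 5).
#' @return object of class `vp_thresholds`: list with `components` (3 x 3
#'   matrix: weight, mean, sd; rows sorted by mean), `onset_threshold`,
#'   `offset_threshold`, `loglik`, `n_used`, `seed`, `flagged_onset`,
#'   `flagged_offset`.
#' @export
fit_li_mixture <- function(li_values, seed = 1L, max_values = 100000L,
                           restarts = 5L) {
  if (inherits(li_values, "vp_li")) li_values <- li_values$li
  x <- li_values[is.finite(li_values)]
  if (length(x) < 1000L)
    stop("mixture fit requires at least 1000 valid locomotor-index values")
  if (stats::var(x) == 0)
    stop("degenerate locomotor-index sample: zero variance")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (length(x) > max_values) x <- sample(x, max_values)
  # EM seeded from k-means centers: starting near the three occupancy
  # modes keeps the components interpretable (rest / intermediate /
  # locomotion) and guards against solutions that split the dominant
  # stillness mode; the best-likelihood converged restart is kept
  fit <- NULL
  for (r in seq_len(restarts)) {
    km <- tryCatch(stats::kmeans(x, centers = 3L, nstart = 3L,
                                 iter.max = 50L),
                   error = function(e) NULL)
    if (is.null(km)) next
    z <- unmap(km$cluster)
    f <- tryCatch(me(data = x, modelName = "V", z = z),
                  error = function(e) NULL)
    if (!is.null(f) && is.finite(f$loglik) &&
        (is.null(fit) || f$loglik > fit$loglik)) fit <- f
  }
  if (is.null(fit))
    stop("3-component mixture fit failed to converge")
  p <- fit$parameters
  comp <- cbind(weight = p$pro, mean = p$mean,
                sd = sqrt(p$variance$sigmasq))
  comp <- comp[order(comp[, "mean"]), , drop = FALSE]
  rownames(comp) <- c("still", "slow", "move")
  off <- gaussian_intersection(comp[1L, ], comp[2L, ])
  on <- gaussian_intersection(comp[2L, ], comp[3L, ])
  structure(list(components = comp,
                 onset_threshold = as.numeric(on),
                 offset_threshold = as.numeric(off),
                 loglik = fit$loglik, n_used = length(x), seed = seed,
                 flagged_onset = attr(on, "flagged"),
                 flagged_offset = attr(off, "flagged")),
            class = "vp_thresholds")
}

#' @export
print.vp_thresholds <- function(x, ...) {
  cat("<vp_thresholds> 3-Gaussian mixture of locomotor index\n")
  print(round(x$components, 4))
  cat(sprintf("  offset %.3f mm < onset %.3f mm (n = %d, loglik = %.1f)\n",
              x$offset_threshold, x$onset_threshold, x$n_used, x$loglik))
  invisible(x)
}

#' Detect movement bouts from a locomotor-index trace
#'
#' A movement onset is the first frame of at least `run_length` consecutive
#' frames whose LI strictly exceeds the onset threshold, provided that at
#' least `stillness_fraction` of the `stillness_window` frames immediately
#' preceding the onset frame have LI strictly below the offset threshold
#' (the animal was still just before). The bout ends at the first subsequent
#' frame whose LI falls strictly below the offset threshold; a bout still
#' open at the end of the trace is closed at the last frame and flagged.
#' Invalid LI frames fail both threshold comparisons.
#'
#' @param li `vp_li` (or list with `li` numeric vector).
#' @param thr `vp_thresholds` (or list with `onset_threshold`,
#'   `offset_threshold`).
#' @param stillness_window frames of pre-onset history examined (default 30,
#'   1 s at 30 frames/s).
#' @param stillness_fraction minimum fraction of that window below the offset
#'   threshold (default 0.7).
#' @param run_length consecutive supra-threshold frames required (default 4).
#' @param frame_rate frames per second used to convert frames to seconds
#'   (default 30).
#' @return data frame `onset_frame`, `offset_frame` (zero-based),
#'   `onset_s`, `offset_s`, `censored` (TRUE when closed at trace end).
#' @export
detect_bouts <- function(li, thr, stillness_window = 30L,
                         stillness_fraction = 0.7, run_length = 4L,
                         frame_rate = 30) {
  x <- li$li
  on_thr <- thr$onset_threshold
  off_thr <- thr$offset_threshold
  stopifnot(off_thr < on_thr)
  n <- length(x)
  above <- !is.na(x) & x > on_thr
  below <- !is.na(x) & x < off_thr
  empty <- data.frame(onset_frame = integer(), offset_frame = integer(),
                      onset_s = numeric(), offset_s = numeric(),
                      censored = logical())
  if (n < run_length) return(empty)
  # run_ok[t]: frames t..t+run_length-1 all above threshold
  run_ok <- rep(FALSE, n)
  cs <- cumsum(c(0L, as.integer(above)))
  idx <- seq_len(n - run_length + 1L)
  run_ok[idx] <- (cs[idx + run_length] - cs[idx]) == run_length
  # still_ok[t]: enough sub-offset frames among the stillness_window before t
  csb <- cumsum(c(0L, as.integer(below)))
  need <- stillness_fraction * stillness_window
  still_ok <- rep(FALSE, n)
  t_all <- seq_len(n)
  lo <- pmax(t_all - stillness_window, 1L)
  cnt <- csb[t_all] - csb[lo]
  still_ok <- cnt >= need & (t_all - stillness_window) >= 1L
  cand <- which(run_ok & still_ok)
  if (length(cand) == 0L) return(empty)
  onsets <- integer(0); offsets <- integer(0); cens <- logical(0)
  pos <- 1L
  below_idx <- which(below)
  while (pos <= length(cand)) {
    t0 <- cand[pos]
    nxt <- below_idx[below_idx > t0]
    if (length(nxt) == 0L) {
      t1 <- n
      cens <- c(cens, TRUE)
    } else {
      t1 <- nxt[1L]
      cens <- c(cens, FALSE)
    }
    onsets <- c(onsets, t0); offsets <- c(offsets, t1)
    pos <- pos + 1L
    while (pos <= length(cand) && cand[pos] <= t1) pos <- pos + 1L
  }
  data.frame(onset_frame = onsets - 1L, offset_frame = offsets - 1L,
             onset_s = (onsets - 1L) / frame_rate,
             offset_s = (offsets - 1L) / frame_rate,
             censored = cens)
}

#' Classify cue trials against detected movement bouts
#'
#' One record per cue presentation. A trial is analyzable only when the
#' animal was still at cue onset (the cue frame falls inside no bout);
#' already-moving trials are retained but tagged `excluded_reason =
#' "moving_at_cue"`. Movement onset is the first bout onset after cue onset;
#' for responded trials the movement ends at the first active lever press or
#' receptacle entry after movement start, otherwise at the movement bout's
#' LI offset.
#'
#' @param bouts data frame from [detect_bouts()].
#' @param events event-log data frame.
#' @param li `vp_li` for the session (used for offset scanning).
#' @param thr `vp_thresholds`.
#' @param frame_rate frames per second (default 30).
#' @return data frame with columns `trial`, `cue_type`, `cue_onset_s`,
#'   `cue_offset_s`, `still_at_cue`, `responded`, `movement_onset_latency_s`,
#'   `movement_start_s`, `movement_end_s`, `end_rule`, `excluded_reason`.
#' @export
classify_trials <- function(bouts, events, li, thr, frame_rate = 30) {
  cues <- cue_table(events)
  n <- nrow(cues)
  press_t <- events$time_s[events$kind == "active_press"]
  entry_t <- events$time_s[events$kind == "port_entry"]
  nframes <- length(li$li)
  below <- !is.na(li$li) & li$li < thr$offset_threshold
  below_idx <- which(below)
  rec <- data.frame(trial = seq_len(n), cue_type = cues$cue_type,
                    cue_onset_s = cues$onset_s, cue_offset_s = cues$offset_s,
                    still_at_cue = NA, responded = NA,
                    movement_onset_latency_s = NA_real_,
                    movement_start_s = NA_real_, movement_end_s = NA_real_,
                    end_rule = NA_character_, excluded_reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    t_on <- cues$onset_s[i]
    t_off <- cues$offset_s[i]
    cue_frame <- floor(t_on * frame_rate)  # zero-based
    if (cue_frame >= nframes) {
      rec$excluded_reason[i] <- "incomplete"
      next
    }
    inside <- nrow(bouts) > 0L &&
      any(bouts$onset_frame <= cue_frame & cue_frame < bouts$offset_frame)
    rec$still_at_cue[i] <- !inside
    responded <- !is.na(t_off) &&
      any(press_t > t_on & press_t <= t_off + 1e-9)
    rec$responded[i] <- responded
    if (inside) {
      rec$excluded_reason[i] <- "moving_at_cue"
      next
    }
    after <- bouts[bouts$onset_s > t_on, , drop = FALSE]
    if (nrow(after) == 0L) next
    ms <- after$onset_s[1L]
    rec$movement_start_s[i] <- ms
    rec$movement_onset_latency_s[i] <- ms - t_on
    if (responded) {
      cand <- c(press_t[press_t > ms], entry_t[entry_t > ms])
      if (length(cand) > 0L) {
        rec$movement_end_s[i] <- min(cand)
        rec$end_rule[i] <- if (min(cand) %in% press_t) "press" else "port_entry"
      } else {
        rec$end_rule[i] <- "li_offset"
        rec$movement_end_s[i] <- after$offset_s[1L]
      }
    } else {
      # first frame after movement start with LI below offset threshold
      start_frame <- floor(ms * frame_rate + 0.5)  # zero-based onset frame
      idx <- below_idx[below_idx - 1L > start_frame]  # below_idx is 1-based
      rec$end_rule[i] <- "li_offset"
      rec$movement_end_s[i] <- if (length(idx) > 0L)
        (idx[1L] - 1L) / frame_rate else NA_real_
    }
  }
  rec
}
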