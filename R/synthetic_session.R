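#' Simulation configuration
#'
#' Default parameters emulate the statistical structure of a 3-h operant
#' discriminative-stimulus session: exponentially scheduled auditory cues
#' (mean intertrial interval 30 s, 10-s maximum cue length), a rat that
#' roams the arena between trials with intermittent stillness, responds to
#' most reward-predictive (DS) cues by a curved, variable-start approach to
#' the operant lever, and a population of neurons whose two-phase cue-evoked
#' excitation (early 40-180 ms peak, late 180-400 ms tail) has a
#' trial-by-trial gain log-linearly coupled to chosen movement and state
#' variables. Head tracking is rendered as two LEDs at 30 frames/s with
#' 1.5-mm Gaussian noise.
#'
#' @param ... overrides for any default field.
#' @return named list of class `vp_sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    duration_s = 10800, frame_rate = 30,
    mean_iti_s = 30, cue_length_s = 10, p_ds = 0.5,
    p_respond_ds = 0.92, p_respond_ns = 0.10,
    latency_meanlog = log(0.8), latency_sdlog = 0.9,
    arena_mm = c(400, 400), lever_xy_mm = c(360, 200),
    receptacle_xy_mm = c(360, 300),
    led_separation_mm = 40, tracking_noise_mm = 1.5,
    tracking_noise_ar1 = 0, p_led_dropout = 0.002,
    still_mean_s = 6, roam_mean_s = 4, fidget_mean_s = 2.5, p_roam = 0.5,
    roam_step_meanlog = log(10), roam_step_sdlog = 0.25,
    fidget_step_meanlog = log(3.5), fidget_step_sdlog = 0.3, ou_rate = 0.3,
    micro_step_mm = 0,
    approach_peak_meanlog = log(430), approach_peak_sdlog = 0.3,
    approach_peak_floor = 260,
    approach_rise_s = 0.10, approach_fall_s = 0.30, bow_sd = 0.30,
    approach_jitter_sdlog = 0.45,
    port_speed_mm_s = 250, press_pause_s = 0.2, consume_still_s = 3,
    n_neurons = 160, frac_excited = 0.65, baseline_range_hz = c(3, 12),
    amp_early_hz = 14, amp_late_hz = 5, ns_gain = 0.6, max_rate_hz = 200,
    coupling = c(radial_velocity_max = 4e-04, path_efficiency = 1.0,
                 lever_distance_mm = -0.0012),
    coupling_ref = c(radial_velocity_max = 500, path_efficiency = 0.8,
                     lever_distance_mm = 200),
    coupling_het_sdlog = 0.4,
    infusion = NULL,
    subject_id = "sim01", session_id = "sim01_s01")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$duration_s > cfg$cue_length_s, cfg$mean_iti_s > 0,
            cfg$p_respond_ds >= 0, cfg$p_respond_ds <= 1,
            cfg$p_respond_ns >= 0, cfg$p_respond_ns <= 1)
  if (!is.null(cfg$infusion))
    stopifnot(cfg$infusion$attenuation > 0, cfg$infusion$attenuation <= 1)
  structure(cfg, class = "vp_sim_config")
}

derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + stream * 104729) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate an exponential cue schedule
#'
#' Cues are scheduled as a single interleaved stream: after each cue's
#' maximum extent (onset + 10 s) an exponentially distributed intertrial
#' interval (mean `mean_iti_s`) elapses before the next onset, approximating
#' a constant hazard of cue onset; each cue is labeled DS with probability
#' `p_ds`, otherwise NS. No two cues can overlap by construction.
#'
#' @param config `vp_sim_config`.
#' @param seed integer seed.
#' @return data frame `cue_type`, `onset_s`, `max_offset_s` with attribute
#'   `itis` (the raw exponential draws, seconds).
#' @export
generate_cue_schedule <- function(config, seed = 1L) {
  with_seed(derive_seed(seed, 1L), {
    horizon <- config$duration_s - config$cue_length_s - 8
    n_guess <- max(16L, ceiling(horizon / (config$mean_iti_s +
                                             config$cue_length_s) * 1.5))
    itis <- numeric(0); onsets <- numeric(0)
    t <- 0
    repeat {
      gaps <- rexp(n_guess, rate = 1 / config$mean_iti_s)
      for (g in gaps) {
        onset <- t + g
        if (onset > horizon) break
        itis <- c(itis, g)
        onsets <- c(onsets, onset)
        t <- onset + config$cue_length_s
      }
      if (t + config$mean_iti_s * 0.0 > horizon || onset > horizon) break
    }
    labels <- ifelse(runif(length(onsets)) < config$p_ds, "DS", "NS")
    out <- data.frame(cue_type = labels, onset_s = onsets,
                      max_offset_s = onsets + config$cue_length_s,
                      stringsAsFactors = FALSE)
    attr(out, "itis") <- itis
    out
  })
}

# trapezoidal frame-speed profile covering total path length L (mm), with
# multiplicative per-frame lognormal jitter emulating natural gait-cycle
# speed fluctuation (rescaled so the total path length is exact)
speed_profile <- function(L, peak, rise_fr, fall_fr, fr, jitter_sdlog = 0) {
  # short movements are quick lunges: compress rise/fall so the nominal
  # peak speed is still approached instead of being scaled away
  n0 <- ceiling(L * fr / peak * 1.7)
  if (n0 < rise_fr + fall_fr) {
    shrink <- n0 / (rise_fr + fall_fr)
    rise_fr <- max(2L, as.integer(round(rise_fr * shrink)))
    fall_fr <- max(3L, as.integer(round(fall_fr * shrink)))
  }
  n <- max(rise_fr + fall_fr, ceiling(L * fr / peak * 1.6))
  repeat {
    k <- seq_len(n)
    v <- pmin(peak, k * peak / rise_fr, (n + 1 - k) * peak / fall_fr)
    tot <- sum(v) / fr
    if (tot >= L) break
    n <- n + 1L
  }
  k <- seq_len(n)
  if (jitter_sdlog > 0) {
    # gait-cycle speed fluctuation develops once stepping begins; the
    # ballistic launch itself is smooth
    wgt <- pmin(1, (k - 1) / 6)
    v <- v * exp(wgt * log(rlnorm(n, -jitter_sdlog^2 / 2, jitter_sdlog)))
  }
  # launch burst: cued lunges begin with their most vigorous phase
  v <- v * (1 + 0.45 * exp(-(k - 1) / 5))
  v * (L / (sum(v) / fr))
}

# curved path from p0 to target with perpendicular sinusoidal bow
approach_path <- function(p0, target, peak, bow, rise_s, fall_s, fr,
                          jitter_sdlog = 0) {
  chord <- sqrt(sum((target - p0)^2))
  if (chord < 1) chord <- 1
  u <- (target - p0) / chord
  w <- c(-u[2L], u[1L])
  g_fine <- seq(0, 1, length.out = 256L)
  q <- function(g) cbind(p0[1L] + u[1L] * g * chord + w[1L] * bow * chord * sin(pi * g),
                         p0[2L] + u[2L] * g * chord + w[2L] * bow * chord * sin(pi * g))
  pts <- q(g_fine)
  seg <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seg))
  L <- arc[length(arc)]
  if (L < 1) {
    # start already at the target: negligible locomotion, brief hold
    return(matrix(p0, nrow = 4L, ncol = 2L, byrow = TRUE))
  }
  arc <- arc + seq_along(arc) * 1e-9  # strictly increasing for approx()
  v <- speed_profile(L, peak, max(1L, round(rise_s * fr)),
                     max(1L, round(fall_s * fr)), fr, jitter_sdlog)
  s <- cumsum(v) / fr
  g_s <- approx(arc, g_fine, xout = pmin(s, L), rule = 2)$y
  q(g_s)
}

#' Generate tracking and behavioral events for a cue schedule
#'
#' Between trials the head alternates among stillness, brisk
#' Ornstein-Uhlenbeck roaming bouts (mean-reverting to the arena center,
#' per-bout step scale), and brief low-amplitude "fidget" epochs emulating
#' head movement without locomotion (these populate the middle mode of the
#' locomotor-index distribution).
#' On responded DS trials the head, after a lognormal reaction latency,
#' executes a curved approach to the lever with a trapezoidal speed profile
#' (brisk rise, slower fall), presses, then travels to the reward
#' receptacle. Head pose is rendered as front/rear LEDs separated along the
#' heading, with isotropic Gaussian tracking noise and rare dropouts.
#'
#' @param schedule data frame from [generate_cue_schedule()].
#' @param config `vp_sim_config`.
#' @param seed integer seed.
#' @return list with `tracking` (data frame), `events` (data frame),
#'   `true_bouts` (movement segments, zero-based frames), `trial_truth`
#'   (per-cue ground truth incl. noise-free features and evoked gain),
#'   `pose_true` (noise-free `vp_pose`).
#' @export
generate_behavior <- function(schedule, config, seed = 1L) {
  with_seed(derive_seed(seed, 2L), {
    fr <- config$frame_rate
    N <- as.integer(round(config$duration_s * fr))
    arena <- config$arena_mm
    lever <- config$lever_xy_mm
    port <- config$receptacle_xy_mm
    if (any(lever < 0) || any(lever > arena) || any(port < 0) || any(port > arena))
      stop("unreachable geometry: lever/receptacle outside arena")
    center <- arena / 2
    margin <- 20
    pos <- matrix(NA_real_, nrow = N, ncol = 2L)
    cur <- center
    fc <- 1L  # next frame to fill (1-based)
    state <- "still"
    bouts <- list(); ev <- list(); truth <- list(); segs <- list()
    add_event <- function(time, kind, payload = "") {
      ev[[length(ev) + 1L]] <<- data.frame(time_s = time, kind = kind,
                                           payload = payload,
                                           stringsAsFactors = FALSE)
    }
    put <- function(m) {
      n <- nrow(m)
      if (n == 0L) return(invisible())
      hi <- min(fc + n - 1L, N)
      if (hi >= fc) pos[fc:hi, ] <<- m[seq_len(hi - fc + 1L), , drop = FALSE]
      fc <<- fc + n
      cur <<- m[n, ]
    }
    add_seg <- function(n, type) {
      segs[[length(segs) + 1L]] <<- c(fc, fc + n - 1L, type)
    }
    last_move_end <- -1000L  # frame at which the last movement ended
    ou_seg <- function(nfr, scale, record_bout, type = 2L) {
      a <- config$ou_rate / fr
      # accelerate in and decelerate out over ~5 frames: animals do not
      # reach full roaming speed instantaneously
      ramp <- pmin(1, seq_len(nfr) / 5, (nfr + 1 - seq_len(nfr)) / 5)
      e1 <- rnorm(nfr, 0, scale) * ramp; e2 <- rnorm(nfr, 0, scale) * ramp
      x <- stats::filter(a * center[1L] + e1, 1 - a, method = "recursive",
                         init = cur[1L])
      y <- stats::filter(a * center[2L] + e2, 1 - a, method = "recursive",
                         init = cur[2L])
      m <- cbind(pmin(pmax(as.numeric(x), margin), arena[1L] - margin),
                 pmin(pmax(as.numeric(y), margin), arena[2L] - margin))
      if (record_bout)
        bouts[[length(bouts) + 1L]] <<- c(fc, fc + nfr - 1L, 0, scale)
      add_seg(nfr, type)
      put(m)
      last_move_end <<- fc - 1L
    }
    still_seg <- function(nfr) {
      # "still" is postural micro-motion (breathing, head sway), not a
      # frozen pose: a tightly anchored OU wander of ~1 mm scale
      if (nfr <= 0L) return(invisible())
      add_seg(nfr, 1L)
      scale <- config$micro_step_mm
      if (scale > 0) {
        a <- 0.15
        x <- stats::filter(a * cur[1L] + rnorm(nfr, 0, scale), 1 - a,
                           method = "recursive", init = cur[1L])
        y <- stats::filter(a * cur[2L] + rnorm(nfr, 0, scale), 1 - a,
                           method = "recursive", init = cur[2L])
        put(cbind(as.numeric(x), as.numeric(y)))
      } else {
        put(matrix(cur, nrow = nfr, ncol = 2L, byrow = TRUE))
      }
    }
    fill_until <- function(frame_excl) {
      while (fc < frame_excl) {
        mean_s <- switch(state, still = config$still_mean_s,
                         roam = config$roam_mean_s,
                         fidget = config$fidget_mean_s)
        nfr <- 1L + as.integer(ceiling(rexp(1L, 1 / mean_s) * fr))
        nfr <- min(nfr, frame_excl - fc)
        if (state == "still") {
          still_seg(nfr)
          state <<- if (runif(1L) < config$p_roam) "roam" else "fidget"
        } else if (state == "roam") {
          ou_seg(nfr, rlnorm(1L, config$roam_step_meanlog,
                             config$roam_step_sdlog), TRUE)
          state <<- "still"
        } else {
          ou_seg(nfr, rlnorm(1L, config$fidget_step_meanlog,
                             config$fidget_step_sdlog), FALSE, type = 3L)
          state <<- "still"
        }
      }
    }
    ds_count <- 0L
    for (i in seq_len(nrow(schedule))) {
      tp <- schedule$cue_type[i]
      t_on <- schedule$onset_s[i]
      f_on <- floor(t_on * fr) + 1L
      if (f_on > N) break
      fill_until(f_on)
      p_resp <- if (tp == "DS") config$p_respond_ds else config$p_respond_ns
      respond <- runif(1L) < p_resp
      tr <- list(trial = i, cue_type = tp, onset_s = t_on, respond = respond,
                 latency_s = NA_real_, move_start_s = NA_real_,
                 press_s = NA_real_, start_x = NA_real_, start_y = NA_real_,
                 peak_speed = NA_real_, bow = NA_real_)
      add_event(t_on, paste0(tp, "_on"))
      if (!respond) {
        add_event(t_on + config$cue_length_s, paste0(tp, "_off"))
        truth[[length(truth) + 1L]] <- tr
        next
      }
      lat <- rlnorm(1L, config$latency_meanlog, config$latency_sdlog)
      if (lat > config$cue_length_s - 2.5) lat <- runif(1L, 0.3, 1.5)
      # reaction: an animal already locomoting keeps moving into the
      # approach; a still or fidgeting animal orients and holds still
      # until movement onset. Re-orientation after recent movement takes
      # time, so initiation follows at least ~1 s of stillness.
      roaming_now <- fc >= 3L &&
        sqrt(sum((pos[fc - 1L, ] - pos[fc - 2L, ])^2)) > 5
      if (!roaming_now)
        lat <- max(lat, (last_move_end + 45L - f_on) / fr + 0.1)
      f_ms <- floor((t_on + lat) * fr) + 1L
      if (f_ms > fc) {
        if (roaming_now)
          ou_seg(f_ms - fc, rlnorm(1L, config$roam_step_meanlog,
                                   config$roam_step_sdlog), TRUE)
        else
          still_seg(f_ms - fc)
      }
      state <- "still"  # next intertrial fill starts from stillness
      # cued approach lunges have a minimum briskness; redraw sub-floor peaks
      repeat {
        peak <- rlnorm(1L, config$approach_peak_meanlog,
                       config$approach_peak_sdlog)
        if (peak >= config$approach_peak_floor) break
      }
      bow <- rnorm(1L, 0, config$bow_sd)
      path <- approach_path(cur, lever, peak, bow, config$approach_rise_s,
                            config$approach_fall_s, fr,
                            config$approach_jitter_sdlog)
      tr$latency_s <- (f_ms - 1L) / fr - t_on
      tr$move_start_s <- (f_ms - 1L) / fr
      tr$start_x <- cur[1L]; tr$start_y <- cur[2L]
      tr$peak_speed <- peak; tr$bow <- bow
      b0 <- fc
      add_seg(nrow(path), 4L)
      put(path)
      last_move_end <- fc - 1L
      press_t <- (fc - 1L - 1L) / fr  # time of last approach frame
      tr$press_s <- press_t
      add_event(press_t, "active_press")
      if (tp == "DS") {
        add_event(press_t, "DS_off")
        still_seg(max(1L, round(config$press_pause_s * fr)))
        port_path <- approach_path(cur, port, config$port_speed_mm_s, 0,
                                   config$approach_rise_s,
                                   config$approach_fall_s, fr,
                                   config$approach_jitter_sdlog)
        add_seg(nrow(port_path), 4L)
        put(port_path)
        last_move_end <- fc - 1L
        entry_t <- (fc - 2L) / fr
        add_event(entry_t, "port_entry")
        add_event(entry_t, "reward")
        bouts[[length(bouts) + 1L]] <- c(b0, fc - 1L, 1, peak)
        still_seg(round(config$consume_still_s * fr))
      } else {
        add_event(t_on + config$cue_length_s, "NS_off")
        bouts[[length(bouts) + 1L]] <- c(b0, fc - 1L, 1, peak)
      }
      truth[[length(truth) + 1L]] <- tr
      if (tp == "DS") ds_count <- ds_count + 1L
    }
    fill_until(N + 1L)
    pos <- pos[seq_len(N), , drop = FALSE]
    # noise-free heading from displacement direction
    dx <- diff(pos[, 1L]); dy <- diff(pos[, 2L])
    step <- sqrt(dx^2 + dy^2)
    h <- c(0, ifelse(step > 0.1, atan2(dy, dx), NA_real_))
    h[1L] <- 0
    if (anyNA(h)) h <- cummax_na_locf(h)
    pose_true <- structure(list(position = pos, heading = wrap_angle(h),
                                valid = rep(TRUE, N), frame_rate = fr),
                           class = "vp_pose")
    if (!is.null(config$infusion))
      add_event(config$infusion$time_s, "infusion",
                config$infusion$condition)
    events <- do.call(rbind, ev)
    events <- events[order(events$time_s), , drop = FALSE]
    rownames(events) <- NULL
    # render LEDs with tracking noise and dropouts
    half <- config$led_separation_mm / 2
    front <- pos + half * cbind(cos(pose_true$heading), sin(pose_true$heading))
    rear <- pos - half * cbind(cos(pose_true$heading), sin(pose_true$heading))
    # tracking error: LED-centroid jitter is temporally correlated, not
    # white; AR(1) with the stated marginal SD (rho = 0 gives white noise)
    rho <- config$tracking_noise_ar1 %||% 0
    ns <- config$tracking_noise_mm
    ar1 <- function() {
      innov <- rnorm(N, 0, ns * sqrt(1 - rho^2))
      innov[1L] <- rnorm(1L, 0, ns)
      as.numeric(stats::filter(innov, rho, method = "recursive"))
    }
    front <- front + cbind(ar1(), ar1())
    rear <- rear + cbind(ar1(), ar1())
    drop_f <- runif(N) < config$p_led_dropout
    drop_r <- runif(N) < config$p_led_dropout
    front[drop_f, ] <- NA_real_
    rear[drop_r, ] <- NA_real_
    tracking <- data.frame(frame = 0:(N - 1L), time_s = (0:(N - 1L)) / fr,
                           red_x_mm = front[, 1L], red_y_mm = front[, 2L],
                           green_x_mm = rear[, 1L], green_y_mm = rear[, 2L])
    tb <- do.call(rbind, lapply(bouts, function(b)
      data.frame(onset_frame = b[1L] - 1L, offset_frame = min(b[2L], N) - 1L,
                 is_approach = b[3L] == 1, scale = b[4L])))
    tb <- tb[tb$onset_frame < tb$offset_frame, , drop = FALSE]
    # per-frame generative state: 1 still, 2 roam, 3 fidget, 4 approach/port
    frame_state <- integer(N)
    for (sg in segs) {
      hi <- min(sg[2L], N)
      if (sg[1L] <= hi) frame_state[sg[1L]:hi] <- sg[3L]
    }
    trial_truth <- do.call(rbind, lapply(truth, as.data.frame))
    trial_truth <- add_truth_features(trial_truth, pose_true, config)
    list(tracking = tracking, events = events, true_bouts = tb,
         trial_truth = trial_truth, pose_true = pose_true,
         frame_state = frame_state)
  })
}

cummax_na_locf <- function(x) {
  # last-observation-carried-forward for headings
  idx <- which(!is.na(x))
  if (length(idx) == 0L) return(rep(0, length(x)))
  fill <- approx(idx, x[idx], xout = seq_along(x), method = "constant",
                 rule = 2)$y
  fill
}

add_truth_features <- function(tt, pose_true, config) {
  lever <- config$lever_xy_mm
  fr <- config$frame_rate
  tt$radial_velocity_max <- NA_real_
  tt$path_efficiency <- NA_real_
  tt$speed_mean <- NA_real_
  tt$lever_distance_mm <- NA_real_
  tt$gain <- NA_real_
  for (i in seq_len(nrow(tt))) {
    f_cue <- floor(tt$onset_s[i] * fr) + 1L
    if (f_cue <= nrow(pose_true$position)) {
      p <- pose_true$position[f_cue, ]
      tt$lever_distance_mm[i] <- sqrt(sum((lever - p)^2))
    }
    if (isTRUE(tt$respond[i]) && !is.na(tt$press_s[i]) &&
        tt$press_s[i] > tt$move_start_s[i]) {
      mf <- movement_features(pose_true, tt$move_start_s[i], tt$press_s[i],
                              lever, tt$latency_s[i])
      tt$radial_velocity_max[i] <- mf$radial_velocity_max
      tt$path_efficiency[i] <- mf$path_efficiency
      tt$speed_mean[i] <- mf$speed_mean
    }
  }
  beta <- config$coupling
  ref <- config$coupling_ref
  lin <- rep(0, nrow(tt))
  for (v in names(beta)) {
    val <- tt[[v]]
    dev <- ifelse(is.na(val), 0, val - ref[[v]])
    lin <- lin + beta[[v]] * dev
  }
  tt$log_gain <- lin
  mult <- ifelse(tt$cue_type == "NS", config$ns_gain, 1)
  if (!is.null(config$infusion))
    mult <- mult * ifelse(tt$onset_s >= config$infusion$time_s,
                          config$infusion$attenuation, 1)
  tt$gain_mult <- mult
  tt$gain <- exp(lin) * mult
  tt
}

#' Generate spike trains coupled to behavioral ground truth
#'
#' Each neuron is an inhomogeneous Poisson process: a homogeneous baseline
#' plus, for excited neurons, a two-phase cue-evoked kernel (early component
#' over 40-180 ms, late over 180-400 ms after cue onset) whose trial gain is
#' the ground-truth `exp(sum(beta * (feature - reference)))` already stored
#' in the trial truth (NS gain ratio and post-infusion attenuation
#' included). Rates exceeding `max_rate_hz` are capped and counted.
#'
#' @param trial_truth data frame from [generate_behavior()].
#' @param config `vp_sim_config`.
#' @param seed integer seed.
#' @return list with `spikes` (data frame `neuron_id`, `time_s`) and
#'   `neuron_truth` (per-neuron baseline, excited flag, coupling echo,
#'   `n_capped`).
#' @export
generate_spike_trains <- function(trial_truth, config, seed = 1L) {
  with_seed(derive_seed(seed, 3L), {
    n <- config$n_neurons
    Tdur <- config$duration_s
    k_exc <- round(config$frac_excited * n)
    ids <- sprintf("n%03d", seq_len(n))
    baseline <- runif(n, config$baseline_range_hz[1L],
                      config$baseline_range_hz[2L])
    excited <- seq_len(n) <= k_exc
    # neurons differ in how strongly behavior modulates their evoked gain
    het <- config$coupling_het_sdlog %||% 0
    coupling_scale <- rlnorm(n, -het^2 / 2, het)
    span_e <- 0.18 - 0.04
    span_l <- 0.40 - 0.18
    out <- vector("list", n)
    truth <- data.frame(neuron_id = ids, baseline_hz = baseline,
                        excited = excited, coupling_scale = coupling_scale,
                        n_capped = 0L, stringsAsFactors = FALSE)
    onsets <- trial_truth$onset_s
    for (j in seq_len(n)) {
      nb <- rpois(1L, baseline[j] * Tdur)
      st <- runif(nb, 0, Tdur)
      if (excited[j]) {
        gains <- exp(coupling_scale[j] * trial_truth$log_gain) *
          trial_truth$gain_mult
        amp_e <- gains * config$amp_early_hz
        amp_l <- gains * config$amp_late_hz
        capped <- amp_e > config$max_rate_hz | amp_l > config$max_rate_hz
        truth$n_capped[j] <- sum(capped)
        amp_e <- pmin(amp_e, config$max_rate_hz)
        amp_l <- pmin(amp_l, config$max_rate_hz)
        ne <- rpois(length(onsets), amp_e * span_e)
        nl <- rpois(length(onsets), amp_l * span_l)
        if (sum(ne) > 0L)
          st <- c(st, rep(onsets, ne) + runif(sum(ne), 0.04, 0.18))
        if (sum(nl) > 0L)
          st <- c(st, rep(onsets, nl) + runif(sum(nl), 0.18, 0.40))
      }
      st <- sort(st[st >= 0 & st <= Tdur])
      dup <- c(FALSE, diff(st) <= 0)
      while (any(dup)) {
        st[dup] <- st[dup] + 1e-9
        st <- sort(st)
        dup <- c(FALSE, diff(st) <= 0)
      }
      out[[j]] <- st
    }
    spikes <- data.frame(neuron_id = rep(ids, lengths(out)),
                         time_s = unlist(out), stringsAsFactors = FALSE)
    list(spikes = spikes, neuron_truth = truth)
  })
}

#' Qualifying ground-truth movement initiations
#'
#' Returns the generated movement-bout onsets that a threshold-crossing
#' detector is, by its own definition, able to see: bouts launched from
#' rest (fully still for the preceding `still_window` frames — the centered
#' locomotor-index window blurs each transition by about `half_window + 1`
#' frames, so initiations with recent movement in that window are invisible
#' to any index-based stillness rule), lasting at least `min_frames`, and
#' with mean head speed over their first second of at least
#' `min_onset_speed` (slower starts sit in the index band between the
#' offset and onset thresholds, where crossing times are indeterminate).
#'
#' @param behavior list returned by [generate_behavior()] (needs
#'   `true_bouts`, `frame_state`, `pose_true`).
#' @param min_onset_speed floor on mean speed over the bout's first second,
#'   mm/s (default 300).
#' @param min_frames minimum bout duration in frames (default 8).
#' @param still_window frames of required full generative stillness before
#'   onset (default 30).
#' @return subset of `true_bouts` rows with an `onset_speed_mm_s` column.
#' @export
true_initiations <- function(behavior, min_onset_speed = 300,
                             min_frames = 8L, still_window = 30L) {
  tb <- behavior$true_bouts
  fs <- behavior$frame_state
  pos <- behavior$pose_true$position
  fr <- behavior$pose_true$frame_rate
  step <- c(0, sqrt(rowSums(diff(pos)^2))) * fr
  keep <- logical(nrow(tb))
  spd <- numeric(nrow(tb))
  for (i in seq_len(nrow(tb))) {
    f1 <- tb$onset_frame[i] + 1L
    f2 <- tb$offset_frame[i] + 1L
    if (f1 <= still_window || f2 - f1 + 1L < min_frames) next
    if (!all(fs[(f1 - still_window):(f1 - 1L)] == 1L)) next
    spd[i] <- mean(step[f1:min(f2, f1 + as.integer(fr) - 1L)])
    keep[i] <- spd[i] >= min_onset_speed
  }
  out <- tb[keep, , drop = FALSE]
  out$onset_speed_mm_s <- spd[keep]
  out
}

#' Generate a complete synthetic session with ground truth
#'
#' Composes [generate_cue_schedule()], [generate_behavior()] and
#' [generate_spike_trains()] into a validated session bundle plus the full
#' generative ground truth. Identical `(config, seed)` yield identical
#' output.
#'
#' @param config `vp_sim_config` (default `sim_config()`).
#' @param seed master integer seed; substreams for schedule, behavior and
#'   spikes are derived from it.
#' @return list with `bundle` (`vp_session`) and `truth` (list: `itis`,
#'   `schedule`, `trials`, `bouts`, `neurons`, `config`).
#' @export
generate_session <- function(config = sim_config(), seed = 1L) {
  schedule <- generate_cue_schedule(config, seed)
  beh <- generate_behavior(schedule, config, seed)
  spk <- generate_spike_trains(beh$trial_truth, config, seed)
  manifest <- list(frame_rate_hz = config$frame_rate,
                   duration_s = config$duration_s,
                   arena_mm = config$arena_mm,
                   lever_xy_mm = config$lever_xy_mm,
                   receptacle_xy_mm = config$receptacle_xy_mm,
                   subject_id = config$subject_id,
                   session_id = config$session_id,
                   infusion_time_s = if (is.null(config$infusion)) NULL
                                     else config$infusion$time_s,
                   infusion_condition = if (is.null(config$infusion)) NULL
                                        else config$infusion$condition)
  bundle <- session_bundle(beh$tracking, beh$events, spk$spikes, manifest)
  truth <- list(itis = attr(schedule, "itis"), schedule = schedule,
                trials = beh$trial_truth, bouts = beh$true_bouts,
                true_bouts = beh$true_bouts, frame_state = beh$frame_state,
                pose_true = beh$pose_true,
                neurons = spk$neuron_truth, config = config)
  list(bundle = bundle, truth = truth)
}
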