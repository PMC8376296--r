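# Literal reference implementations used as independent oracles. They are
# deliberately naive (double loops, per-spike counting) and must stay
# independent of the package's vectorized code paths.

# locomotor index by literal definition: sample SD of the 2*hw+1
# displacements d[t-hw..t+hw], d[A] = |pos[A] - pos[A-1]|
oracle_li <- function(pos, hw = 4L) {
  n <- nrow(pos)
  d <- rep(NA_real_, n)
  for (a in 2:n) d[a] <- sqrt(sum((pos[a, ] - pos[a - 1L, ])^2))
  out <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    lo <- t - hw; hi <- t + hw
    if (lo < 2L || hi > n) next
    win <- d[lo:hi]
    if (anyNA(win)) next
    out[t] <- sd(win)
  }
  out
}

# frame-by-frame bout scanner implementing the stated rules literally
oracle_bouts <- function(li, on_thr, off_thr, still_win = 30L,
                         still_frac = 0.7, run_len = 4L) {
  n <- length(li)
  above <- !is.na(li) & li > on_thr
  below <- !is.na(li) & li < off_thr
  onsets <- integer(0); offsets <- integer(0)
  t <- 1L
  while (t <= n - run_len + 1L) {
    ok_run <- all(above[t:(t + run_len - 1L)])
    ok_still <- FALSE
    if (t - still_win >= 1L)
      ok_still <- sum(below[(t - still_win):(t - 1L)]) >= still_frac * still_win
    if (ok_run && ok_still) {
      t1 <- NA_integer_
      for (u in (t + 1L):n) if (below[u]) { t1 <- u; break }
      if (is.na(t1)) t1 <- n
      onsets <- c(onsets, t); offsets <- c(offsets, t1)
      t <- t1 + 1L
    } else {
      t <- t + 1L
    }
  }
  data.frame(onset_frame = onsets - 1L, offset_frame = offsets - 1L)
}

# per-spike loop counter for peri-event binning
oracle_counts <- function(spikes, aligns, window, bin_ms = 20) {
  nbin <- as.integer((window[2L] - window[1L]) / bin_ms)
  m <- matrix(0L, nrow = length(aligns), ncol = nbin)
  for (i in seq_along(aligns)) {
    for (s in spikes) {
      rel <- (s - aligns[i]) * 1000
      if (rel >= window[1L] && rel < window[2L]) {
        b <- floor((rel - window[1L]) / bin_ms) + 1L
        m[i, b] <- m[i, b] + 1L
      }
    }
  }
  m
}

# exact paired Wilcoxon signed-rank p by full enumeration of sign flips
oracle_wilcoxon_exact <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(mask) {
    signs <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    sum(r[signs])
  }, numeric(1))
  p_low <- mean(vs <= v_obs)
  p_high <- mean(vs >= v_obs)
  list(V = v_obs, p = min(1, 2 * min(p_low, p_high)))
}

# movement features recomputed literally from their definitions
oracle_movement_features <- function(pos, heading, tt, lever) {
  m <- nrow(pos)
  step <- sqrt(rowSums((pos[-1L, , drop = FALSE] - pos[-m, , drop = FALSE])^2))
  fr <- 1 / diff(tt[1:2])
  speed <- step * fr
  dist <- sqrt((pos[, 1L] - lever[1L])^2 + (pos[, 2L] - lever[2L])^2)
  radial <- -diff(dist) * fr
  theta <- atan2(pos[, 2L] - lever[2L], pos[, 1L] - lever[1L])
  wrap <- function(a) { w <- (a + pi) %% (2 * pi) - pi; w[w == -pi] <- pi; w }
  ang <- abs(wrap(diff(theta)) * fr)
  dh <- wrap(diff(heading))
  accel <- diff(speed) * fr
  chord <- sqrt(sum((pos[m, ] - pos[1L, ])^2))
  u <- (pos[m, ] - pos[1L, ]) / chord
  devs <- abs(-u[2L] * (pos[, 1L] - pos[1L, 1L]) + u[1L] * (pos[, 2L] - pos[1L, 2L]))
  net <- sum(dh)
  list(radial_velocity_mean = mean(radial),
       radial_velocity_max = max(radial),
       radial_velocity_sd = sd(radial),
       speed_mean = mean(speed), speed_sd = sd(speed), speed_max = max(speed),
       path_length_mm = sum(step),
       latency_max_speed_s = tt[which.max(speed) + 1L] - tt[1L],
       latency_max_accel_s = tt[which.max(accel) + 2L] - tt[1L],
       max_path_deviation_mm = max(devs),
       turn_efficiency = if (abs(net) >= 1e-3) sum(abs(dh)) / abs(net) else NA_real_,
       angular_velocity_sd = sd(ang), angular_velocity_max = max(ang),
       angular_velocity_mean = mean(ang),
       net_heading_change_rad = net,
       path_efficiency = chord / sum(step))
}

# minimal valid session bundle built in code
make_mini_bundle <- function(n_frames = 400L, n_neurons = 2L, seed = 1L,
                             duration_s = n_frames / 30) {
  set.seed(seed)
  fr <- 30
  t <- (0:(n_frames - 1L)) / fr
  x <- cumsum(rnorm(n_frames, 0, 2)) + 200
  y <- cumsum(rnorm(n_frames, 0, 2)) + 200
  tracking <- data.frame(frame = 0:(n_frames - 1L), time_s = t,
                         red_x_mm = x + 15, red_y_mm = y,
                         green_x_mm = x - 15, green_y_mm = y)
  events <- data.frame(time_s = c(1, 2.5, 3.0, 3.2, 3.3, 6, 8),
                       kind = c("DS_on", "active_press", "DS_off",
                                "port_entry", "reward", "NS_on", "NS_off"),
                       payload = "", stringsAsFactors = FALSE)
  events <- events[events$time_s < duration_s - 0.5, ]
  events$time_s <- pmin(events$time_s, duration_s - 0.6)
  spikes <- do.call(rbind, lapply(seq_len(n_neurons), function(j)
    data.frame(neuron_id = sprintf("n%02d", j),
               time_s = sort(runif(50L, 0, duration_s)),
               stringsAsFactors = FALSE)))
  manifest <- list(frame_rate_hz = fr, duration_s = duration_s,
                   arena_mm = c(400, 400), lever_xy_mm = c(360, 200),
                   receptacle_xy_mm = c(360, 300), subject_id = "s1",
                   session_id = "s1_01", infusion_time_s = NULL,
                   infusion_condition = NULL)
  session_bundle(tracking, events, spikes, manifest, check = FALSE)
}

# random small but valid bundle for round-trip property tests
random_bundle <- function(seed) {
  set.seed(seed)
  n <- sample(60:150, 1L)
  fr <- 30
  dur <- ceiling(n / fr) + 5
  t <- (0:(n - 1L)) / fr
  x <- cumsum(rnorm(n)) + 100; y <- cumsum(rnorm(n)) + 100
  tracking <- data.frame(frame = 0:(n - 1L), time_s = round(t, 6),
                         red_x_mm = round(x + 10, 6), red_y_mm = round(y, 6),
                         green_x_mm = round(x - 10, 6), green_y_mm = round(y, 6))
  # drop some LED samples
  miss <- sample(n, max(1L, n %/% 20))
  tracking$red_x_mm[miss] <- NA; tracking$red_y_mm[miss] <- NA
  ds_on <- round(runif(1L, 0.5, dur - 3), 6)
  events <- data.frame(time_s = c(ds_on, round(ds_on + 1.5, 6)),
                       kind = c("DS_on", "DS_off"), payload = "",
                       stringsAsFactors = FALSE)
  k <- sample(1:3, 1L)
  spikes <- do.call(rbind, lapply(seq_len(k), function(j)
    data.frame(neuron_id = sprintf("n%02d", j),
               time_s = round(sort(runif(sample(5:30, 1L), 0, dur)), 6),
               stringsAsFactors = FALSE)))
  manifest <- list(frame_rate_hz = fr, duration_s = dur,
                   arena_mm = c(300, 300), lever_xy_mm = c(250, 150),
                   receptacle_xy_mm = c(250, 200), subject_id = "rX",
                   session_id = sprintf("rX_%02d", seed),
                   infusion_time_s = NULL, infusion_condition = NULL)
  session_bundle(tracking, events, spikes, manifest, check = FALSE)
}
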