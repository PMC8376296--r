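make_pose <- function(x, y = rep(0, length(x))) {
  structure(list(position = cbind(x, y), heading = rep(0, length(x)),
                 valid = rep(TRUE, length(x)), frame_rate = 30),
            class = "vp_pose")
}

test_that("locomotor index is zero at rest and under uniform translation", {
  p <- make_pose(rep(5, 30))
  li <- locomotor_index(p)
  expect_true(all(li$li[li$valid] == 0))

  p2 <- make_pose(seq(0, 58, by = 2))  # exactly 2 mm/frame
  li2 <- locomotor_index(p2)
  expect_true(all(abs(li2$li[li2$valid]) < 1e-9))
})

test_that("locomotor index matches the literal definition on a ramp", {
  x <- c(0, 0, 0, 0, 0, 0, 1, 3, 6, 10, 15, 21)
  p <- make_pose(x)
  li <- locomotor_index(p)
  ref <- oracle_li(p$position)
  expect_equal(li$li, ref, tolerance = 1e-12)
  # center frame value equals the SD of the 9 local displacements
  expect_equal(li$li[6], sd(c(0, 0, 0, 0, 0, 1, 2, 3, 4)), tolerance = 1e-12)
})

test_that("locomotor index equals brute-force recomputation on random paths", {
  set.seed(42)
  for (k in 1:60) {
    n <- sample(15:80, 1)
    p <- make_pose(cumsum(rnorm(n, 0, 3)), cumsum(rnorm(n, 0, 3)))
    if (k %% 3 == 0) {  # inject tracking gaps
      bad <- sample(n, 2)
      p$valid[bad] <- FALSE
      p$position[bad, ] <- NA
    }
    expect_equal(locomotor_index(p)$li, oracle_li(p$position),
                 tolerance = 1e-12)
  }
})

test_that("gaussian intersection solves the equal-density point", {
  x <- gaussian_intersection(c(0.5, 0, 1), c(0.5, 2, 1))
  expect_equal(as.numeric(x), 1, tolerance = 1e-12)
  expect_false(attr(x, "flagged"))

  # defining property for unequal components
  lo <- c(0.6, 1, 0.4); hi <- c(0.4, 4, 1.4)
  x2 <- gaussian_intersection(lo, hi)
  d1 <- lo[1] * dnorm(as.numeric(x2), lo[2], lo[3])
  d2 <- hi[1] * dnorm(as.numeric(x2), hi[2], hi[3])
  expect_equal(d1, d2, tolerance = 1e-9)

  # dominance case: no equal-density point between the means
  x3 <- gaussian_intersection(c(0.999, 0, 1), c(0.001, 1, 1))
  expect_true(attr(x3, "flagged"))
  grid <- seq(0, 1, length.out = 500)[-c(1, 500)]
  expect_true(all(0.999 * dnorm(grid, 0, 1) > 0.001 * dnorm(grid, 1, 1)))

  expect_error(gaussian_intersection(c(0.5, 0, 1), c(0.5, 0, 1)))
})

test_that("mixture fit recovers known generating parameters", {
  set.seed(11)
  n <- 30000
  z <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  x <- rnorm(n, c(0.5, 5, 20)[z], c(0.2, 1.5, 5)[z])
  fit <- fit_li_mixture(x, seed = 7)
  expect_equal(unname(fit$components[, "mean"]), c(0.5, 5, 20),
               tolerance = 0.05)
  expect_lt(fit$offset_threshold, fit$onset_threshold)
  expect_gt(fit$offset_threshold, fit$components[1, "mean"])
  expect_lt(fit$onset_threshold, fit$components[3, "mean"])
  # components sorted ascending by mean
  expect_true(all(diff(fit$components[, "mean"]) > 0))
})

test_that("mixture fit rejects degenerate input", {
  expect_error(fit_li_mixture(rep(1, 5000)), "zero variance")
  expect_error(fit_li_mixture(rnorm(100)), "1000")
})

test_that("thresholds are ordered across many seeded fits", {
  set.seed(99)
  for (k in 1:40) {
    n <- 3000
    mu <- sort(c(runif(1, 0.3, 1), runif(1, 2, 6), runif(1, 8, 25)))
    z <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    x <- rnorm(n, mu[z], c(0.2, 1, 4)[z])
    fit <- fit_li_mixture(x, seed = k, restarts = 2)
    expect_lt(fit$offset_threshold, fit$onset_threshold)
  }
})

test_that("bout detection handles a constructed square wave", {
  li <- structure(list(li = c(rep(0.1, 60), rep(30, 20), rep(0.1, 20)),
                       valid = rep(TRUE, 100), half_window = 4L),
                  class = "vp_li")
  thr <- list(onset_threshold = 10, offset_threshold = 1)
  b <- detect_bouts(li, thr)
  expect_equal(nrow(b), 1L)
  expect_equal(b$onset_frame, 60L)
  expect_equal(b$offset_frame, 80L)

  li2 <- structure(list(li = rep(5, 100), valid = rep(TRUE, 100),
                        half_window = 4L), class = "vp_li")
  expect_equal(nrow(detect_bouts(li2, thr)), 0L)
})

test_that("bout detection matches the frame-by-frame reference scanner", {
  set.seed(7)
  thr <- list(onset_threshold = 6, offset_threshold = 2)
  for (k in 1:120) {
    n <- 400
    li_vals <- abs(cumsum(rnorm(n, 0, 2)))
    li_vals[sample(n, 5)] <- NA  # invalid frames fail both comparisons
    li <- structure(list(li = li_vals, valid = !is.na(li_vals),
                         half_window = 4L), class = "vp_li")
    got <- detect_bouts(li, thr)
    ref <- oracle_bouts(li_vals, 6, 2)
    expect_equal(got$onset_frame, ref$onset_frame)
    expect_equal(got$offset_frame, ref$offset_frame)
  }
})

test_that("detected bouts are disjoint, ordered and re-verifiable", {
  set.seed(13)
  li_vals <- abs(cumsum(rnorm(3000, 0, 2)))
  li <- structure(list(li = li_vals, valid = rep(TRUE, 3000),
                       half_window = 4L), class = "vp_li")
  thr <- list(onset_threshold = 8, offset_threshold = 2)
  b <- detect_bouts(li, thr)
  if (nrow(b) > 1L) {
    expect_true(all(b$onset_frame[-1L] > b$offset_frame[-nrow(b)]))
  }
  for (i in seq_len(nrow(b))) {
    t0 <- b$onset_frame[i] + 1L
    expect_true(all(li_vals[t0:(t0 + 3L)] > 8))
    expect_gte(sum(li_vals[(t0 - 30):(t0 - 1)] < 2), 21)
  }
})

test_that("trial classification follows the constructed timeline", {
  fr <- 30
  n <- 3600  # 120 s
  li_vals <- rep(0.5, n)
  li_vals[3014:3100] <- 20   # bout onset 0-based frame 3013 = 100.433 s
  li <- structure(list(li = li_vals, valid = rep(TRUE, n), half_window = 4L),
                  class = "vp_li")
  thr <- list(onset_threshold = 10, offset_threshold = 1)
  bouts <- detect_bouts(li, thr)
  events <- data.frame(time_s = c(100.0, 101.5, 101.6, 50, 52),
                       kind = c("DS_on", "active_press", "DS_off",
                                "NS_on", "NS_off"), payload = "")
  events <- events[order(events$time_s), ]
  tr <- classify_trials(bouts, events, li, thr, frame_rate = fr)
  ds <- tr[tr$cue_type == "DS", ]
  expect_true(ds$still_at_cue)
  expect_true(ds$responded)
  expect_equal(ds$movement_start_s, 3013 / 30, tolerance = 1e-9)
  expect_equal(ds$movement_onset_latency_s, 3013 / 30 - 100, tolerance = 1e-9)
  expect_equal(ds$end_rule, "press")
  expect_equal(ds$movement_end_s, 101.5)
  # NS trial: no bout after it before the DS bout, still classified
  ns <- tr[tr$cue_type == "NS", ]
  expect_true(ns$still_at_cue)
  expect_false(ns$responded)
})

test_that("cue inside a bout is excluded as moving at cue", {
  n <- 3600
  li_vals <- rep(0.5, n); li_vals[1501:1800] <- 20
  li <- structure(list(li = li_vals, valid = rep(TRUE, n), half_window = 4L),
                  class = "vp_li")
  thr <- list(onset_threshold = 10, offset_threshold = 1)
  bouts <- detect_bouts(li, thr)
  events <- data.frame(time_s = c(52, 62), kind = c("DS_on", "DS_off"),
                       payload = "")
  tr <- classify_trials(bouts, events, li, thr)
  expect_equal(tr$excluded_reason, "moving_at_cue")
  expect_false(tr$still_at_cue)
  expect_true(is.na(tr$movement_start_s))
})

test_that("non-responded movement end equals first sub-threshold frame", {
  n <- 3600
  li_vals <- rep(0.5, n)
  li_vals[1501:1600] <- 20         # bout: frames 1500..1599 (0-based)
  li <- structure(list(li = li_vals, valid = rep(TRUE, n), half_window = 4L),
                  class = "vp_li")
  thr <- list(onset_threshold = 10, offset_threshold = 1)
  bouts <- detect_bouts(li, thr)
  events <- data.frame(time_s = c(49, 59), kind = c("DS_on", "DS_off"),
                       payload = "")
  tr <- classify_trials(bouts, events, li, thr)
  expect_false(tr$responded)
  expect_equal(tr$end_rule, "li_offset")
  # oracle: first 0-based frame after movement start with li < 1
  start_f <- round(tr$movement_start_s * 30)
  ref <- (which(li_vals < 1 & seq_along(li_vals) - 1L > start_f)[1L]) - 1L
  expect_equal(tr$movement_end_s, ref / 30)
})

test_that("ground-truth initiations are detected within three frames", {
  errs <- c()
  for (sd in c(3, 7, 19)) {
    gs <- generate_session(sim_config(duration_s = 1800, n_neurons = 2),
                           seed = sd)
    pose <- head_pose(gs$bundle)
    li <- locomotor_index(pose)
    thr <- fit_li_mixture(li, seed = 1)
    b <- detect_bouts(li, thr)
    ti <- true_initiations(gs$truth)
    errs <- c(errs, vapply(ti$onset_frame, function(f)
      b$onset_frame[which.min(abs(b$onset_frame - f))] - f, numeric(1)))
  }
  expect_gt(length(errs), 100)
  expect_gte(mean(abs(errs) <= 3), 0.95)
})
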