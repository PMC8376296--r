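track_df <- function(red, green) {
  n <- nrow(red)
  data.frame(frame = 0:(n - 1), time_s = (0:(n - 1)) / 30,
             red_x_mm = red[, 1], red_y_mm = red[, 2],
             green_x_mm = green[, 1], green_y_mm = green[, 2])
}

test_that("head pose combines the LEDs as midpoint plus heading", {
  tr <- track_df(matrix(c(10, 0), 1, 2), matrix(c(0, 0), 1, 2))
  p <- head_pose(rbind(tr, tr), front_led = "red")
  expect_equal(p$position[1, ], c(5, 0), ignore_attr = TRUE)
  expect_equal(p$heading[1], 0)

  tr2 <- track_df(matrix(c(0, 10), 1, 2), matrix(c(0, 0), 1, 2))
  p2 <- head_pose(rbind(tr2, tr2), front_led = "red")
  expect_equal(p2$heading[1], pi / 2)
  # reversed front LED flips the heading
  p3 <- head_pose(rbind(tr2, tr2), front_led = "green")
  expect_equal(p3$heading[1], -pi / 2)
})

test_that("short LED dropouts are linearly interpolated, long ones invalid", {
  n <- 12
  red <- cbind(seq(0, 22, by = 2), rep(0, n))
  green <- cbind(seq(-10, 12, by = 2), rep(0, n))
  tr <- track_df(red, green)
  tr$red_x_mm[5:7] <- NA; tr$red_y_mm[5:7] <- NA
  p <- head_pose(tr, max_gap = 5)
  expect_true(all(p$valid))
  # linear gap fill reproduces the linear motion exactly
  expect_equal(p$position[, 1], seq(-5, 17, by = 2), ignore_attr = TRUE)

  tr$red_x_mm[2:9] <- NA; tr$red_y_mm[2:9] <- NA  # 8-frame gap > max_gap
  p2 <- head_pose(tr, max_gap = 5)
  expect_true(all(!p2$valid[2:9]))
})

test_that("kinematic series recovers circular and radial motion", {
  fr <- 30
  lever <- c(0, 0)
  t <- (0:299) / fr
  # uniform circular motion, radius 100 mm, 0.5 rad/s
  pos <- cbind(100 * cos(0.5 * t), 100 * sin(0.5 * t))
  pose <- structure(list(position = pos, heading = rep(0, 300),
                         valid = rep(TRUE, 300), frame_rate = fr),
                    class = "vp_pose")
  ks <- kinematic_series(pose, lever)
  i <- 3:298
  expect_true(all(abs(ks$radial_velocity_mm_s[i]) < 0.1))
  expect_equal(mean(abs(ks$angular_velocity_rad_s[i])), 0.5, tolerance = 1e-3)
  expect_equal(mean(ks$speed_mm_s[i]), 50, tolerance = 0.1)

  # straight approach toward the lever at 300 mm/s
  pos2 <- cbind(seq(500, by = -10, length.out = 40), rep(0, 40))
  pose2 <- structure(list(position = pos2, heading = rep(pi, 40),
                          valid = rep(TRUE, 40), frame_rate = fr),
                     class = "vp_pose")
  ks2 <- kinematic_series(pose2, lever)
  expect_equal(ks2$radial_velocity_mm_s[5], 300, tolerance = 1e-9)
  expect_equal(ks2$angular_velocity_rad_s[5], 0, tolerance = 1e-9)
})

test_that("speed decomposes into radial and tangential parts", {
  set.seed(5)
  fr <- 30
  t <- (0:199) / fr
  pos <- cbind(300 + 150 * cos(0.8 * t) + 30 * sin(1.7 * t),
               250 + 150 * sin(0.8 * t))
  pose <- structure(list(position = pos, heading = rep(0, 200),
                         valid = rep(TRUE, 200), frame_rate = fr),
                    class = "vp_pose")
  lever <- c(0, 0)
  ks <- kinematic_series(pose, lever)
  i <- 5:195
  lhs <- ks$speed_mm_s[i]^2
  rhs <- ks$radial_velocity_mm_s[i]^2 +
    (ks$lever_distance_mm[i] * ks$angular_velocity_rad_s[i])^2
  expect_lt(median(abs(lhs - rhs) / lhs), 0.01)
})

test_that("movement features on closed-form paths", {
  fr <- 30
  # straight path, 10 frames at 10 mm per frame
  pos <- cbind(seq(0, 90, by = 10), rep(0, 10))
  pose <- structure(list(position = pos, heading = rep(0, 10),
                         valid = rep(TRUE, 10), frame_rate = fr),
                    class = "vp_pose")
  f <- movement_features(pose, 0, 9 / fr, lever_xy = c(1000, 0))
  expect_equal(f$speed_mean, 300)
  expect_equal(f$path_length_mm, 90)
  expect_equal(f$path_efficiency, 1)
  expect_equal(f$max_path_deviation_mm, 0)
  expect_equal(f$net_heading_change_rad, 0)
  expect_true(is.na(f$turn_efficiency))  # undefined for straight motion

  # right-angle path with legs 30 and 40 mm (3-4-5 triangle)
  pos2 <- rbind(cbind(seq(0, 30, by = 10), 0),
                cbind(rep(30, 4), seq(10, 40, by = 10)))
  pose2 <- structure(list(position = pos2, heading = rep(0, 8),
                          valid = rep(TRUE, 8), frame_rate = fr),
                     class = "vp_pose")
  f2 <- movement_features(pose2, 0, 7 / fr, lever_xy = c(500, 500))
  expect_equal(f2$path_length_mm, 70)
  expect_equal(f2$path_efficiency, 5 / 7)

  # semicircular arc: efficiency 2/pi; quarter-turn sweep: turn efficiency 1
  th <- seq(0, pi, length.out = 61)
  pos3 <- cbind(100 * cos(th), 100 * sin(th))
  pose3 <- structure(list(position = pos3, heading = rep(0, 61),
                          valid = rep(TRUE, 61), frame_rate = fr),
                     class = "vp_pose")
  f3 <- movement_features(pose3, 0, 60 / fr, lever_xy = c(0, 500))
  expect_equal(f3$path_efficiency, 2 / pi, tolerance = 1e-3)

  h <- seq(0, pi / 2, length.out = 20)
  pose4 <- structure(list(position = cbind(cumsum(cos(h)) * 10,
                                           cumsum(sin(h)) * 10),
                          heading = h, valid = rep(TRUE, 20),
                          frame_rate = fr), class = "vp_pose")
  f4 <- movement_features(pose4, 0, 19 / fr, lever_xy = c(900, 0))
  expect_equal(f4$turn_efficiency, 1, tolerance = 1e-9)
  expect_equal(f4$net_heading_change_rad, pi / 2, tolerance = 1e-9)
})

test_that("every feature equals its literal recomputation on random walks", {
  set.seed(77)
  fr <- 30
  for (k in 1:40) {
    n <- sample(10:60, 1)
    pos <- cbind(cumsum(rnorm(n, 1, 4)) + 100, cumsum(rnorm(n, -1, 4)) + 100)
    h <- cumsum(rnorm(n, 0, 0.2))
    pose <- structure(list(position = pos, heading = h,
                           valid = rep(TRUE, n), frame_rate = fr),
                      class = "vp_pose")
    lever <- c(400, 150)
    tt <- (0:(n - 1)) / fr
    f <- movement_features(pose, 0, (n - 1) / fr, lever)
    ref <- oracle_movement_features(pos, h, tt, lever)
    for (nm in names(ref)) {
      expect_equal(f[[nm]], ref[[nm]], tolerance = 1e-10, label = nm)
    }
  }
})

test_that("features are invariant under rigid motions of the arena", {
  set.seed(8)
  n <- 40
  pos <- cbind(cumsum(rnorm(n, 2, 5)) + 100, cumsum(rnorm(n, 0, 5)) + 100)
  h <- cumsum(rnorm(n, 0, 0.3))
  lever <- c(300, 250)
  pose <- structure(list(position = pos, heading = h, valid = rep(TRUE, n),
                         frame_rate = 30), class = "vp_pose")
  f0 <- movement_features(pose, 0, (n - 1) / 30, lever)

  ang <- 0.83; shift <- c(-40, 95)
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  pose2 <- structure(list(position = t(R %*% t(pos)) +
                            matrix(shift, n, 2, byrow = TRUE),
                          heading = h + ang, valid = rep(TRUE, n),
                          frame_rate = 30), class = "vp_pose")
  f1 <- movement_features(pose2, 0, (n - 1) / 30,
                          as.numeric(R %*% lever) + shift)
  for (nm in setdiff(names(f0), c("incomplete")))
    expect_equal(f1[[nm]], f0[[nm]], tolerance = 1e-9, label = nm)
})

test_that("turn efficiency and path efficiency obey their bounds", {
  set.seed(21)
  for (k in 1:30) {
    n <- sample(8:50, 1)
    pos <- cbind(cumsum(rnorm(n, 1, 3)), cumsum(rnorm(n, 1, 3)))
    h <- cumsum(rnorm(n, 0, 0.4))
    pose <- structure(list(position = pos, heading = h, valid = rep(TRUE, n),
                           frame_rate = 30), class = "vp_pose")
    f <- movement_features(pose, 0, (n - 1) / 30, c(100, 100))
    expect_gt(f$path_efficiency, 0)
    expect_lte(f$path_efficiency, 1 + 1e-12)
    if (!is.na(f$turn_efficiency)) expect_gte(f$turn_efficiency, 1 - 1e-12)
  }
})

test_that("state features read the cue-onset frame and event history", {
  n <- 60
  pos <- matrix(rep(c(0, 0), each = n), n, 2)
  pose <- structure(list(position = pos, heading = rep(0, n),
                         valid = rep(TRUE, n), frame_rate = 30),
                    class = "vp_pose")
  events <- data.frame(time_s = c(90, 95, 98) - 89,  # 1, 6, 9 s
                       kind = c("reward", "active_press", "DS_on"),
                       payload = "")
  sf <- state_features(pose, events, cue_t = 11 / 30, lever_xy = c(30, 40))
  expect_equal(sf$lever_distance_mm, 50)          # 3-4-5
  expect_equal(sf$lever_orientation_rad, atan2(40, 30))

  # heading +x, lever straight up: orientation pi/2
  pose$heading[] <- 0
  sf2 <- state_features(pose, events, cue_t = 11 / 30, lever_xy = c(0, 40))
  expect_equal(sf2$lever_orientation_rad, pi / 2)

  # reward at 90 s, cue at 100 s -> 10 s elapsed
  ev <- data.frame(time_s = c(90), kind = "reward", payload = "")
  n2 <- 3030
  pose2 <- structure(list(position = matrix(0, n2, 2), heading = rep(0, n2),
                          valid = rep(TRUE, n2), frame_rate = 30),
                     class = "vp_pose")
  sf3 <- state_features(pose2, ev, cue_t = 100, lever_xy = c(10, 0))
  expect_equal(sf3$time_since_reward_s, 10)
  expect_true(is.na(sf3$time_since_cue_s))
})
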