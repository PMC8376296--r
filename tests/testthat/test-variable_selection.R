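test_that("SMC flags duplicated and independent variables correctly", {
  set.seed(12)
  n <- 500
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  x[, "d"] <- x[, "a"]  # exact duplicate
  s <- smc_scores(x)
  expect_equal(unname(s["a"]), 1, tolerance = 1e-9)
  expect_equal(unname(s["d"]), 1, tolerance = 1e-9)

  set.seed(13)
  y <- matrix(rnorm(10000 * 10), 10000, 10,
              dimnames = list(NULL, letters[1:10]))
  expect_true(all(smc_scores(y) < 0.01))
})

test_that("SMC equals the correlation-matrix closed form", {
  set.seed(14)
  for (k in 1:10) {
    n <- 300
    p <- sample(3:6, 1)
    base <- matrix(rnorm(n * p), n, p)
    x <- base + 0.5 * base[, sample(p)]  # induce correlation
    colnames(x) <- paste0("v", 1:p)
    got <- smc_scores(x)
    Rinv <- solve(cor(x))
    ref <- 1 - 1 / diag(Rinv)
    expect_equal(unname(got), unname(ref), tolerance = 1e-9)
  }
})

test_that("multicollinearity filter drops the worst offender first", {
  set.seed(15)
  n <- 2000
  x <- rnorm(n); y <- rnorm(n)
  z <- x + y + rnorm(n, 0, 0.1)
  dat <- data.frame(x = x, y = y, z = z)
  out <- filter_multicollinear(dat, tolerance = 0.8)
  expect_equal(out$dropped$variable[1], "z")
  expect_setequal(out$retained, c("x", "y"))
  # literal re-application of the rule reaches the same set
  dat2 <- dat
  repeat {
    s <- smc_scores(dat2)
    if (max(s, na.rm = TRUE) <= 0.8) break
    worst <- sort(names(which(s == max(s, na.rm = TRUE))))[1]
    dat2[[worst]] <- NULL
  }
  expect_setequal(out$retained, names(dat2))

  # nothing dropped when correlations are mild; filter is idempotent
  w <- data.frame(a = rnorm(500), b = rnorm(500), c = rnorm(500))
  out2 <- filter_multicollinear(w)
  expect_equal(nrow(out2$dropped), 0L)
  out3 <- filter_multicollinear(w[out2$retained])
  expect_equal(nrow(out3$dropped), 0L)
})

test_that("exactly one member of a duplicate pair survives the filter", {
  set.seed(16)
  d <- data.frame(a = rnorm(400), b = rnorm(400), c = rnorm(400))
  d$a2 <- d$a
  out <- filter_multicollinear(d)
  expect_equal(sum(c("a", "a2") %in% out$retained), 1L)
})

test_that("Kaiser factor count from correlation eigenvalues", {
  set.seed(17)
  n <- 4000
  f1 <- rnorm(n); f2 <- rnorm(n)
  x <- cbind(f1 + rnorm(n, 0, 0.4), f1 + rnorm(n, 0, 0.4),
             f1 + rnorm(n, 0, 0.5),
             f2 + rnorm(n, 0, 0.4), f2 + rnorm(n, 0, 0.5),
             rnorm(n))
  colnames(x) <- paste0("v", 1:6)
  pk <- pca_factor_count(x)
  expect_equal(pk$n_factors, 2L)
  expect_equal(sum(pk$eigenvalues), 6, tolerance = 1e-9)
  expect_true(all(diff(pk$eigenvalues) <= 1e-12))

  # perfectly correlated pair in a noise-free construction
  u <- rnorm(500)
  y <- cbind(u, u, rnorm(500), rnorm(500))
  colnames(y) <- paste0("w", 1:4)
  expect_gte(pca_factor_count(y)$eigenvalues[1], 2 - 1e-9)

  # eigenvalues invariant to column permutation
  perm <- sample(ncol(x))
  expect_equal(pca_factor_count(x[, perm])$eigenvalues, pk$eigenvalues,
               tolerance = 1e-9)
})

test_that("factor model recovers a known orthogonal two-factor structure", {
  set.seed(18)
  n <- 20000
  L <- rbind(c(0.9, 0), c(0.8, 0), c(0.7, 0),
             c(0, 0.9), c(0, 0.8), c(0, 0.7))
  f <- matrix(rnorm(n * 2), n, 2)
  e_sd <- sqrt(1 - rowSums(L^2))
  x <- f %*% t(L) + matrix(rnorm(n * 6), n, 6) %*% diag(e_sd)
  colnames(x) <- paste0("v", 1:6)
  fm <- factor_model(x, 2)
  got <- fm$loadings
  # the loading matrix is identified only up to rotation; compare the
  # rotation-invariant reproduced common covariance
  expect_lt(max(abs(got %*% t(got) - L %*% t(L))), 0.05)
  # varimax recovers the simple structure up to factor permutation
  grp <- unname(fm$factor_assignment)
  expect_true(all(grp[1:3] == grp[1]) && all(grp[4:6] == grp[4]) &&
                grp[1] != grp[4])
})

test_that("single-factor data yields negligible second-factor loadings", {
  set.seed(19)
  n <- 8000
  g <- rnorm(n)
  x <- sapply(c(0.9, 0.85, 0.8, 0.75, 0.7),
              function(l) l * g + rnorm(n, 0, sqrt(1 - l^2)))
  colnames(x) <- paste0("v", 1:5)
  # unrotated ML solution: the second factor has essentially nothing to
  # explain (ML can park a small amount of one variable's uniqueness there,
  # so compare explained variances rather than single loadings)
  fm <- factor_model(x, 2, rotation = "none")
  expect_lt(sum(fm$loadings[, 2]^2) / sum(fm$loadings[, 1]^2), 0.05)
  expect_lt(max(abs(fm$loadings[, 2])), 0.3)
})

test_that("rep scores equal the published worked examples", {
  # highest loading minus the signed sum of the remaining loadings
  expect_equal(unname(rep_scores(rbind(c(0.94, 0.25, 0.16, 0.01, -0.03)))),
               0.55, tolerance = 1e-12)
  expect_equal(unname(rep_scores(rbind(c(0.04, 0.75, 0.08, -0.09, 0.00)))),
               0.72, tolerance = 1e-12)
  expect_equal(unname(rep_scores(rbind(c(0, 0.9, 0, 0, 0)))), 0.9)
})

test_that("rep scores reproduce the whole reference table within rounding", {
  ref <- reference_factor_loadings()
  L <- as.matrix(ref[, paste0("factor", 1:5)])
  rownames(L) <- ref$variable
  rs <- rep_scores(L)
  have <- !is.na(ref$rep_score_printed)
  expect_true(all(abs(rs[have] - ref$rep_score_printed[have]) <= 0.015))
  exact_rows <- c("radial_velocity_max", "latency_max_accel_s", "speed_mean",
                  "angular_velocity_sd", "speed_max", "angular_velocity_mean")
  expect_equal(unname(rs[exact_rows]),
               c(0.55, 0.72, -0.36, 0.19, 0.25, 0.26), tolerance = 1e-12)
})

test_that("regressor selection picks representatives and independents", {
  ref <- reference_factor_loadings()
  L <- as.matrix(ref[, paste0("factor", 1:5)])
  rownames(L) <- ref$variable
  fm <- structure(list(loadings = L, rotation = "varimax",
                       rep_scores = rep_scores(L),
                       factor_assignment = apply(abs(L), 1, which.max)),
                  class = "vp_factor_model")
  sel <- select_regressors(fm, strong = 0.6, independent = 0.4)
  reps <- sel$variable[sel$reason == "representative"]
  expect_equal(sel$variable[sel$reason == "representative" & sel$factor == 1],
               "radial_velocity_max")
  expect_equal(sel$variable[sel$reason == "representative" & sel$factor == 2],
               "move_duration_s")
  indep <- sel$variable[sel$reason == "independent"]
  expect_setequal(indep, c("turn_efficiency", "movement_onset_latency_s",
                           "net_heading_change_rad"))
})

test_that("selection edge cases: one strong per factor; all independent", {
  L <- rbind(a = c(0.8, 0.1), b = c(0.1, 0.75), c = c(0.2, 0.1))
  fm <- structure(list(loadings = L, rotation = "varimax",
                       rep_scores = rep_scores(L),
                       factor_assignment = apply(abs(L), 1, which.max)),
                  class = "vp_factor_model")
  sel <- select_regressors(fm)
  expect_setequal(sel$variable[sel$reason == "representative"], c("a", "b"))

  L2 <- rbind(a = c(0.3, 0.1), b = c(0.1, 0.2), c = c(0.2, 0.1))
  fm2 <- structure(list(loadings = L2, rotation = "varimax",
                        rep_scores = rep_scores(L2),
                        factor_assignment = apply(abs(L2), 1, which.max)),
                   class = "vp_factor_model")
  sel2 <- select_regressors(fm2)
  expect_true(all(sel2$reason == "independent"))
  expect_equal(nrow(sel2), 3L)

  # manual override is honored and logged
  sel3 <- select_regressors(fm, manual = "c")
  expect_true(any(sel3$variable == "c" & sel3$reason == "manual"))
})
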