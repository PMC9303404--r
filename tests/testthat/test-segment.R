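# Change-point detection, OS/CS labeling, dwell extraction and trace
# diagnostics.

test_that("clean steps are localized exactly and constants left whole", {
  expect_identical(detect_changepoints(rep(5, 400)), integer(0))
  z <- step_series(1000, at = 500, jump = 73, noise = 0)
  expect_identical(detect_changepoints(z), 500L)
  expect_error(detect_changepoints(numeric(0)), "empty")
})

test_that("segmentation is offset-invariant and monotone in penalty", {
  z <- step_series(2000, at = 700, jump = 73, noise = 7.9, seed = 4)
  expect_identical(detect_changepoints(z), detect_changepoints(z + 1234.5))
  n_bp <- vapply(c(0.5, 1, 2, 5, 20), function(p)
    length(detect_changepoints(z, penalty = p)), numeric(1))
  expect_true(all(diff(n_bp) <= 0))
})

test_that("true transitions are recovered on decimated synthetic traces", {
  r <- fixture_rates()
  hits <- 0; total <- 0; label_ok <- 0; label_n <- 0
  for (s in 1:4) {
    traj <- simulate_trajectory(r, 2000, seed = 40 + s)
    cfg <- trace_config(r, duration = 2000, seed = 70 + s)
    tr <- render_trace(traj, cfg)
    f_eff <- cfg$f_s / cfg$decimate
    bp <- detect_changepoints(tr$z)
    seg <- label_segments(tr$z, bp)
    # transitions bounding dwells > 1 s
    dw <- true_dwells(traj)
    t_trans <- cumsum(dw$duration_s)
    t_trans <- t_trans[-length(t_trans)]
    long <- dw$duration_s[-nrow(dw)] > 1 & dw$duration_s[-1] > 1
    t_trans <- t_trans[long]
    found <- seg$breakpoints / f_eff
    hits <- hits + sum(vapply(t_trans, function(x)
      any(abs(found - x) <= 2 / f_eff), logical(1)))
    total <- total + length(t_trans)
    # per-sample label accuracy against the true lumped state
    open_true <- {
      idx <- findInterval(tr$t, traj$event_times)
      traj$states[idx] %in% c("RP_I", "RP_O")
    }
    lab <- rep(seg$labels, diff(c(0, seg$breakpoints, seg$n))[
      seq_along(seg$labels)])
    label_ok <- label_ok + sum((lab == "OS") == open_true)
    label_n <- label_n + length(open_true)
  }
  expect_gte(hits / total, 0.95)
  expect_gte(label_ok / label_n, 0.98)
})

test_that("two clean levels are labelled perfectly, flat traces all-CS", {
  z <- c(rep(900, 300), rep(827, 200), rep(900, 250))
  seg <- label_segments(z, detect_changepoints(z))
  expect_identical(seg$labels, c("CS", "OS", "CS"))
  expect_equal(seg$levels, c(900, 827, 900))
  zn <- step_series(800, at = 400, jump = 0, noise = 8, seed = 5)
  segn <- label_segments(zn, detect_changepoints(zn))
  expect_true(all(segn$labels == "CS"))
})

test_that("dwell extraction censors boundaries and enforces t_min", {
  seg <- structure(list(breakpoints = c(100L, 200L),
                        labels = c("CS", "OS", "CS"),
                        levels = c(900, 827, 900), n = 300L),
                   class = "segmentation")
  dw <- extract_dwells(seg, f_s_eff = 5.8, t_min = 0)
  expect_equal(nrow(dw), 3L)
  expect_identical(dw$censored, c(TRUE, FALSE, TRUE))
  expect_equal(dw$duration_s[2], 100 / 5.8, tolerance = 1e-12)
  expect_equal(dwell_durations(dw), 100 / 5.8)
  # a sub-t_min dwell disappears and its neighbours merge
  seg2 <- structure(list(breakpoints = c(580L, 582L, 1160L),
                         labels = c("CS", "OS", "CS", "OS"),
                         levels = c(900, 827, 900, 827), n = 1500L),
                    class = "segmentation")
  dw2 <- extract_dwells(seg2, f_s_eff = 5.8, t_min = 1)
  expect_equal(nrow(dw2), 2L)   # short OS dropped, flanking CS merged
  expect_identical(dw2$label, c("CS", "OS"))
  expect_true(all(dw2$duration_s >= 1))
  expect_equal(sum(dw2$duration_s), 1500 / 5.8, tolerance = 1e-12)
})

test_that("retained dwell counts track ground truth above t_min", {
  r <- fixture_rates()
  n_est <- 0; n_true <- 0
  for (s in 1:4) {
    traj <- simulate_trajectory(r, 3000, seed = 140 + s)
    cfg <- trace_config(r, duration = 3000, seed = 170 + s)
    tr <- render_trace(traj, cfg)
    dw <- extract_dwells(label_segments(tr$z, detect_changepoints(tr$z)),
                         f_s_eff = 5.8, t_min = 0.09)
    n_est <- n_est + sum(!dw$censored)
    td <- true_dwells(traj)
    n_true <- n_true + sum(!td$censored & td$duration_s >= 0.09)
  }
  expect_lt(abs(n_est - n_true) / n_true, 0.05)
})

test_that("Allan deviation: zero for constants, -1/2 slope for white noise", {
  flat <- allan_deviation(rep(3.2, 256), f_s = 58)
  expect_true(all(flat$adev < 1e-10))
  set.seed(10)
  wn <- allan_deviation(rnorm(2^15, sd = 25), f_s = 58)
  fitl <- lm(log(adev) ~ log(tau), data = wn[wn$tau < 10, ])
  expect_equal(unname(coef(fitl)[2]), -0.5, tolerance = 0.05)
  # correlated (AR-1/OU-like) noise decays monotonically past t_c
  set.seed(11)
  ou <- as.numeric(arima.sim(list(ar = 0.95), 2^15)) * 10
  av <- allan_deviation(ou, f_s = 58)
  tail_part <- av$adev[av$tau > 0.3]   # beyond t_c ~ 1/(58*(1-.95)) = .34 s
  expect_true(all(diff(tail_part) < 0))
})

test_that("correlation time recovers the 1/e lag of AR-1 noise", {
  set.seed(12)
  phi <- 0.9
  x <- as.numeric(arima.sim(list(ar = phi), 2^16))
  tc <- correlation_time(x, f_s = 58)
  expect_equal(tc, -1 / log(phi) / 58, tolerance = 0.15)
  # white noise decorrelates within one sample
  set.seed(13)
  expect_lt(correlation_time(rnorm(4096), 58), 1 / 58)
})

test_that("drift is removed only when it exceeds the threshold", {
  t <- seq(0, 100, by = 0.1)
  z <- 900 + 1.2 * t
  zd <- detrend_extension(t, z)
  expect_lt(diff(range(zd)), 1e-6)
  z2 <- 900 + 0.1 * t
  zd2 <- detrend_extension(t, z2)
  expect_equal(as.numeric(zd2), z2)
})
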