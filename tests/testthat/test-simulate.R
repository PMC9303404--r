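# Gillespie trajectory generator, trace rendering and ground-truth dwells.

test_that("trajectories respect the scheme topology and reproduce bitwise", {
  r <- fixture_rates()
  t1 <- simulate_trajectory(r, 500, seed = 11)
  t2 <- simulate_trajectory(r, 500, seed = 11)
  expect_identical(t1, t2)
  expect_identical(t1$states[1], "R+P")
  expect_true(all(diff(t1$event_times) > 0))
  # k2 = 0: RP_I unreachable
  r0 <- rate_constants(k1 = 0.5, k_neg1 = 2, k2 = 0, R_conc = 2)
  t0 <- simulate_trajectory(r0, 500, seed = 3)
  expect_true(all(t0$states %in% c("R+P", "RP_C")))
  # dead scheme errors
  expect_error(simulate_trajectory(rate_constants(), 10), "absorbing")
})

test_that("closed-state exit rate follows rapid pre-equilibration binding", {
  # k1[R] = 1, k-1 = 10 >> k2 = 0.16: Eq-style k_open = k2 [R]/(K_D + [R])
  r <- rate_constants(k1 = 0.5, k_neg1 = 10, k2 = 0.16, R_conc = 2,
                      k3 = 1e-9, k_neg3 = 1e-9, k5 = 50)
  k_open <- 0.16 * 2 / (10 / 0.5 + 2)        # = P_RPc k2 with K_D = k-1/k1
  dur <- 2100 / k_open * 0.07                # enough for ~2000 CS dwells
  cs <- c()
  for (s in 1:15) {
    td <- true_dwells(simulate_trajectory(r, dur, seed = 100 + s))
    cs <- c(cs, dwell_durations(td, "CS"))
  }
  expect_gt(length(cs), 1500)
  se <- sd(cs) / sqrt(length(cs))
  expect_lt(abs(mean(cs) - 1 / k_open), 3 * se)
})

test_that("open-state dwells follow the accepted-model phase-type law", {
  r <- fixture_rates()
  tau <- simulate_os_dwells(2e4, r$k5, r$k3, r$k_neg3, seed = 5)
  sc <- build_scheme("M4_A3", r)
  ks <- suppressWarnings(
    stats::ks.test(tau, function(q) phase_type_cdf(sc, q)))
  expect_lt(unname(ks$statistic), 0.012)
  # mean matches p+/k+ + p-/k- within 3 SE
  f <- micro_to_fit(r$k5, r$k3, r$k_neg3)
  mu <- (1 - f$p_minus) / f$k_plus + f$p_minus / f$k_minus
  expect_lt(abs(mean(tau) - mu), 3 * sd(tau) / sqrt(length(tau)))
  expect_equal(mu, phase_type_mean(sc), tolerance = 1e-12)
})

test_that("rendering maps states to levels, adds noise, and decimates", {
  r <- fixture_rates()
  # hand-built trajectory: CS 0-10 s, OS 10-20 s, CS 20-30 s
  traj <- structure(list(event_times = c(0, 10, 20),
                         states = c("R+P", "RP_I", "RP_C"),
                         duration = 30), class = "state_trajectory")
  cfg <- trace_config(r, z_CS = 900, jump_pos = 73, noise_sd = 0,
                      duration = 30, decimate = 1, f_s = 58)
  tr <- render_trace(traj, cfg)
  expect_setequal(unique(tr$z), c(900, 827))
  expect_equal(tr$z[tr$t >= 10 & tr$t < 20], rep(827, 580))
  # negative supercoiling uses the smaller jump; RP_O renders like RP_I
  traj$states[2] <- "RP_O"
  cfg2 <- trace_config(r, z_CS = 900, jump_neg = 42,
                       supercoiling_sign = "-", noise_sd = 0,
                       duration = 30, decimate = 1)
  expect_setequal(unique(render_trace(traj, cfg2)$z), c(900, 858))
  # decimation divides white-noise SD by sqrt(decimate)
  cfg3 <- trace_config(r, noise_sd = 25, duration = 600, decimate = 10,
                       seed = 8)
  trn <- render_trace(structure(list(event_times = 0, states = "R+P",
                                     duration = 600),
                                class = "state_trajectory"), cfg3)
  expect_equal(sd(trn$z), 25 / sqrt(10), tolerance = 0.05)
  # drift shows up as the programmed slope
  cfg4 <- trace_config(r, noise_sd = 0, duration = 600, decimate = 10,
                       drift_rate = 0.4)
  trd <- render_trace(structure(list(event_times = 0, states = "R+P",
                                     duration = 600),
                                class = "state_trajectory"), cfg4)
  expect_equal(unname(coef(lm(trd$z ~ trd$t))[2]), 0.4, tolerance = 1e-6)
})

test_that("ground-truth dwells lump states, conserve time, alternate", {
  r <- fixture_rates()
  traj <- simulate_trajectory(r, 3000, seed = 21)
  dw <- true_dwells(traj)
  expect_equal(sum(dw$duration_s), 3000)
  expect_true(all(dw$label %in% c("OS", "CS")))
  expect_true(all(dw$label[-1] != dw$label[-nrow(dw)]))
  expect_true(dw$censored[1] && dw$censored[nrow(dw)])
  # OS dwell count equals the number of RP_C -> RP_I entries
  entries <- sum(traj$states == "RP_I" &
                   c("", traj$states[-length(traj$states)]) == "RP_C")
  expect_equal(sum(dw$label == "OS"), entries)
  # trajectory with no opening: single censored CS dwell
  r0 <- rate_constants(k1 = 0.5, k_neg1 = 2, k2 = 0, R_conc = 2)
  dw0 <- true_dwells(simulate_trajectory(r0, 100, seed = 2))
  expect_equal(nrow(dw0), 1L)
  expect_identical(dw0$label, "CS")
  expect_true(dw0$censored)
})

test_that("open-state occupancy matches the renewal-theory fraction", {
  r <- fixture_rates()
  f <- micro_to_fit(r$k5, r$k3, r$k_neg3)
  mu_os <- (1 - f$p_minus) / f$k_plus + f$p_minus / f$k_minus
  mu_cs <- phase_type_mean(build_scheme("CS_chain", r))
  pred <- mu_os / (mu_os + mu_cs)
  occ <- 0; tot <- 0
  for (s in 1:6) {
    traj <- simulate_trajectory(r, 30000, seed = 300 + s)
    dw <- true_dwells(traj)
    occ <- occ + sum(dw$duration_s[dw$label == "OS"])
    tot <- tot + 30000
  }
  expect_equal(occ / tot, pred, tolerance = 0.02)
})
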