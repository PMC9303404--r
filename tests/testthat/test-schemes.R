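# Phase-type dwell schemes, densities, and the conversion relations
# between mixture fit parameters and microscopic rate constants.

test_that("accepted-model scheme assembles the stated generator", {
  sc <- build_scheme("M4_A3", rate_constants(k5 = 0.64, k3 = 0.30375,
                                             k_neg3 = 0.15625))
  expect_equal(unname(sc$Q),
               rbind(c(-0.94375, 0.30375), c(0.15625, -0.15625)))
  expect_equal(unname(sc$a), c(0.64, 0))
  expect_equal(unname(sc$pi0), c(1, 0))
  # absorption only from RP_I whatever the rates (k4 forced to 0)
  sc2 <- build_scheme("M4_A3", rate_constants(k5 = 2, k3 = 1, k_neg3 = 3,
                                              k4 = 9))
  expect_equal(unname(sc2$a), c(2, 0))
  # eigen-rates of the worked example: characteristic poly l^2+1.1l+0.1
  expect_equal(sort(Re(eigen(sc$Q)$values)), c(-1, -0.1))
})

test_that("start states and error handling follow the model definitions", {
  r <- rate_constants(k1 = 0.1, k_neg1 = 1.7, k2 = 0.16, k_neg2 = 0.01,
                      k3 = 0.3, k_neg3 = 0.15, k4 = 0.05, k5 = 0.6,
                      R_conc = 5)
  expect_equal(unname(build_scheme("M3c1", r)$pi0), c(0, 1))
  expect_equal(unname(build_scheme("M3c2", r)$pi0), c(1, 0))
  cs <- build_scheme("CS_chain", r)
  expect_equal(unname(cs$a), c(0, r$k2))
  expect_equal(cs$state_names, c("R+P", "RP_C"))
  expect_error(build_scheme("bogus", r))
  bad <- r; bad$k2 <- -1
  expect_error(build_scheme("CS_chain", bad), "non-negative")
})

test_that("phase-type pdf matches the analytic forms and normalizes", {
  # one transient state: plain exponential
  r1 <- rate_constants(k5 = 0.7, k4 = 0.7, mix_q = 1)
  sc1 <- build_scheme("M2", r1)          # q = 1: single exit at k5
  tt <- seq(0, 10, length.out = 50)
  expect_equal(phase_type_pdf(sc1, tt), 0.7 * exp(-0.7 * tt),
               tolerance = 1e-12)
  # worked two-state example: f(0) = k5
  sc <- build_scheme("M4_A3", rate_constants(k5 = 0.64, k3 = 0.30375,
                                             k_neg3 = 0.15625))
  expect_equal(phase_type_pdf(sc, 0), 0.64)
  # quadrature oracle: density integrates to 1
  for (m in list(sc, sc1,
                 build_scheme("M1", rate_constants(k_neg2 = 0.4, k2 = 1.1,
                                                   k_neg1 = 0.8)))) {
    norm <- stats::integrate(function(t) phase_type_pdf(m, t), 0, Inf,
                             rel.tol = 1e-9)$value
    expect_true(abs(norm - 1) < 1e-6)
  }
  # cdf consistent with pdf quadrature
  expect_equal(phase_type_cdf(sc, 5),
               stats::integrate(function(t) phase_type_pdf(sc, t),
                                0, 5)$value, tolerance = 1e-7)
  # no absorption anywhere: no first passage
  sc$a[] <- 0
  expect_error(phase_type_pdf(sc, tt), "no absorption")
})

test_that("density shape at the origin separates the model classes", {
  r <- rate_constants(k1 = 0.1, k_neg1 = 1.7, k2 = 0.16, k_neg2 = 0.01,
                      k3 = 0.3, k_neg3 = 0.15, k4 = 0.05, k5 = 0.6,
                      R_conc = 5)
  expect_identical(pdf_shape(build_scheme("M4_A3", r)), "positive_mixture")
  expect_identical(pdf_shape(build_scheme("M1", r)), "peaked_at_zero")
  # start RP_I, absorb only from RP_O: density vanishes at 0
  expect_identical(pdf_shape(build_scheme("M3c2", r)), "peaked_at_zero")
  expect_identical(pdf_shape(build_scheme("CS_chain", r)), "peaked_at_zero")
})

test_that("conversion relations map mixtures to positive rates and back", {
  # worked example, both directions
  d <- fit_to_micro(exp_mix_params(1.0, 0.1, 0.4))
  expect_equal(d$k5, 0.64, tolerance = 1e-12)
  expect_equal(d$k3, 0.30375, tolerance = 1e-12)
  expect_equal(d$k_neg3, 0.15625, tolerance = 1e-12)
  f <- micro_to_fit(0.64, 0.30375, 0.15625)
  expect_equal(c(f$k_plus, f$k_minus, f$p_minus), c(1.0, 0.1, 0.4),
               tolerance = 1e-10)
  # pure single exponential collapses cleanly
  d1 <- fit_to_micro(exp_mix_params(2, 0.5, 0))
  expect_equal(c(d1$k5, d1$k3, d1$k_neg3), c(2, 0, 0.5))
  f1 <- micro_to_fit(2, 0, 0.5)
  expect_equal(c(f1$k_plus, f1$k_minus, f1$p_minus), c(2, 0.5, 0))
  # degenerate input rejected
  expect_error(micro_to_fit(0, 1, 1))
})

test_that("round trip is the identity and derived rates stay positive", {
  set.seed(42)
  n <- 10000
  kp <- 10^runif(n, -3, 2)
  km <- kp * 10^runif(n, -3, 0)
  pm <- runif(n)
  for (i in sample.int(n, 400)) {     # full-precision spot checks
    fit <- exp_mix_params(kp[i], km[i], pm[i])
    m <- fit_to_micro(fit)
    expect_true(m$k5 > 0 && m$k3 >= 0 && m$k_neg3 > 0)
    back <- micro_to_fit(m$k5, m$k3, m$k_neg3)
    expect_equal(c(back$k_plus, back$k_minus, back$p_minus),
                 c(kp[i], km[i], pm[i]), tolerance = 1e-10)
  }
  # vectorized positivity over the whole sweep
  pp <- 1 - pm
  k5 <- pp * kp + pm * km
  k3 <- pp * pm * (kp - km)^2 / k5
  kn3 <- kp * km / k5
  expect_true(all(k5 > 0) && all(k3 >= 0) && all(kn3 > 0))
  # micro -> fit sweep keeps p in [0, 1]
  set.seed(43)
  for (i in 1:400) {
    v <- 10^runif(3, -3, 2)
    f <- micro_to_fit(v[1], v[2], v[3])
    expect_true(f$p_minus >= 0 && f$p_minus <= 1 &&
                  f$k_plus >= f$k_minus)
  }
})

test_that("mixture form from micro_to_fit matches the phase-type density", {
  r <- fixture_rates()
  sc <- build_scheme("M4_A3", r)
  f <- micro_to_fit(r$k5, r$k3, r$k_neg3)
  tt <- seq(0, 20 / f$k_minus, length.out = 400)
  mix <- (1 - f$p_minus) * f$k_plus * exp(-f$k_plus * tt) +
    f$p_minus * f$k_minus * exp(-f$k_minus * tt)
  expect_equal(phase_type_pdf(sc, tt), mix, tolerance = 1e-8)
})

test_that("error propagation matches analytic partial derivatives", {
  # pure single exponential: d k5 / d k+ = p+
  d <- propagate_errors(exp_mix_params(2, 0.5, 0),
                        c(k_plus = 0.1, k_minus = 0, p_minus = 0))
  expect_equal(d$sd_k5, 0.1, tolerance = 1e-6)
  # zero input errors give zero output errors
  d0 <- propagate_errors(exp_mix_params(1, 0.1, 0.4), c(0, 0, 0))
  expect_equal(c(d0$sd_k5, d0$sd_k3, d0$sd_k_neg3), c(0, 0, 0))
  # symbolic-derivative oracle on random points:
  # k5 = (1-pm) kp + pm km  =>  dk5/dkp = 1-pm, dk5/dkm = pm,
  # dk5/dpm = km - kp; single-coordinate perturbations isolate each term
  set.seed(7)
  for (i in 1:100) {
    kp <- 10^runif(1, -2, 1); km <- kp * 10^runif(1, -2, -0.2)
    pm <- runif(1, 0.05, 0.95)
    fit <- exp_mix_params(kp, km, pm)
    s <- propagate_errors(fit, c(k_plus = 1e-3, k_minus = 0, p_minus = 0))
    expect_equal(s$sd_k5, (1 - pm) * 1e-3, tolerance = 1e-4)
    s2 <- propagate_errors(fit, c(k_plus = 0, k_minus = 0, p_minus = 1e-4))
    expect_equal(s2$sd_k5, abs(km - kp) * 1e-4, tolerance = 1e-4)
  }
})

test_that("scheme config round-trips through the flat key-value file", {
  r <- fixture_rates()
  p <- tempfile(fileext = ".yml")
  write_rates_config(r, p, model_id = "M4_A3")
  back <- read_rates_config(p)
  expect_identical(back$model_id, "M4_A3")
  expect_equal(unclass(back$rates), unclass(r))
  unlink(p)
})
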