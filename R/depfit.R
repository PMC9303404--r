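# Dependence of the extracted rate constants on holoenzyme concentration
# (rapid pre-equilibration binding model), temperature (Arrhenius and the
# coupled binding-Arrhenius form) and monovalent-salt concentration
# (log-log sensitivity slopes).

#' Gas constant in kcal/mol/K
#'
#' Used to express activation energies in kcal/mol; multiply by 4.184 for
#' kJ/mol.
#' @export
R_GAS_KCAL <- 1.98720425e-3

#' Fit the holo-concentration dependence of the opening rate
#'
#' Rapid pre-equilibration binding model: holo binding/unbinding
#' equilibrates fast relative to the closed-to-open isomerization, so the
#' observed opening rate is `k_open = k2 * [R] / (K_D + [R])` with
#' `K_D = k_-1 / k1`. Fitted by (optionally weighted) nonlinear least
#' squares.
#'
#' @param R_conc Holoenzyme concentrations (nM), length >= 3.
#' @param k_open Observed opening rate constants (1/s), all > 0.
#' @param sd Optional one-SD errors of `k_open`; supplies weights
#'   `1/sd^2`.
#' @return Object of class `binding_fit`: list with `K_D` (nM), `k2`
#'   (1/s), `sds`, `resid_norm` and the `nls` fit object. A relative SD
#'   above 1 on `K_D` flags an unidentifiable (flat) curve.
#' @export
fit_binding <- function(R_conc, k_open, sd = NULL) {
  stopifnot(length(R_conc) == length(k_open), length(R_conc) >= 3,
            all(k_open > 0), all(R_conc >= 0))
  df <- data.frame(R = R_conc, k = k_open)
  w <- if (is.null(sd)) rep(1, nrow(df)) else 1 / sd^2
  # linearized start: 1/k = (K_D/k2) (1/R) + 1/k2
  pos <- df$R > 0
  lin <- stats::lm(I(1 / k) ~ I(1 / R), data = df[pos, ])
  k2_0 <- 1 / max(stats::coef(lin)[1], .Machine$double.eps)
  KD_0 <- max(stats::coef(lin)[2] * k2_0, min(df$R[pos]) / 10)
  fit <- minpack.lm::nlsLM(k ~ k2 * R / (KD + R), data = df,
                           start = list(k2 = k2_0, KD = KD_0),
                           weights = w,
                           lower = c(k2 = 1e-12, KD = 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
                 error = function(e) c(k2 = NA_real_, KD = NA_real_))
  structure(list(K_D = unname(cf["KD"]), k2 = unname(cf["k2"]),
                 sds = c(K_D = unname(se["KD"]), k2 = unname(se["k2"])),
                 resid_norm = sqrt(sum(stats::resid(fit)^2)),
                 fit = fit),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Binding fit: K_D = %.4g nM (sd %.3g), k2 = %.4g 1/s (sd %.3g)\n",
              x$K_D, x$sds["K_D"], x$k2, x$sds["k2"]))
  invisible(x)
}

#' Arrhenius fit of a rate constant versus temperature
#'
#' Linear least squares of `log(k)` against `1/T` for
#' `k = k0 exp(-dE / (R_gas T))`. Negative activation energies are
#' permitted: an apparently negative `dE` indicates that the observed rate
#' is not an elementary step but proceeds through a stabilizing
#' intermediate.
#'
#' @param k Rate constants (1/s), all > 0.
#' @param temp_C Temperatures (degrees Celsius), length >= 2, not all
#'   equal.
#' @param sd Optional one-SD errors of `k` (weights `(k/sd)^2` on the log
#'   scale).
#' @return Object of class `arrhenius_fit`: `k0` (1/s), `dE` (kcal/mol),
#'   `dE_kJ` (kJ/mol), `sds`.
#' @export
fit_arrhenius <- function(k, temp_C, sd = NULL) {
  stopifnot(length(k) == length(temp_C), length(k) >= 2, all(k > 0))
  TK <- temp_C + 273.15
  if (length(unique(TK)) < 2) stop("need at least two distinct temperatures")
  w <- if (is.null(sd)) rep(1, length(k)) else (k / sd)^2
  fit <- stats::lm(log(k) ~ I(1 / TK), weights = w)
  cf <- stats::coef(fit)
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
                 error = function(e) rep(NA_real_, 2))
  dE <- -cf[2] * R_GAS_KCAL
  structure(list(k0 = unname(exp(cf[1])), dE = unname(dE),
                 dE_kJ = unname(dE) * 4.184,
                 sds = c(k0 = unname(exp(cf[1]) * se[1]),
                         dE = unname(R_GAS_KCAL * se[2])),
                 fit = fit),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit: k0 = %.4g 1/s, dE = %.4g kcal/mol (%.4g kJ/mol)\n",
              x$k0, x$dE, x$dE_kJ))
  invisible(x)
}

kopen_temp_model <- function(lk2, dE2, lKD, dEd, invT_c, R_conc) {
  # reference-temperature parametrization: invT_c = 1/T - 1/T0
  k2 <- exp(lk2 - dE2 * invT_c / R_GAS_KCAL)
  KD <- exp(lKD - dEd * invT_c / R_GAS_KCAL)
  k2 * R_conc / (KD + R_conc)
}

#' Temperature dependence of the opening rate with binding turnover
#'
#' Fits `k_open(T) = k2(T) [R] / (K_D(T) + [R])` with Arrhenius forms
#' `k2(T) = k2_0 exp(-dE2 / (R_gas T))` and
#' `K_D(T) = KD_0 exp(-dE_diff / (R_gas T))`,
#' `dE_diff = dE_-1 - dE_1`. When `dE_diff > dE2` the fitted curve is
#' non-monotonic in temperature: isomerization limits the reaction at low
#' temperature and holo dissociation from the closed complex at high
#' temperature. Internally the Arrhenius factors are anchored at the mean
#' inverse temperature (decorrelating prefactors and energies); multi-start
#' nonlinear least squares, unweighted.
#'
#' @param k_open Opening rates (1/s) at each temperature, all > 0.
#' @param temp_C Temperatures (degrees Celsius), length >= 4, spanning the
#'   turnover.
#' @param R_conc Holoenzyme concentration (nM, scalar).
#' @param n_starts Number of energy-grid starts.
#' @return Object of class `temp_binding_fit`: `k2_0` (1/s), `dE2`
#'   (kcal/mol), `KD_0` (nM), `dE_diff` (kcal/mol), kJ echoes, `sds`
#'   (on the energies), `resid_norm`.
#' @export
fit_kopen_temperature <- function(k_open, temp_C, R_conc, n_starts = 24) {
  stopifnot(length(k_open) == length(temp_C), length(k_open) >= 4,
            all(k_open > 0), R_conc > 0)
  TK <- temp_C + 273.15
  invT0 <- mean(1 / TK)
  df <- data.frame(k = k_open, invT_c = 1 / TK - invT0)

  grid <- expand.grid(dE2 = c(5, 20, 50), dEd = c(0, 20, 60, 120, 250),
                      lKD = log(R_conc) + c(-1, 1))
  grid <- grid[seq_len(min(nrow(grid), n_starts)), ]
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    st <- list(lk2 = log(max(k_open)), dE2 = grid$dE2[i],
               lKD = grid$lKD[i], dEd = grid$dEd[i])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        k ~ kopen_temp_model(lk2, dE2, lKD, dEd, invT_c, R_conc),
        data = df, start = st,
        control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("temperature fit failed to converge from all starts")
  cf <- stats::coef(best$fit)
  se <- tryCatch(suppressWarnings(
    summary(best$fit)$coefficients[, "Std. Error"]),
                 error = function(e) stats::setNames(rep(NA_real_, 4),
                                                     names(cf)))
  k2_0 <- exp(cf[["lk2"]] + cf[["dE2"]] * invT0 / R_GAS_KCAL)
  KD_0 <- exp(cf[["lKD"]] + cf[["dEd"]] * invT0 / R_GAS_KCAL)
  structure(list(k2_0 = k2_0, dE2 = cf[["dE2"]],
                 KD_0 = KD_0, dE_diff = cf[["dEd"]],
                 dE2_kJ = cf[["dE2"]] * 4.184,
                 dE_diff_kJ = cf[["dEd"]] * 4.184,
                 sds = c(dE2 = unname(se["dE2"]), dE_diff = unname(se["dEd"])),
                 resid_norm = sqrt(best$rss),
                 R_conc = R_conc, invT0 = invT0, fit = best$fit),
            class = "temp_binding_fit")
}

#' @export
print.temp_binding_fit <- function(x, ...) {
  cat(sprintf(
    "Opening-rate temperature fit: dE2 = %.4g kcal/mol, dE_diff = %.4g kcal/mol\n",
    x$dE2, x$dE_diff))
  cat(sprintf("  k2_0 = %.4g 1/s, KD_0 = %.4g nM (at [R] = %.3g nM)\n",
              x$k2_0, x$KD_0, x$R_conc))
  invisible(x)
}

#' Predicted opening rate from a temperature fit
#'
#' @param object A `temp_binding_fit`.
#' @param temp_C Temperatures (degrees Celsius).
#' @param ... Unused.
#' @export
predict.temp_binding_fit <- function(object, temp_C, ...) {
  cf <- stats::coef(object$fit)
  kopen_temp_model(cf[["lk2"]], cf[["dE2"]], cf[["lKD"]], cf[["dEd"]],
                   1 / (temp_C + 273.15) - object$invT0, object$R_conc)
}

#' Salt sensitivity of a rate constant
#'
#' The sensitivity `S = d log(k) / d log([salt])`, estimated as the slope
#' of a least-squares line of `log(k)` versus `log([salt])`; `k`
#' proportional to `[salt]^S` gives exactly `S`.
#'
#' @param k Rate constants (1/s), all > 0.
#' @param salt_conc Salt concentrations (mM), all > 0, length >= 2.
#' @return Object of class `salt_sensitivity`: `S` (dimensionless) and
#'   `sd`.
#' @export
salt_sensitivity <- function(k, salt_conc) {
  stopifnot(length(k) == length(salt_conc), length(k) >= 2,
            all(k > 0), all(salt_conc > 0))
  fit <- stats::lm(log(k) ~ log(salt_conc))
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients[2, "Std. Error"]),
                 error = function(e) NA_real_)
  structure(list(S = unname(stats::coef(fit)[2]), sd = unname(se),
                 fit = fit),
            class = "salt_sensitivity")
}

#' @export
print.salt_sensitivity <- function(x, ...) {
  cat(sprintf("Salt sensitivity: S = d ln k / d ln [salt] = %.3g (sd %.3g)\n",
              x$S, x$sd))
  invisible(x)
}
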