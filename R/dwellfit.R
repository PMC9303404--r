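# Maximum-likelihood fitting of dwell-time distributions: one versus two
# exponentials, left-truncated at the minimum resolvable dwell, with BIC
# model selection and bootstrap errors.

get_tau <- function(dwells, label = NULL) {
  if (inherits(dwells, "dwell_set")) {
    tau <- dwell_durations(dwells, label = label)
  } else {
    tau <- as.numeric(dwells)
  }
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("dwell durations must be positive and finite")
  tau
}

new_expmix_fit <- function(model, params, logL, n, t_min,
                           sds = NULL, n_boot = 0L) {
  m <- if (model == "single") 1L else 3L
  structure(list(model = model, params = params, logL = logL, n = n,
                 bic = m * log(n) - 2 * logL, t_min = t_min,
                 sds = sds, n_boot = n_boot),
            class = "expmix_fit")
}

#' @export
print.expmix_fit <- function(x, ...) {
  cat(sprintf("%s-exponential dwell fit (n = %d, t_min = %.3g s)\n",
              if (x$model == "single") "Single" else "Double", x$n, x$t_min))
  p <- unlist(x$params)
  s <- if (is.null(x$sds)) rep(NA_real_, length(p)) else
    unlist(x$sds)[names(p)]
  for (i in seq_along(p))
    cat(sprintf("  %-8s %.5g  (sd %.3g)\n", names(p)[i], p[i], s[i]))
  cat(sprintf("  logL = %.4f, BIC = %.4f\n", x$logL, x$bic))
  invisible(x)
}

#' Single-exponential dwell-time fit (closed form)
#'
#' MLE of `f(t) = k exp(-k (t - t_min))` for dwells left-truncated at
#' `t_min`: `k_hat = 1 / (mean(tau) - t_min)`.
#'
#' @param dwells A `dwell_set` (uncensored dwells are used) or a numeric
#'   vector of durations (s).
#' @param label Dwell label to fit when `dwells` is a `dwell_set`
#'   (`"OS"`/`"CS"`; `NULL` uses all uncensored dwells).
#' @param t_min Left-truncation point (s); defaults to the `dwell_set`
#'   attribute, else 0.
#' @return An object of class `expmix_fit` with `model = "single"`,
#'   `params$k`, `logL`, `n` and `bic = log(n) - 2 logL`.
#' @export
fit_single_exp <- function(dwells, label = NULL, t_min = NULL) {
  if (is.null(t_min))
    t_min <- if (inherits(dwells, "dwell_set")) attr(dwells, "t_min") else 0
  tau <- get_tau(dwells, label)
  if (length(tau) < 1L) stop("need at least one uncensored dwell")
  if (any(tau < t_min)) stop("dwells shorter than 't_min' present")
  mbar <- mean(tau) - t_min
  if (mbar <= 0) stop("degenerate data: mean dwell <= t_min")
  k <- 1 / mbar
  n <- length(tau)
  logL <- n * log(k) - k * sum(tau - t_min)
  new_expmix_fit("single", list(k = k), logL, n, t_min)
}

# log density of the truncated double-exponential mixture at theta =
# (log k+, log k-, logit p-)
expmix_nll <- function(theta, tau, t_min) {
  kp <- exp(theta[1]); km <- exp(theta[2])
  pm <- stats::plogis(theta[3]); pp <- 1 - pm
  # log f(tau) by log-sum-exp
  a <- log(pp) + log(kp) - kp * tau
  b <- log(pm) + log(km) - km * tau
  mx <- pmax(a, b)
  lf <- mx + log(exp(a - mx) + exp(b - mx))
  # survival at t_min for renormalization
  lS <- if (t_min > 0) {
    sa <- log(pp) - kp * t_min
    sb <- log(pm) - km * t_min
    ms <- max(sa, sb)
    ms + log(exp(sa - ms) + exp(sb - ms))
  } else 0
  -(sum(lf) - length(tau) * lS)
}

# analytic gradient of expmix_nll in (log k+, log k-, logit p-), written
# with per-observation component responsibilities so it stays finite when
# one component's density underflows
expmix_nll_grad <- function(theta, tau, t_min) {
  kp <- exp(theta[1]); km <- exp(theta[2])
  pm <- stats::plogis(theta[3]); pp <- 1 - pm
  la <- log(pp) + log(kp) - kp * tau
  lb <- log(pm) + log(km) - km * tau
  mx <- pmax(la, lb)
  wa <- exp(la - mx); wb <- exp(lb - mx)
  ra <- wa / (wa + wb); rb <- 1 - ra        # responsibilities
  g1 <- sum(ra * (1 - kp * tau))            # d logL / d log k+
  g2 <- sum(rb * (1 - km * tau))            # d logL / d log k-
  g3 <- sum(pp * rb - pm * ra)              # d logL / d logit p-
  if (t_min > 0) {
    sa <- log(pp) - kp * t_min
    sb <- log(pm) - km * t_min
    ms <- max(sa, sb)
    qa <- exp(sa - ms); qb <- exp(sb - ms)
    Ra <- qa / (qa + qb); Rb <- 1 - Ra      # survival responsibilities
    n <- length(tau)
    g1 <- g1 + n * Ra * kp * t_min
    g2 <- g2 + n * Rb * km * t_min
    g3 <- g3 - n * (pp * Rb - pm * Ra)
  }
  -c(g1, g2, g3)
}

#' Double-exponential dwell-time fit
#'
#' Maximizes the likelihood of
#' `f(t) = p+ k+ exp(-k+ t) + p- k- exp(-k- t)`, renormalized on
#' `[t_min, Inf)` when `t_min > 0`, by bounded quasi-Newton search
#' (`optim` with L-BFGS-B) over `(log k+, log k-, logit p-)`. The label
#' switching of the mixture is resolved by relabelling so that
#' `k+ >= k-`. The best of `restarts` initializations (one moment-based,
#' the rest stratified random) is returned.
#'
#' @inheritParams fit_single_exp
#' @param restarts Number of initializations (>= 1).
#' @param seed Optional seed for the random restarts.
#' @return An `expmix_fit` with `model = "double"` and
#'   `params = list(k_plus, k_minus, p_minus)`.
#' @export
fit_double_exp <- function(dwells, label = NULL, t_min = NULL,
                           restarts = 8, seed = NULL) {
  if (is.null(t_min))
    t_min <- if (inherits(dwells, "dwell_set")) attr(dwells, "t_min") else 0
  tau <- get_tau(dwells, label)
  n <- length(tau)
  if (n < 4L) stop("need at least 4 uncensored dwells")
  if (any(tau < t_min)) stop("dwells shorter than 't_min' present")
  if (!is.null(seed)) set.seed(seed)

  k1 <- 1 / max(mean(tau) - t_min, .Machine$double.eps)
  inits <- list(c(log(4 * k1), log(k1 / 4), 0))
  if (restarts > 1) {
    for (i in seq_len(restarts - 1L)) {
      u <- stats::runif(3)
      inits[[i + 1L]] <- c(log(k1) + u[1] * 4,       # k+ in [k1, 55 k1]
                           log(k1) - u[2] * 4,       # k- in [k1/55, k1]
                           stats::qlogis(0.05 + 0.9 * u[3]))
    }
  }
  lb <- c(log(1e-8), log(1e-8), -12)
  ub <- c(log(1e6), log(1e6), 12)
  best <- NULL
  for (th0 in inits) {
    res <- tryCatch(
      stats::optim(th0, expmix_nll, gr = expmix_nll_grad,
                   tau = tau, t_min = t_min,
                   method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("double-exponential fit failed to converge")

  kp <- exp(best$par[1]); km <- exp(best$par[2])
  pm <- stats::plogis(best$par[3])
  if (kp < km) { tmp <- kp; kp <- km; km <- tmp; pm <- 1 - pm }
  new_expmix_fit("double",
                 list(k_plus = kp, k_minus = km, p_minus = pm),
                 -best$value, n, t_min)
}

#' Select between single- and double-exponential dwell models
#'
#' Returns the model with the lower Bayesian (Schwarz) information
#' criterion `BIC = m log(n) - 2 logL` (`m` = 1 or 3 free parameters);
#' ties favour the single exponential.
#'
#' @param fit1,fit2 `expmix_fit` objects for the single and double model,
#'   fitted on the same dwell set.
#' @return `"single"` or `"double"`.
#' @export
select_model <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "expmix_fit"), inherits(fit2, "expmix_fit"))
  if (fit1$n != fit2$n)
    stop("fits must be computed on the same dwell set")
  if (fit1$model == fit2$model) stop("expected one single and one double fit")
  single <- if (fit1$model == "single") fit1 else fit2
  double <- if (fit1$model == "double") fit1 else fit2
  if (single$bic <= double$bic) "single" else "double"
}

#' Bootstrap errors of dwell-fit parameters
#'
#' Resamples the dwells with replacement `n_boot` times, refits with
#' `fitter`, and reports the standard deviation of each parameter across
#' replicates. Replicates whose fit fails are dropped and counted; more
#' than 20% failures signals an unstable fit.
#'
#' @param dwells Dwell durations (vector or `dwell_set`).
#' @param fitter Fitting function called as `fitter(tau, t_min = t_min)`
#'   and returning an `expmix_fit`, e.g. [fit_single_exp()] or a wrapper
#'   around [fit_double_exp()].
#' @param n_boot Number of bootstrap replicates (1000 by default).
#' @param seed Optional seed.
#' @param label,t_min As in [fit_single_exp()].
#' @return Named list: `sds` (per-parameter one-SD errors), `n_fail`,
#'   `n_boot`.
#' @export
bootstrap_errors <- function(dwells, fitter, n_boot = 1000, seed = NULL,
                             label = NULL, t_min = NULL) {
  if (is.null(t_min))
    t_min <- if (inherits(dwells, "dwell_set")) attr(dwells, "t_min") else 0
  tau <- get_tau(dwells, label)
  if (!is.null(seed)) set.seed(seed)
  n <- length(tau)
  reps <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    tb <- tau[sample.int(n, n, replace = TRUE)]
    reps[[b]] <- tryCatch(unlist(fitter(tb, t_min = t_min)$params),
                          error = function(e) NULL)
  }
  ok <- !vapply(reps, is.null, logical(1))
  if (mean(!ok) > 0.2)
    stop("bootstrap unstable: more than 20% of replicates failed to fit")
  mat <- do.call(rbind, reps[ok])
  list(sds = apply(mat, 2, stats::sd), n_fail = sum(!ok), n_boot = n_boot)
}

#' One-stop dwell-distribution fit with model selection and errors
#'
#' Fits both the single- and double-exponential models, selects by BIC,
#' and attaches bootstrap one-SD errors to the selected fit.
#'
#' @inheritParams fit_double_exp
#' @param n_boot Bootstrap replicates for the errors (0 skips the
#'   bootstrap).
#' @param boot_restarts Restarts used inside bootstrap refits of the
#'   double model (fewer than for the primary fit, for speed).
#' @return The selected `expmix_fit`, with `sds` and `n_boot` filled in,
#'   plus attribute `alternative` holding the unselected fit.
#' @export
fit_dwell_distribution <- function(dwells, label = NULL, t_min = NULL,
                                   restarts = 8, n_boot = 200,
                                   boot_restarts = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f1 <- fit_single_exp(dwells, label = label, t_min = t_min)
  f2 <- fit_double_exp(dwells, label = label, t_min = t_min,
                       restarts = restarts)
  pick <- select_model(f1, f2)
  sel <- if (pick == "single") f1 else f2
  alt <- if (pick == "single") f2 else f1
  if (n_boot > 0) {
    fitter <- if (pick == "single") {
      function(tb, t_min) fit_single_exp(tb, t_min = t_min)
    } else {
      function(tb, t_min) fit_double_exp(tb, t_min = t_min,
                                         restarts = boot_restarts)
    }
    bs <- bootstrap_errors(dwells, fitter, n_boot = n_boot,
                           label = label, t_min = sel$t_min)
    sel$sds <- as.list(bs$sds)
    sel$n_boot <- n_boot
  }
  attr(sel, "alternative") <- alt
  sel
}
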