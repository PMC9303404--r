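# Kinetic schemes for promoter open/closed-state dwell times.
#
# The observable open state (OS) lumps the open intermediate RP_I and the
# stable open complex RP_O; the closed state (CS) lumps the free promoter
# R+P and the closed complex RP_C.  An OS (or CS) dwell is the first-passage
# time of a small continuous-time Markov chain to absorption, i.e. a
# phase-type random variable with density f(t) = pi0' expm(Q t) a.

#' Rate constants of the promoter binding/opening scheme
#'
#' Bundles the microscopic rate constants of the scheme
#' R + P <-> RP_C -> RP_I <-> RP_O, with holoenzyme dissociation from RP_I
#' (rate `k5`) and optionally from RP_O (rate `k4`).
#'
#' @param k1 Association rate constant (1/nM/s).
#' @param k_neg1 Dissociation rate from RP_C (1/s).
#' @param k2 RP_C -> RP_I isomerization rate (1/s).
#' @param k_neg2 RP_I -> RP_C reverse isomerization rate (1/s); the forward
#'   isomerization is treated as effectively irreversible, so the default
#'   is 0 and only the reversed-pathway model `M1` uses a nonzero value.
#' @param k3 RP_I -> RP_O rate (1/s).
#' @param k_neg3 RP_O -> RP_I rate (1/s).
#' @param k4 Dissociation rate from RP_O (1/s); 0 in the accepted model.
#' @param k5 Dissociation rate from RP_I (1/s).
#' @param R_conc Holoenzyme concentration (nM).
#' @param mix_q Start-state weight of the first pathway in the two-parallel-
#'   pathway model `M2` (dimensionless, in `[0, 1]`).
#' @return An object of class `rate_constants` (a named list).
#' @export
rate_constants <- function(k1 = 0, k_neg1 = 0, k2 = 0, k_neg2 = 0,
                           k3 = 0, k_neg3 = 0, k4 = 0, k5 = 0,
                           R_conc = 0, mix_q = 0.5) {
  r <- list(k1 = k1, k_neg1 = k_neg1, k2 = k2, k_neg2 = k_neg2,
            k3 = k3, k_neg3 = k_neg3, k4 = k4, k5 = k5,
            R_conc = R_conc, mix_q = mix_q)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("rate constant '", nm, "' must be a finite numeric scalar")
    if (v < 0) stop("rate constant '", nm, "' must be >= 0")
  }
  if (r$mix_q > 1) stop("'mix_q' must lie in [0, 1]")
  class(r) <- "rate_constants"
  r
}

as_rate_constants <- function(x) {
  if (inherits(x, "rate_constants")) return(x)
  if (is.list(x)) return(do.call(rate_constants, x[names(x) %in%
    c("k1", "k_neg1", "k2", "k_neg2", "k3", "k_neg3", "k4", "k5",
      "R_conc", "mix_q")]))
  stop("cannot interpret 'rates' as rate constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Promoter scheme rate constants (1/s; k1 in 1/nM/s):\n")
  v <- unlist(x)
  print(signif(v, 4))
  invisible(x)
}

scheme_models <- c("M1", "M2", "M3c1", "M3c2",
                   "M4_full", "M4_A1", "M4_A2", "M4_A3", "CS_chain")

need_rates <- function(rates, nms, model_id) {
  for (nm in nms) {
    v <- rates[[nm]]
    if (is.null(v) || !is.finite(v) || v < 0)
      stop("model ", model_id, " requires a non-negative rate '", nm, "'")
  }
}

#' Build the first-passage (phase-type) scheme for a dwell-time model
#'
#' Assembles the generator over transient states, the per-state absorption
#' rates and the initial distribution for one of the candidate models of the
#' OS dwell time (or, for `"CS_chain"`, of the CS dwell time).
#'
#' Models:
#' \describe{
#'   \item{M1}{Reversed pathway: OS starts in RP_I, walks back through RP_C
#'     (rates `k_neg2`, `k2`) and dissociates from RP_C at `k_neg1`.}
#'   \item{M2}{Two parallel single-exit pathways with exit rates `k5` and
#'     `k4`, entered with probabilities `mix_q` and `1 - mix_q`.}
#'   \item{M3c1, M3c2}{Dissociation only from RP_O (rate `k4`); the OS starts
#'     in RP_O (case 1) or RP_I (case 2).}
#'   \item{M4_full, M4_A1}{Dissociation from both RP_I (`k5`) and RP_O
#'     (`k4`); assumption 1 (rapid RP_I/RP_O equilibrium) shares the same
#'     generator and differs only in how fit parameters are mapped back.}
#'   \item{M4_A2}{`k_neg3` forced to 0 (RP_O irreversible).}
#'   \item{M4_A3}{`k4` forced to 0 (dissociation only via RP_I); the accepted
#'     model.}
#'   \item{CS_chain}{CS dwell: transient states R+P and RP_C with
#'     pseudo-first-order binding at `k1 * R_conc`, unbinding at `k_neg1`,
#'     absorption into RP_I at `k2`.}
#' }
#'
#' @param model_id One of `"M1"`, `"M2"`, `"M3c1"`, `"M3c2"`, `"M4_full"`,
#'   `"M4_A1"`, `"M4_A2"`, `"M4_A3"`, `"CS_chain"`.
#' @param rates A [rate_constants()] object (or coercible list).
#' @return An object of class `kinetic_scheme`: list with `model_id`,
#'   `state_names`, generator `Q` (off-diagonal >= 0, row sums <= 0),
#'   absorption rates `a = -rowSums(Q)` restricted to exits that leave the
#'   lumped observable state, and initial distribution `pi0`.
#' @export
build_scheme <- function(model_id, rates) {
  model_id <- match.arg(model_id, scheme_models)
  r <- as_rate_constants(rates)
  sc <- switch(model_id,
    M1 = {
      need_rates(r, c("k_neg2", "k2", "k_neg1"), model_id)
      list(states = c("RP_I", "RP_C"),
           Q = rbind(c(-r$k_neg2, r$k_neg2),
                     c(r$k2, -(r$k2 + r$k_neg1))),
           pi0 = c(1, 0))
    },
    M2 = {
      need_rates(r, c("k5", "k4", "mix_q"), model_id)
      list(states = c("RP_I_a", "RP_I_b"),
           Q = rbind(c(-r$k5, 0), c(0, -r$k4)),
           pi0 = c(r$mix_q, 1 - r$mix_q))
    },
    M3c1 = ,
    M3c2 = {
      need_rates(r, c("k3", "k_neg3", "k4"), model_id)
      list(states = c("RP_I", "RP_O"),
           Q = rbind(c(-r$k3, r$k3),
                     c(r$k_neg3, -(r$k_neg3 + r$k4))),
           pi0 = if (model_id == "M3c1") c(0, 1) else c(1, 0))
    },
    M4_full = ,
    M4_A1 = {
      need_rates(r, c("k5", "k3", "k_neg3", "k4"), model_id)
      list(states = c("RP_I", "RP_O"),
           Q = rbind(c(-(r$k5 + r$k3), r$k3),
                     c(r$k_neg3, -(r$k_neg3 + r$k4))),
           pi0 = c(1, 0))
    },
    M4_A2 = {
      need_rates(r, c("k5", "k3", "k4"), model_id)
      list(states = c("RP_I", "RP_O"),
           Q = rbind(c(-(r$k5 + r$k3), r$k3),
                     c(0, -r$k4)),
           pi0 = c(1, 0))
    },
    M4_A3 = {
      need_rates(r, c("k5", "k3", "k_neg3"), model_id)
      list(states = c("RP_I", "RP_O"),
           Q = rbind(c(-(r$k5 + r$k3), r$k3),
                     c(r$k_neg3, -r$k_neg3)),
           pi0 = c(1, 0))
    },
    CS_chain = {
      need_rates(r, c("k1", "R_conc", "k_neg1", "k2"), model_id)
      k1R <- r$k1 * r$R_conc
      list(states = c("R+P", "RP_C"),
           Q = rbind(c(-k1R, k1R),
                     c(r$k_neg1, -(r$k_neg1 + r$k2))),
           pi0 = c(1, 0))
    })
  out <- list(model_id = model_id,
              state_names = sc$states,
              Q = sc$Q,
              a = -rowSums(sc$Q),
              pi0 = sc$pi0)
  dimnames(out$Q) <- list(sc$states, sc$states)
  names(out$a) <- names(out$pi0) <- sc$states
  class(out) <- "kinetic_scheme"
  out
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Phase-type dwell scheme '", x$model_id, "' over states: ",
      paste(x$state_names, collapse = ", "), "\n", sep = "")
  cat("Generator Q (1/s):\n"); print(signif(x$Q, 5))
  cat("Absorption rates a:", paste(signif(x$a, 5), collapse = ", "), "\n")
  cat("Initial distribution pi0:", paste(signif(x$pi0, 5), collapse = ", "),
      "\n")
  invisible(x)
}

# Spectral pieces of a scheme: density f(t) = sum_j w_j * (-lambda_j) *
# exp(lambda_j t) whenever Q is diagonalizable; returns NULL if the
# eigenbasis is ill-conditioned (caller falls back to expm()).
scheme_spectrum <- function(scheme) {
  e <- eigen(scheme$Q)
  lam <- e$values
  if (any(abs(Im(lam)) > 1e-10 * max(abs(lam), 1)))
    return(NULL)  # complex pair: keep exactness via expm fallback
  V <- Re(e$vectors)
  if (abs(det(V)) < 1e-12) return(NULL)  # defective (repeated eigenvalue)
  lam <- Re(lam)
  left <- drop(scheme$pi0 %*% V)            # pi0' V
  right <- drop(solve(V, scheme$a))         # V^-1 a
  list(lambda = lam, coef = left * right)   # f(t) = sum coef_j e^{lambda_j t}
}

scheme_check_absorbing <- function(scheme) {
  if (all(scheme$a <= 0))
    stop("scheme has no absorption (all exit rates zero): no first passage")
}

#' Phase-type first-passage density of a dwell scheme
#'
#' Evaluates `f(t) = pi0' expm(Q t) a`, the density of the time to
#' absorption of the transient chain. Uses the eigendecomposition of `Q`
#' when it is cleanly diagonalizable and falls back to scaling-and-squaring
#' (`Matrix::expm`) otherwise.
#'
#' @param scheme A [build_scheme()] result.
#' @param t Non-negative time grid (s).
#' @return Density values (1/s), same length as `t`.
#' @export
phase_type_pdf <- function(scheme, t) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (any(t < 0)) stop("'t' must be non-negative")
  scheme_check_absorbing(scheme)
  sp <- scheme_spectrum(scheme)
  if (!is.null(sp)) {
    f <- drop(exp(outer(t, sp$lambda)) %*% sp$coef)
  } else {
    f <- vapply(t, function(ti) {
      E <- as.matrix(Matrix::expm(scheme$Q * ti))
      drop(scheme$pi0 %*% E %*% scheme$a)
    }, numeric(1))
  }
  pmax(f, 0)
}

#' Phase-type first-passage distribution function
#'
#' `F(t) = 1 - pi0' expm(Q t) 1`, the probability that absorption has
#' occurred by time `t`.
#'
#' @inheritParams phase_type_pdf
#' @export
phase_type_cdf <- function(scheme, t) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (any(t < 0)) stop("'t' must be non-negative")
  scheme_check_absorbing(scheme)
  sp <- scheme_spectrum(scheme)
  ones <- rep(1, length(scheme$pi0))
  if (!is.null(sp)) {
    e <- eigen(scheme$Q)
    V <- Re(e$vectors)
    coef <- drop(scheme$pi0 %*% V) * drop(solve(V, ones))
    surv <- drop(exp(outer(t, sp$lambda)) %*% coef)
  } else {
    surv <- vapply(t, function(ti) {
      E <- as.matrix(Matrix::expm(scheme$Q * ti))
      drop(scheme$pi0 %*% E %*% ones)
    }, numeric(1))
  }
  pmin(pmax(1 - surv, 0), 1)
}

#' Mean first-passage time of a dwell scheme
#'
#' `E[T] = pi0' (-Q)^{-1} 1`; used as the generator-truth mean dwell.
#'
#' @inheritParams phase_type_pdf
#' @export
phase_type_mean <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  scheme_check_absorbing(scheme)
  drop(scheme$pi0 %*% solve(-scheme$Q, rep(1, length(scheme$pi0))))
}

#' Qualitative shape of the dwell-time density at the origin
#'
#' A scheme whose start states carry no direct absorption has `f(0+) = 0`:
#' its density rises from zero ("peaked", resembling a gamma density)
#' rather than being a positive mixture of decaying exponentials. This
#' dichotomy drives the keep/discard logic over the candidate dwell models.
#'
#' @inheritParams phase_type_pdf
#' @return `"positive_mixture"` if `f(0+) = pi0' a > 0`, else
#'   `"peaked_at_zero"`.
#' @export
pdf_shape <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  f0 <- sum(scheme$pi0 * scheme$a)
  if (f0 > 1e-12 * max(scheme$a, 1)) "positive_mixture" else "peaked_at_zero"
}

#' Exponential-mixture dwell parameters
#'
#' Container for the parameters of the double-exponential dwell density
#' `f(t) = p+ k+ exp(-k+ t) + p- k- exp(-k- t)` with `p+ + p- = 1`.
#'
#' @param k_plus Fast rate (1/s).
#' @param k_minus Slow rate (1/s).
#' @param p_minus Weight of the slow exponential, in `[0, 1]`.
#' @return An object of class `exp_mix_params`.
#' @export
exp_mix_params <- function(k_plus, k_minus, p_minus) {
  if (!is.finite(k_plus) || !is.finite(k_minus) || k_plus <= 0 || k_minus <= 0)
    stop("'k_plus' and 'k_minus' must be positive")
  if (!is.finite(p_minus) || p_minus < 0 || p_minus > 1)
    stop("'p_minus' must lie in [0, 1]")
  structure(list(k_plus = k_plus, k_minus = k_minus,
                 p_minus = p_minus, p_plus = 1 - p_minus),
            class = "exp_mix_params")
}

#' @export
print.exp_mix_params <- function(x, ...) {
  cat(sprintf(
    "Exponential mixture: k+ = %.4g 1/s, k- = %.4g 1/s, p- = %.4g\n",
    x$k_plus, x$k_minus, x$p_minus))
  invisible(x)
}

# Raw conversion on plain numbers; shared by fit_to_micro and the
# finite-difference error propagation (which must be free to step slightly
# outside the validated parameter domain).
expmix_to_micro_raw <- function(k_plus, k_minus, p_minus) {
  p_plus <- 1 - p_minus
  k5 <- p_plus * k_plus + p_minus * k_minus
  if (k5 <= 0) stop("degenerate mixture: k5 = p+ k+ + p- k- must be > 0")
  k3 <- p_plus * p_minus * (k_plus - k_minus)^2 / k5
  k_neg3 <- k_plus * k_minus / k5
  c(k5 = k5, k3 = k3, k_neg3 = k_neg3)
}

#' Convert exponential-mixture fit parameters to microscopic rate constants
#'
#' Exact conversion relations for the accepted dissociation model (entry in
#' RP_I, reversible excursion to RP_O, dissociation only from RP_I):
#' `k5 = p+ k+ + p- k-`, `k3 = p+ p- (k+ - k-)^2 / k5`,
#' `k-3 = k+ k- / k5`. All three are positive for any valid mixture.
#'
#' @param fit An [exp_mix_params()] object.
#' @return An object of class `derived_rates` with fields `k5`, `k3`,
#'   `k_neg3` and (NA until [propagate_errors()] fills them) their one-SD
#'   errors.
#' @export
fit_to_micro <- function(fit) {
  stopifnot(inherits(fit, "exp_mix_params"))
  m <- expmix_to_micro_raw(fit$k_plus, fit$k_minus, fit$p_minus)
  structure(list(k5 = m[["k5"]], k3 = m[["k3"]], k_neg3 = m[["k_neg3"]],
                 sd_k5 = NA_real_, sd_k3 = NA_real_, sd_k_neg3 = NA_real_),
            class = "derived_rates")
}

#' @export
print.derived_rates <- function(x, ...) {
  cat(sprintf("Microscopic rates (1/s): k5 = %.4g (sd %.3g), k3 = %.4g (sd %.3g), k-3 = %.4g (sd %.3g)\n",
              x$k5, x$sd_k5, x$k3, x$sd_k3, x$k_neg3, x$sd_k_neg3))
  invisible(x)
}

#' Convert microscopic rate constants to exponential-mixture parameters
#'
#' Inverse of [fit_to_micro()]: the mixture rates are the negated
#' eigenvalues of the accepted-model generator
#' `Q = [[-(k5 + k3), k3], [k-3, -k-3]]` and the weight solves
#' `k5 = p+ k+ + p- k-`. With `k3 = 0` the dwell is a single exponential at
#' `k5` (no RP_O entry) and `p+ = 1`, `k- = k-3` by convention. A repeated
#' eigenvalue also collapses to the single-exponential limit.
#'
#' @param k5,k3,k_neg3 Strictly positive rates (1/s); `k3 = 0` is allowed.
#' @return An [exp_mix_params()] object.
#' @export
micro_to_fit <- function(k5, k3, k_neg3) {
  if (k5 <= 0 || k_neg3 <= 0 || k3 < 0)
    stop("'k5' and 'k_neg3' must be > 0 and 'k3' >= 0")
  if (k3 == 0)
    return(exp_mix_params(k_plus = k5, k_minus = k_neg3, p_minus = 0))
  s <- k5 + k3 + k_neg3
  disc <- s^2 - 4 * k5 * k_neg3
  if (disc <= 0) {  # repeated eigenvalue: measure-zero Erlang boundary
    k <- s / 2
    return(exp_mix_params(k_plus = k, k_minus = k, p_minus = 0))
  }
  k_plus <- (s + sqrt(disc)) / 2
  k_minus <- (s - sqrt(disc)) / 2
  # direct form (not 1 - p_plus): avoids cancellation when p_minus is tiny
  p_minus <- (k_plus - k5) / (k_plus - k_minus)
  exp_mix_params(k_plus = k_plus, k_minus = k_minus,
                 p_minus = min(max(p_minus, 0), 1))
}

#' Propagate fit-parameter errors to the microscopic rate constants
#'
#' First-order (delta-method) propagation
#' `sd(k_mic_j) = sqrt(sum_i (d k_mic_j / d x_i * sd_i)^2)` over
#' `x = (k+, k-, p-)`, with the partial derivatives evaluated by central
#' finite differences (relative step 1e-6).
#'
#' @param fit An [exp_mix_params()] object.
#' @param sds Named or positional numeric vector of one-SD errors for
#'   `k_plus`, `k_minus`, `p_minus` (all >= 0).
#' @return A `derived_rates` object with the `sd_*` fields filled in.
#' @export
propagate_errors <- function(fit, sds) {
  stopifnot(inherits(fit, "exp_mix_params"))
  sds <- unlist(sds)
  if (!is.null(names(sds)))
    sds <- sds[c("k_plus", "k_minus", "p_minus")]
  if (length(sds) != 3L || any(!is.finite(sds)) || any(sds < 0))
    stop("'sds' must give three non-negative errors for (k+, k-, p-)")
  x <- c(fit$k_plus, fit$k_minus, fit$p_minus)
  J <- matrix(0, 3, 3)  # rows: k5, k3, k_neg3; cols: k+, k-, p-
  for (i in 1:3) {
    h <- 1e-6 * max(abs(x[i]), 1e-6)
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    fp <- expmix_to_micro_raw(xp[1], xp[2], xp[3])
    fm <- expmix_to_micro_raw(xm[1], xm[2], xm[3])
    J[, i] <- (fp - fm) / (2 * h)
  }
  out <- fit_to_micro(fit)
  sd3 <- sqrt(rowSums(sweep(J, 2, sds, `*`)^2))
  out$sd_k5 <- sd3[1]; out$sd_k3 <- sd3[2]; out$sd_k_neg3 <- sd3[3]
  out
}
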