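# Synthetic-data generator: exact stochastic simulation of the promoter
# state chain, rendered as a noisy two-level magnetic-tweezers extension
# trace with ground-truth dwell records.

#' Configuration of a synthetic extension trace
#'
#' @param rates A [rate_constants()] object driving the state chain.
#' @param z_CS Closed-state extension level (nm).
#' @param jump_pos,jump_neg OS -> CS extension jump for positively /
#'   negatively supercoiled tethers (nm).
#' @param supercoiling_sign `"+"` or `"-"`; selects which jump applies.
#' @param noise_sd Per-sample additive Gaussian noise on the raw signal (nm).
#' @param f_s Raw sampling frequency (Hz).
#' @param duration Trace length (s).
#' @param decimate Block-averaging factor applied after noise (integer >= 1).
#' @param drift_rate Linear drift added to the raw signal (nm/s).
#' @param seed Optional integer seed recorded with the trace.
#' @param label Free-text condition labels (named list, e.g. salt,
#'   temperature) echoed into trace metadata.
#' @return An object of class `trace_config`.
#' @export
trace_config <- function(rates, z_CS = 900, jump_pos = 73, jump_neg = 42,
                         supercoiling_sign = c("+", "-"), noise_sd = 25,
                         f_s = 58, duration = 1500, decimate = 10,
                         drift_rate = 0, seed = NULL, label = list()) {
  supercoiling_sign <- match.arg(supercoiling_sign)
  stopifnot(f_s > 0, duration > 0, noise_sd >= 0,
            decimate >= 1, decimate == round(decimate))
  structure(list(rates = as_rate_constants(rates), z_CS = z_CS,
                 jump_pos = jump_pos, jump_neg = jump_neg,
                 supercoiling_sign = supercoiling_sign,
                 noise_sd = noise_sd, f_s = f_s, duration = duration,
                 decimate = as.integer(decimate), drift_rate = drift_rate,
                 seed = seed, label = label),
            class = "trace_config")
}

promoter_states <- c("R+P", "RP_C", "RP_I", "RP_O")

# Transition table of the full binding/opening scheme. Row i: exits from
# state i as (rate, destination) pairs; dissociation returns to R+P.
scheme_transitions <- function(r) {
  list(
    `R+P` = list(rate = c(r$k1 * r$R_conc), to = c(2L)),
    RP_C  = list(rate = c(r$k_neg1, r$k2), to = c(1L, 3L)),
    RP_I  = list(rate = c(r$k_neg2, r$k3, r$k5), to = c(2L, 4L, 1L)),
    RP_O  = list(rate = c(r$k_neg3, r$k4), to = c(3L, 1L))
  )
}

#' Simulate a promoter state trajectory (exact Gillespie)
#'
#' Continuous-time Markov chain over R+P, RP_C, RP_I, RP_O started in R+P:
#' exponential waiting time at the total exit rate of the current state,
#' branch chosen proportionally to the competing rates. Binding is
#' pseudo-first-order at `k1 * R_conc`; dissociation (from RP_I via `k5`,
#' RP_O via `k4`, RP_C via `k_neg1`) returns the promoter to R+P.
#'
#' @param rates A [rate_constants()] object.
#' @param duration Simulated time (s).
#' @param seed Optional integer seed (bit-reproducible trajectories).
#' @return An object of class `state_trajectory`: list with `event_times`
#'   (strictly increasing, starting at 0), `states` (state after each
#'   event; first entry is `"R+P"`) and `duration`.
#' @export
simulate_trajectory <- function(rates, duration, seed = NULL) {
  stopifnot(duration > 0)
  r <- as_rate_constants(rates)
  if (!is.null(seed)) set.seed(seed)
  trans <- scheme_transitions(r)
  tot <- vapply(trans, function(x) sum(x$rate), numeric(1))

  nbuf <- 1024L
  times <- numeric(nbuf); states <- integer(nbuf)
  times[1L] <- 0; states[1L] <- 1L
  n <- 1L; t_now <- 0; s_now <- 1L
  while (TRUE) {
    rate_out <- tot[[s_now]]
    if (rate_out <= 0) {
      # absorbing configuration: legal only if we can sit here to the end
      if (all(tot <= 0))
        stop("all exit rates are zero: absorbing configuration")
      break
    }
    t_now <- t_now + stats::rexp(1L, rate_out)
    if (t_now >= duration) break
    tr <- trans[[s_now]]
    s_now <- if (length(tr$rate) == 1L) tr$to else
      tr$to[sample.int(length(tr$rate), 1L, prob = tr$rate)]
    n <- n + 1L
    if (n > nbuf) {
      nbuf <- nbuf * 2L
      length(times) <- nbuf; length(states) <- nbuf
    }
    times[n] <- t_now; states[n] <- s_now
  }
  structure(list(event_times = times[seq_len(n)],
                 states = promoter_states[states[seq_len(n)]],
                 duration = duration),
            class = "state_trajectory")
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf("Promoter state trajectory: %d events over %.4g s; final state %s\n",
              length(x$event_times) - 1L, x$duration,
              x$states[length(x$states)]))
  invisible(x)
}

#' Render a state trajectory as a noisy extension trace
#'
#' Maps the lumped closed state (R+P, RP_C) to the `z_CS` extension level
#' and the lumped open state (RP_I, RP_O) to `z_CS - jump` (the jump chosen
#' by the supercoiling sign; RP_I and RP_O render at the same level, since
#' a bubble-size difference between them is not observable). Each raw
#' sample takes the state occupied at its timestamp; linear drift and
#' i.i.d. Gaussian noise are added and the signal is then block-averaged by
#' the decimation factor.
#'
#' @param traj A [simulate_trajectory()] result.
#' @param config A [trace_config()]; its `duration`/`rates` should match the
#'   trajectory's.
#' @param seed Optional seed for the noise (defaults to `config$seed`).
#' @return An object of class `extension_trace`: list with `t` (s), `z`
#'   (nm) and `meta` (the config echo).
#' @export
render_trace <- function(traj, config, seed = config$seed) {
  stopifnot(inherits(traj, "state_trajectory"),
            inherits(config, "trace_config"))
  if (!is.null(seed)) set.seed(seed)
  jump <- if (config$supercoiling_sign == "+") config$jump_pos else
    config$jump_neg
  t_raw <- seq(0, traj$duration - 1 / config$f_s, by = 1 / config$f_s)
  idx <- findInterval(t_raw, traj$event_times)
  open <- traj$states[idx] %in% c("RP_I", "RP_O")
  z <- ifelse(open, config$z_CS - jump, config$z_CS)
  z <- z + config$drift_rate * t_raw
  if (config$noise_sd > 0)
    z <- z + stats::rnorm(length(z), sd = config$noise_sd)
  d <- config$decimate
  if (d > 1L) {
    nb <- floor(length(z) / d)
    z <- colMeans(matrix(z[seq_len(nb * d)], nrow = d))
    t_out <- colMeans(matrix(t_raw[seq_len(nb * d)], nrow = d))
  } else t_out <- t_raw
  structure(list(t = t_out, z = z, meta = config),
            class = "extension_trace")
}

#' @export
print.extension_trace <- function(x, ...) {
  cat(sprintf("Extension trace: %d samples, %.4g s at %.3g Hz effective\n",
              length(x$z), x$meta$duration,
              x$meta$f_s / x$meta$decimate))
  invisible(x)
}

#' Ground-truth lumped dwells of a state trajectory
#'
#' Lumps R+P and RP_C into the closed state (CS) and RP_I, RP_O into the
#' open state (OS) and returns the alternating dwell durations. The first
#' and last dwell are flagged censored (their start/end is not observed).
#'
#' @param traj A [simulate_trajectory()] result.
#' @return A `dwell_set` data frame with columns `label` ("OS"/"CS"),
#'   `start_s`, `duration_s`, `censored`; attribute `t_min` is 0.
#' @export
true_dwells <- function(traj) {
  stopifnot(inherits(traj, "state_trajectory"))
  open <- traj$states %in% c("RP_I", "RP_O")
  brk <- c(TRUE, diff(open) != 0)          # event starts a new lumped dwell
  starts <- traj$event_times[brk]
  lab <- ifelse(open[brk], "OS", "CS")
  ends <- c(starts[-1L], traj$duration)
  dw <- data.frame(label = lab, start_s = starts,
                   duration_s = ends - starts,
                   censored = FALSE, stringsAsFactors = FALSE)
  dw$censored[c(1L, nrow(dw))] <- TRUE
  as_dwell_set(dw, t_min = 0)
}

as_dwell_set <- function(df, t_min = 0) {
  attr(df, "t_min") <- t_min
  class(df) <- c("dwell_set", "data.frame")
  df
}

#' Durations of selected dwells
#'
#' Convenience accessor: uncensored dwell durations of one label.
#'
#' @param dwells A `dwell_set` data frame.
#' @param label `"OS"`, `"CS"` or `NULL` for both.
#' @param keep_censored Include censored boundary dwells (default FALSE;
#'   censored dwells are excluded from all fits).
#' @export
dwell_durations <- function(dwells, label = NULL, keep_censored = FALSE) {
  stopifnot(inherits(dwells, "dwell_set"))
  keep <- if (keep_censored) rep(TRUE, nrow(dwells)) else !dwells$censored
  if (!is.null(label)) keep <- keep & dwells$label == label
  dwells$duration_s[keep]
}

#' Sample open-state first-passage dwells (vectorized Gillespie)
#'
#' Exact stochastic simulation of the accepted dissociation model restricted
#' to the open-state subchain: start in RP_I, hop to RP_O at `k3` (returning
#' at `k_neg3`) and absorb (dissociate) from RP_I at `k5`. Equivalent to,
#' and much faster than, extracting OS dwells from full trajectories.
#'
#' @param n Number of dwells.
#' @param k5,k3,k_neg3 Positive rates (1/s).
#' @param seed Optional seed.
#' @return Numeric vector of `n` dwell durations (s).
#' @export
simulate_os_dwells <- function(n, k5, k3, k_neg3, seed = NULL) {
  stopifnot(n >= 1, k5 > 0, k3 >= 0, k_neg3 > 0)
  if (!is.null(seed)) set.seed(seed)
  tot <- numeric(n)
  active <- seq_len(n)                      # dwells currently in RP_I
  exit_I <- k5 + k3
  while (length(active)) {
    tot[active] <- tot[active] + stats::rexp(length(active), exit_I)
    to_O <- stats::runif(length(active)) < k3 / exit_I
    active <- active[to_O]
    if (length(active))
      tot[active] <- tot[active] + stats::rexp(length(active), k_neg3)
  }
  tot
}
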