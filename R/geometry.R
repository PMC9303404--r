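# Supercoiling arithmetic: transcription-bubble size and bent-DNA length
# from the OS/CS extension jumps, and twist shifts from rotation-extension
# curves.
#
# On a plectonemic tether, unwinding n base pairs removes n/pitch turns of
# twist, which the conserved linking number converts into writhe: the
# extension changes by (n/pitch) * dz_per_turn, with the same sign for
# positive and negative supercoiling. Wrapping/bending of a length L_bend
# of DNA shortens the tether by L_bend irrespective of the supercoiling
# sign. Hence J_pos = n*dz/pitch + L and J_neg = n*dz/pitch - L, which
# inverts to the formulas below.

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Transcription-bubble size and bent-DNA length from extension jumps
#'
#' `n = pitch * (J_pos + J_neg) / (2 * dz_per_turn)` base pairs unwound and
#' `L_bend = (J_pos - J_neg) / 2` nanometres of DNA bent onto the enzyme,
#' from the OS-CS extension jump magnitudes measured on positively and
#' negatively supercoiled tethers.
#'
#' @param J_pos,J_neg Jump magnitudes (nm), `J_pos >= J_neg >= 0`.
#' @param dz_per_turn Extension loss per added turn in the plectonemic
#'   regime (nm/turn); ~60 nm in reaction buffer.
#' @param pitch DNA helical pitch (bp/turn), ~10.5.
#' @return Object of class `geometry_result`: `n_bp` and `L_bend` rounded
#'   to the nearest bp / nm (half away from zero), plus the unrounded
#'   `raw_n`, `raw_L`.
#' @export
bubble_and_bend <- function(J_pos, J_neg, dz_per_turn = 60, pitch = 10.5) {
  stopifnot(dz_per_turn > 0, pitch > 0)
  if (J_neg < 0 || J_pos < J_neg)
    stop("inconsistent jumps: need J_pos >= J_neg >= 0")
  raw_n <- pitch * (J_pos + J_neg) / (2 * dz_per_turn)
  raw_L <- (J_pos - J_neg) / 2
  structure(list(n_bp = round_half_away(raw_n),
                 L_bend = round_half_away(raw_L),
                 raw_n = raw_n, raw_L = raw_L,
                 dz_per_turn = dz_per_turn, pitch = pitch),
            class = "geometry_result")
}

#' @export
print.geometry_result <- function(x, ...) {
  cat(sprintf(
    "Transcription bubble: %g bp (raw %.4g); bent DNA length: %g nm (raw %.4g)\n",
    x$n_bp, x$raw_n, x$L_bend, x$raw_L))
  invisible(x)
}

#' Expected extension jumps for a given bubble size and bent length
#'
#' Inverse of [bubble_and_bend()]:
#' `J_pos = n * dz_per_turn / pitch + L_bend`,
#' `J_neg = n * dz_per_turn / pitch - L_bend`. A negative predicted
#' `J_neg` is clipped to zero and flagged.
#'
#' @param n_bp Unwound base pairs (>= 0).
#' @param L_bend Bent DNA length (nm, >= 0).
#' @inheritParams bubble_and_bend
#' @return Named list `J_pos`, `J_neg` (nm) and logical `clipped`.
#' @export
expected_jump <- function(n_bp, L_bend, dz_per_turn = 60, pitch = 10.5) {
  stopifnot(n_bp >= 0, L_bend >= 0, dz_per_turn > 0, pitch > 0)
  base <- n_bp * dz_per_turn / pitch
  J_neg <- base - L_bend
  clipped <- J_neg < 0
  list(J_pos = base + L_bend, J_neg = max(J_neg, 0), clipped = clipped)
}

parabola_apex <- function(turns, ext, frac = 0.9) {
  keep <- ext >= frac * max(ext)
  if (sum(keep) < 3) stop("too few points near the apex for a parabola fit")
  x <- turns[keep]; y <- ext[keep]
  cf <- stats::coef(stats::lm(y ~ x + I(x^2)))
  if (!is.finite(cf[3]) || cf[3] >= 0)
    stop("apex not locally parabolic (curve may not cover its maximum)")
  apex <- -cf[2] / (2 * cf[3])
  if (apex <= min(turns) || apex >= max(turns))
    stop("apex lies at the boundary of the scanned turn range")
  unname(apex)
}

#' Twist shift between two rotation-extension curves
#'
#' Locates the apex (maximum-extension turn) of each curve by a parabola
#' fit to the points within `frac` of the maximal extension; the zero of
#' twist is defined by the reference-buffer apex, and the buffer-induced
#' twist change is the apex displacement expressed per kilobase.
#'
#' @param curve_ref,curve_test Data frames (or lists) with columns/fields
#'   `turns` and `ext` (nm), each covering its apex.
#' @param length_kb Tether length (kb).
#' @param frac Fraction of the maximal extension defining the apex window.
#' @return Object of class `twist_shift`: `delta_turns`
#'   (apex_test - apex_ref) and `deg_per_kb = 360 * delta_turns /
#'   length_kb`.
#' @export
twist_shift <- function(curve_ref, curve_test, length_kb, frac = 0.9) {
  stopifnot(length_kb > 0)
  a_ref <- parabola_apex(curve_ref$turns, curve_ref$ext, frac)
  a_test <- parabola_apex(curve_test$turns, curve_test$ext, frac)
  dt <- a_test - a_ref
  structure(list(delta_turns = dt, deg_per_kb = 360 * dt / length_kb,
                 apex_ref = a_ref, apex_test = a_test,
                 length_kb = length_kb),
            class = "twist_shift")
}

#' @export
print.twist_shift <- function(x, ...) {
  cat(sprintf("Twist shift: %+.3g turns over %.3g kb = %+.4g deg/kb\n",
              x$delta_turns, x$length_kb, x$deg_per_kb))
  invisible(x)
}
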