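# Change-point segmentation of two-level extension traces into OS/CS
# dwells, plus trace-quality diagnostics (Allan deviation, correlation
# time).

# L1 cost of a segment: sum of absolute deviations from the segment median.
# Any point between the two central order statistics minimizes the L1 sum
# equally, so a single partial-sort order statistic suffices and is exact.
cost_l1 <- function(v) {
  n <- length(v)
  if (n < 2L) return(0)
  h <- (n + 1L) %/% 2L
  sum(abs(v - sort.int(v, partial = h)[h]))
}

# Robust per-sample noise scale from first differences (a level step
# contributes a single outlier, which the MAD ignores). Falls back to the
# classical SD for series whose differences are mostly exactly zero
# (noiseless fixtures), and to 1 for constant series.
noise_scale <- function(z) {
  d <- diff(z)
  s <- stats::mad(d, center = 0) / sqrt(2)
  if (s <= 0) s <- stats::sd(d) / sqrt(2)
  if (!is.finite(s) || s <= 0) s <- 1
  s
}

#' Bottom-up L1 change-point detection
#'
#' Segments an extension series by bottom-up merging: the series is first
#' cut into contiguous blocks of `min_size` samples; the adjacent pair of
#' segments whose merge increases the total cost the least is merged
#' repeatedly, while that cost increase stays below `penalty`. The cost of
#' a segment is the sum of absolute deviations from its median, computed on
#' the series standardized by a robust noise scale so that `penalty` is
#' expressed in units of the per-sample noise.
#'
#' @param z Numeric extension series (nm).
#' @param penalty Positive merge penalty (noise units). Larger penalties
#'   stop merging earlier in the gain ladder, i.e. give fewer breakpoints
#'   only through the complementary direction: merging continues while the
#'   cheapest merge gain is below `penalty`, so the number of detected
#'   transitions is non-increasing in `penalty`.
#' @param min_size Initial block size in samples (>= 1).
#' @param scale Noise scale used for standardization; default estimated
#'   from the median absolute first difference.
#' @return Integer vector of internal breakpoints: each is the index of the
#'   last sample of a segment (the final segment end `length(z)` is not
#'   reported). Empty for a homogeneous series.
#' @export
detect_changepoints <- function(z, penalty = 1, min_size = 2, scale = NULL) {
  if (length(z) == 0L) stop("empty series")
  stopifnot(penalty > 0, min_size >= 1)
  if (length(z) < 2L * min_size) return(integer(0))
  if (is.null(scale)) scale <- noise_scale(z)
  x <- z / scale

  n <- length(x)
  n0 <- floor(n / min_size)
  ends <- as.integer(seq_len(n0) * min_size)
  ends[n0] <- n                         # last block absorbs the remainder
  starts <- c(1L, ends[-n0] + 1L)

  # doubly linked list over segments
  nxt <- c(seq_len(n0)[-1L], NA_integer_)
  prv <- c(NA_integer_, seq_len(n0)[-n0])
  cost <- vapply(seq_len(n0), function(i) cost_l1(x[starts[i]:ends[i]]),
                 numeric(1))
  # gain[i]: cost increase of merging segment i with its successor
  gain <- rep(Inf, n0)
  for (i in seq_len(n0 - 1L))
    gain[i] <- cost_l1(x[starts[i]:ends[i + 1L]]) - cost[i] - cost[i + 1L]

  while (TRUE) {
    i <- which.min(gain)
    if (gain[i] >= penalty) break
    j <- nxt[i]
    ends[i] <- ends[j]
    cost[i] <- cost[i] + cost[j] + gain[i]
    nxt[i] <- nxt[j]
    if (!is.na(nxt[j])) prv[nxt[j]] <- i
    gain[j] <- Inf
    p <- prv[i]
    if (!is.na(p))
      gain[p] <- cost_l1(x[starts[p]:ends[i]]) - cost[p] - cost[i]
    k <- nxt[i]
    gain[i] <- if (is.na(k)) Inf else
      cost_l1(x[starts[i]:ends[k]]) - cost[i] - cost[k]
  }
  # collect surviving segments by walking the list
  out <- integer(0)
  i <- 1L
  while (!is.na(i)) { out <- c(out, ends[i]); i <- nxt[i] }
  out[-length(out)]
}

# 1-D 2-means on segment medians, weighted by segment length.
two_means_1d <- function(v, w, iter = 50L) {
  c1 <- min(v); c2 <- max(v)
  assign <- NULL
  for (it in seq_len(iter)) {
    newassign <- abs(v - c1) <= abs(v - c2)  # TRUE -> lower cluster
    if (identical(newassign, assign)) break
    assign <- newassign
    if (any(assign)) c1 <- sum(v[assign] * w[assign]) / sum(w[assign])
    if (any(!assign)) c2 <- sum(v[!assign] * w[!assign]) / sum(w[!assign])
  }
  list(lower = assign, centers = c(c1, c2))
}

#' Label segments as open or closed state
#'
#' Classifies segment medians into two levels by one-dimensional 2-means
#' (length-weighted). The lower-extension cluster is the open state:
#' promoter opening shortens the tether. If the two cluster centers are
#' closer than `min_separation` noise scales, the trace is taken to have no
#' OS visits and everything is labelled CS. Adjacent same-label segments
#' are merged.
#'
#' @param z Extension series used for the detection.
#' @param breakpoints Integer breakpoints from [detect_changepoints()].
#' @param scale Noise scale (default re-estimated from `z`).
#' @param min_separation Minimum center separation, in noise units, to
#'   accept a two-level interpretation.
#' @return An object of class `segmentation`: list with `breakpoints`
#'   (after same-label merging), `labels`, `levels` (segment medians, nm)
#'   and `n` (series length).
#' @export
label_segments <- function(z, breakpoints, scale = NULL,
                           min_separation = 4) {
  n <- length(z)
  if (n == 0L) stop("empty series")
  if (is.null(scale)) scale <- noise_scale(z)
  ends <- c(breakpoints, n)
  starts <- c(1L, breakpoints + 1L)
  med <- mapply(function(s, e) stats::median(z[s:e]), starts, ends)
  len <- ends - starts + 1L

  if (length(med) == 1L) {
    lab <- "CS"
  } else {
    km <- two_means_1d(med, len)
    if (diff(km$centers) < min_separation * scale) {
      lab <- rep("CS", length(med))
    } else {
      lab <- ifelse(km$lower, "OS", "CS")
    }
  }
  # merge adjacent same-label segments
  keep <- c(TRUE, lab[-1L] != lab[-length(lab)])
  g <- cumsum(keep)
  m_ends <- as.integer(tapply(ends, g, max))
  m_lab <- lab[keep]
  m_lev <- mapply(function(s, e) stats::median(z[s:e]),
                  c(1L, m_ends[-length(m_ends)] + 1L), m_ends)
  structure(list(breakpoints = m_ends[-length(m_ends)],
                 labels = m_lab, levels = as.numeric(m_lev), n = n),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("Segmentation: %d segments (%d OS, %d CS) over %d samples\n",
              length(x$labels), sum(x$labels == "OS"),
              sum(x$labels == "CS"), x$n))
  invisible(x)
}

#' Extract labelled dwell times from a segmentation
#'
#' Converts segment lengths to durations at the effective sampling
#' frequency. The first and last dwell are flagged censored (their
#' boundaries are set by the recording, not by transitions) and are
#' excluded from fitting. Dwells shorter than `t_min` -- below the assay's
#' spatiotemporal resolution -- are discarded and their flanking same-label
#' neighbours merged (absorbing the discarded time), iterating until every
#' retained dwell is at least `t_min` long.
#'
#' @param seg A [label_segments()] result.
#' @param f_s_eff Effective sampling frequency of the segmented series (Hz).
#' @param t_min Minimum dwell duration (s); default 0.09 s, i.e. twice the
#'   typical 45 ms correlation time of the assay.
#' @return A `dwell_set` data frame (`label`, `duration_s`, `censored`)
#'   with attribute `t_min`.
#' @export
extract_dwells <- function(seg, f_s_eff, t_min = 0.09) {
  stopifnot(inherits(seg, "segmentation"), f_s_eff > 0, t_min >= 0)
  ends <- c(seg$breakpoints, seg$n)
  len <- diff(c(0L, ends))
  dur <- len / f_s_eff
  lab <- seg$labels
  cen <- rep(FALSE, length(dur))
  cen[c(1L, length(dur))] <- TRUE

  repeat {
    short <- which(dur < t_min)
    if (!length(short)) break
    i <- short[which.min(dur[short])]
    if (length(dur) == 1L) break
    if (i == 1L) {                       # fold into the right neighbour
      dur[2L] <- dur[2L] + dur[1L]
      cen[2L] <- TRUE
      dur <- dur[-1L]; lab <- lab[-1L]; cen <- cen[-1L]
    } else if (i == length(dur)) {
      dur[i - 1L] <- dur[i - 1L] + dur[i]
      cen[i - 1L] <- TRUE
      dur <- dur[-i]; lab <- lab[-i]; cen <- cen[-i]
    } else {                             # merge the two flanking dwells
      dur[i - 1L] <- dur[i - 1L] + dur[i] + dur[i + 1L]
      cen[i - 1L] <- cen[i - 1L] || cen[i + 1L]
      dur <- dur[-c(i, i + 1L)]; lab <- lab[-c(i, i + 1L)]
      cen <- cen[-c(i, i + 1L)]
    }
  }
  as_dwell_set(data.frame(label = lab, duration_s = dur, censored = cen,
                          stringsAsFactors = FALSE), t_min = t_min)
}

#' Overlapping Allan deviation of an extension signal
#'
#' Two-sample deviation of consecutive block means,
#' `sigma(tau) = sqrt(mean((ybar_{i+m} - ybar_i)^2) / 2)` with fully
#' overlapping blocks of `m` samples, at octave-spaced averaging times
#' `tau = m / f_s`. White noise of SD `s0` gives
#' `sigma(tau) = s0 / sqrt(m)`, i.e. slope -1/2 on a log-log plot; a
#' flattening or minimum reveals the correlation time and drift of the
#' bead-tracking signal.
#'
#' @param z Numeric signal.
#' @param f_s Sampling frequency (Hz).
#' @return A data frame with columns `tau` (s) and `adev` (signal units).
#' @export
allan_deviation <- function(z, f_s) {
  n <- length(z)
  stopifnot(n >= 4L, f_s > 0)
  ms <- 2^(0:floor(log2(n / 2)))
  ms <- ms[2 * ms <= n]
  cs <- c(0, cumsum(z))
  adev <- vapply(ms, function(m) {
    yb <- (cs[(m + 1):(n + 1)] - cs[1:(n - m + 1)]) / m  # overlapping means
    d <- yb[(m + 1):length(yb)] - yb[1:(length(yb) - m)]
    sqrt(mean(d^2) / 2)
  }, numeric(1))
  data.frame(tau = ms / f_s, adev = adev)
}

#' Correlation time of a signal from its autocorrelation
#'
#' Estimates the correlation time as the lag at which the empirical
#' autocorrelation first falls below 1/e, with linear interpolation
#' between lags.
#'
#' @param z Numeric signal.
#' @param f_s Sampling frequency (Hz).
#' @param max_lag Largest lag examined (samples).
#' @return Correlation time (s); `NA` if the autocorrelation never drops
#'   below 1/e within `max_lag`.
#' @export
correlation_time <- function(z, f_s, max_lag = min(length(z) - 1L, 2000L)) {
  stopifnot(length(z) >= 4L, f_s > 0)
  ac <- stats::acf(z, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  thr <- exp(-1)
  below <- which(ac < thr)
  if (!length(below)) return(NA_real_)
  i <- below[1L]                        # acf index 1 is lag 0
  if (i == 1L) return(0)
  lag_hi <- i - 1L; lag_lo <- i - 2L
  frac <- (ac[i - 1L] - thr) / (ac[i - 1L] - ac[i])
  (lag_lo + frac) / f_s
}

#' Remove linear drift from an extension trace
#'
#' Fits a Tukey resistant line to (t, z) and subtracts it when the fitted
#' slope magnitude exceeds `threshold`; smaller slopes are left untouched
#' so that genuine level structure is not distorted.
#'
#' @param t,z Time (s) and extension (nm).
#' @param threshold Slope magnitude (nm/s) above which drift is removed.
#' @return The detrended `z` (attribute `slope` reports the fitted slope).
#' @export
detrend_extension <- function(t, z, threshold = 0.5) {
  fit <- stats::line(t, z)
  sl <- stats::coef(fit)[2]
  if (is.finite(sl) && abs(sl) > threshold)
    z <- z - sl * (t - mean(t))
  attr(z, "slope") <- unname(sl)
  z
}
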