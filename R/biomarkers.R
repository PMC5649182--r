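#' Action potential duration at 90% repolarization
#'
#' APD90 is measured from the instant of maximum upstroke velocity to the
#' downward crossing of `V90 = Vpeak - 0.9 * (Vpeak - Vrest)`, with linear
#' interpolation between samples. `Vrest` is the pre-stimulus diastolic
#' potential.
#'
#' @param trace a `cell_trace` or a list with `time` and `V`.
#' @param window optional `c(t0, t1)` limiting the beat analyzed; defaults
#'   to the whole trace.
#' @param stim_time stimulus onset (ms); defaults to the trace's stimulus
#'   start if present, otherwise the time of maximum dV/dt minus 2 ms.
#' @return APD90 in ms, or `NA` with attribute `unmeasurable` if the AP
#'   does not repolarize inside the window.
#' @export
measure_apd90 <- function(trace, window = NULL, stim_time = NULL) {
  tt <- trace$time; V <- trace$V
  if (!is.null(window)) {
    keep <- tt >= window[1] & tt <= window[2]
    tt <- tt[keep]; V <- V[keep]
  }
  if (length(tt) < 5) return(structure(NA_real_, unmeasurable = TRUE))
  if (is.null(stim_time) && !is.null(trace$stimulus))
    stim_time <- trace$stimulus$start
  dv <- diff(V) / diff(tt)
  iup <- which.max(dv)
  if (dv[iup] <= 1) return(structure(NA_real_, unmeasurable = TRUE))
  t_up <- tt[iup]
  vrest <- if (!is.null(stim_time) && any(tt < stim_time)) {
    V[max(which(tt < stim_time))]
  } else V[max(1, iup - ceiling(2 / max(diff(tt))))]
  vpeak <- max(V[tt >= t_up])
  v90 <- vpeak - 0.9 * (vpeak - vrest)
  after <- which(tt > t_up)
  ipk <- after[which.max(V[after])]
  below <- which(tt > tt[ipk] & V < v90)
  if (!length(below)) return(structure(NA_real_, unmeasurable = TRUE))
  i2 <- below[1]; i1 <- i2 - 1
  tcross <- tt[i1] + (v90 - V[i1]) * (tt[i2] - tt[i1]) / (V[i2] - V[i1])
  tcross - t_up
}

#' Maximum upstroke velocity
#'
#' Peak of the finite-difference dV/dt during the rising phase with
#' `V > -60 mV`, which excludes the stimulus artifact.
#'
#' @inheritParams measure_apd90
#' @return MUV in mV/ms, or `NA` (unmeasurable) when there is no upstroke.
#' @export
measure_muv <- function(trace, window = NULL) {
  tt <- trace$time; V <- trace$V
  if (!is.null(window)) {
    keep <- tt >= window[1] & tt <= window[2]
    tt <- tt[keep]; V <- V[keep]
  }
  n <- length(V)
  if (n < 3) return(structure(NA_real_, unmeasurable = TRUE))
  dv <- (V[3:n] - V[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
  mid <- V[2:(n - 1)]
  ok <- mid > -60 & dv > 0
  if (!any(ok)) return(structure(NA_real_, unmeasurable = TRUE))
  max(dv[ok])
}

#' Resting and peak potential of a beat
#' @inheritParams measure_apd90
#' @export
measure_v_extremes <- function(trace) {
  c(rest = min(trace$V), peak = max(trace$V))
}

#' Detect early afterdepolarizations
#'
#' An EAD is flagged when, after the plateau onset and before 90%
#' repolarization, the membrane potential shows a positive excursion of at
#' least `min_rise` mV (a local minimum followed by a rise during the
#' repolarization phase).
#'
#' @inheritParams measure_apd90
#' @param min_rise minimum depolarizing excursion (mV).
#' @export
detect_ead <- function(trace, min_rise = 1, window = NULL) {
  tt <- trace$time; V <- trace$V
  if (!is.null(window)) {
    keep <- tt >= window[1] & tt <= window[2]
    tt <- tt[keep]; V <- V[keep]
  }
  dv <- diff(V) / diff(tt)
  iup <- which.max(dv)
  if (!length(iup) || dv[iup] <= 1) return(FALSE)
  vrest <- V[1]
  vpeak <- max(V)
  v90 <- vpeak - 0.9 * (vpeak - vrest)
  ipk <- which.max(V)
  # repolarization phase: from 20 ms after the peak until V falls below v90
  i0 <- which(tt > tt[ipk] + 20)
  if (!length(i0)) return(FALSE)
  i0 <- i0[1]
  iend <- which(tt > tt[i0] & V < v90)
  iend <- if (length(iend)) iend[1] else length(V)
  seg <- V[i0:iend]
  if (length(seg) < 3) return(FALSE)
  # largest rise from a running minimum
  runmin <- cummin(seg)
  max(seg - runmin) >= min_rise
}

#' Dominant frequency of a signal
#'
#' Largest peak of the power spectral density (Hann-tapered periodogram)
#' in the 0.5-20 Hz physiological band, after removal of the mean and a
#' linear trend.
#'
#' @param x numeric signal, uniformly sampled.
#' @param dt sampling interval (ms).
#' @param band frequency band searched (Hz).
#' @return dominant frequency (Hz), or `NA` (flat signal).
#' @export
dominant_frequency <- function(x, dt, band = c(0.5, 20)) {
  n <- length(x)
  if (n < 16) return(NA_real_)
  tt <- seq_len(n)
  x <- stats::residuals(stats::lm(x ~ tt))
  if (sd(x) < 1e-12) return(NA_real_)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  X <- fft(x * w)
  fs <- 1000 / dt
  freq <- (seq_len(n) - 1) * fs / n
  keep <- freq >= band[1] & freq <= band[2]
  if (!any(keep)) return(NA_real_)
  p <- Mod(X[keep])^2
  freq[keep][which.max(p)]
}

#' Lifespan of re-entrant activity
#'
#' Last time any recording site crosses `threshold` (default -30 mV)
#' upward, in seconds, capped at the window length.
#'
#' @param vprobe matrix of probe voltages (sites x samples).
#' @param time sample times (ms).
#' @param threshold crossing threshold (mV).
#' @export
reentry_lifespan <- function(vprobe, time, threshold = -30) {
  vprobe <- rbind(vprobe)
  last <- 0
  for (q in seq_len(nrow(vprobe))) {
    v <- vprobe[q, ]
    up <- which(v[-1] > threshold & v[-length(v)] <= threshold)
    if (length(up)) last <- max(last, time[up[length(up)] + 1])
  }
  min(last, max(time)) / 1000
}
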