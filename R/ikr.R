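#' Markov I_Kr transition-rate matrix
#'
#' Build the 7x7 generator matrix `A` of the drug-extended Markov chain for
#' I_Kr (state order C1, C2, C3, O, I, O*, I*) at a fixed voltage and drug
#' concentration, so that `ds/dt = A %*% s`. Columns of `A` sum to zero
#' (conservative chain). Binding to the open and inactivated states is
#' concentration-scaled (`k * [D] * state`); there is no closed-state
#' binding.
#'
#' @param V membrane potential (mV).
#' @param rates 16-element rate parameter vector (see [ikr_rate_params()]).
#' @param binding numeric `c(kA, lA, kI, lI)`; defaults to no drug.
#' @param D drug concentration (uM).
#' @export
ikr_rate_matrix <- function(V, rates, binding = c(0, 0, 0, 0), D = 0) {
  if (D < 0) stop("D must be >= 0")
  .cpp_markov_matrix(V, as.numeric(rates), as.numeric(binding), D)
}

#' Markov I_Kr occupancy derivatives
#'
#' @param s 7-element occupancy vector (C1, C2, C3, O, I, O*, I*).
#' @inheritParams ikr_rate_matrix
#' @return derivative vector; sums to zero exactly.
#' @export
ikr_markov_rhs <- function(s, V, rates, binding = c(0, 0, 0, 0), D = 0) {
  as.numeric(ikr_rate_matrix(V, rates, binding, D) %*% s)
}

#' I_Kr current from a Markov state
#'
#' Only the drug-free open state conducts: `IKr = gKr * O * (V - EKr)`.
#'
#' @param s occupancy vector or list with element `O` at position 4.
#' @param V membrane potential (mV).
#' @param g_kr maximal conductance (mS/uF).
#' @param e_kr K reversal potential (mV).
#' @export
ikr_current <- function(s, V, g_kr, e_kr) {
  g_kr * s[[4]] * (V - e_kr)
}

#' Heterozygote I_Kr current
#'
#' Mix of two independently gated channel populations, each with its own
#' kinetics and drug states. The default 0.5/0.5 weighting represents the
#' heterozygous SQT1 condition; weight 1 on the mutant population gives the
#' homozygous mutant.
#'
#' @param s_wt,s_mut occupancy vectors of the two populations.
#' @param V membrane potential (mV).
#' @param g_kr shared maximal conductance (must be common to both
#'   populations).
#' @param e_kr reversal potential (mV).
#' @param w_mut weight of the mutant population in `[0, 1]`.
#' @export
heterozygote_current <- function(s_wt, s_mut, V, g_kr, e_kr, w_mut = 0.5) {
  if (length(g_kr) != 1) stop("populations must share a single g_Kr")
  (1 - w_mut) * ikr_current(s_wt, V, g_kr, e_kr) +
    w_mut * ikr_current(s_mut, V, g_kr, e_kr)
}

#' Voltage-clamp protocol
#'
#' A piecewise-constant clamp: a matrix of (holding voltage, duration)
#' segments repeated `nrep` times, with a measurement window given as the
#' index of the segment whose current is measured (tail segment for the
#' I_Kr protocol, test pulse for the Na protocol).
#'
#' @param segments two-column matrix (V in mV, duration in ms).
#' @param nrep number of protocol repetitions.
#' @param measure index of the measured segment.
#' @export
clamp_protocol <- function(segments, nrep = 1, measure = nrow(segments)) {
  segments <- as.matrix(segments)
  if (ncol(segments) != 2) stop("segments must have columns (V, duration)")
  if (any(segments[, 2] <= 0)) stop("segment durations must be > 0")
  if (measure < 1 || measure > nrow(segments)) stop("measure outside protocol")
  structure(list(segments = segments, nrep = nrep, measure = measure),
            class = "clamp_protocol")
}

#' Default hERG tail-current protocol
#'
#' 2 s depolarizing step to +20 mV from a -80 mV holding potential followed
#' by a 500 ms repolarizing tail step to -40 mV at 0.25 Hz; block is
#' measured on the peak tail current once the pulse train has equilibrated.
#'
#' @export
herg_tail_protocol <- function() {
  clamp_protocol(rbind(c(-80, 1450), c(20, 2000), c(-40, 550)),
                 nrep = 12, measure = 3)
}

#' Default Na use-dependence protocol
#'
#' 30 pulses of 50 ms to -20 mV from a -100 mV holding potential at 2 Hz.
#'
#' @export
na_pulse_protocol <- function() {
  clamp_protocol(rbind(c(-100, 450), c(-20, 50)), nrep = 30, measure = 2)
}

# simulate the Markov chain under a piecewise-constant clamp by exact
# matrix-exponential propagation; returns the peak open probability during
# the measured segment of the final repetition, and the full O(t) there.
herg_clamp_open <- function(rates, binding, D, protocol, sample_dt = 2) {
  segs <- protocol$segments
  nseg <- nrow(segs)
  # cache per-segment propagators
  props <- lapply(seq_len(nseg), function(i) {
    A <- ikr_rate_matrix(segs[i, 1], rates, binding, D)
    as.matrix(Matrix::expm(A * segs[i, 2]))
  })
  s <- c(1, 0, 0, 0, 0, 0, 0)
  meas <- protocol$measure
  Emeas <- {
    A <- ikr_rate_matrix(segs[meas, 1], rates, binding, D)
    as.matrix(Matrix::expm(A * sample_dt))
  }
  open_trace <- NULL
  for (rep in seq_len(protocol$nrep)) {
    for (i in seq_len(nseg)) {
      if (rep == protocol$nrep && i == meas) {
        nsamp <- max(2L, ceiling(segs[i, 2] / sample_dt))
        tr <- numeric(nsamp)
        sm <- s
        for (k in seq_len(nsamp)) {
          sm <- as.numeric(Emeas %*% sm)
          tr[k] <- sm[4]
        }
        open_trace <- tr
      }
      s <- as.numeric(props[[i]] %*% s)
    }
  }
  list(peak = max(open_trace), trace = open_trace)
}

#' Simulated fractional block of I_Kr
#'
#' Fractional block of the hERG tail current under a voltage-clamp
#' protocol: `1 - I_drug / I_free`, with the current measured at the tail
#' peak after the pulse train has reached a periodic steady state. The
#' drug-free reference is simulated under the identical protocol.
#'
#' @param protocol a [clamp_protocol()]; default [herg_tail_protocol()].
#' @param condition "WT" or "N588K".
#' @param binding numeric `c(kA, lA, kI, lI)` binding parameters.
#' @param D drug concentration (uM).
#' @return fractional block in `[0, 1]`.
#' @export
simulate_fractional_block <- function(protocol = herg_tail_protocol(),
                                      condition = "WT", binding, D) {
  if (D < 0) stop("D must be >= 0")
  rates <- ikr_rate_params(condition)
  free <- herg_clamp_open(rates, c(0, 0, 0, 0), 0, protocol)$peak
  if (free < 1e-12) stop("drug-free tail current is ~0; block undefined")
  if (D == 0) return(0)
  drugged <- herg_clamp_open(rates, binding, D, protocol)$peak
  1 - drugged / free
}

#' Steady-state Markov occupancancies at fixed voltage
#'
#' Null-space steady state of the transition-rate matrix, normalized to sum
#' to one. Used both as a model operation and as the independent linear-
#' algebra oracle for the time-integrated chain.
#'
#' @inheritParams ikr_rate_matrix
#' @export
ikr_steady_state <- function(V, rates, binding = c(0, 0, 0, 0), D = 0) {
  A <- ikr_rate_matrix(V, rates, binding, D)
  # with no drug the two bound states are disconnected; restrict to the
  # drug-free subchain (their steady occupancy is 0)
  k <- if (D > 0 && (binding[1] > 0 || binding[3] > 0)) 1:7 else 1:5
  M <- rbind(A[k, k], rep(1, length(k)))
  b <- c(rep(0, length(k)), 1)
  s <- qr.solve(M, b)
  out <- numeric(7)
  out[k] <- s / sum(s)
  out
}
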