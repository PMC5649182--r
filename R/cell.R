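#' Simulate a single myocyte
#'
#' Integrates the cell model with fixed-step explicit Euler (Rush-Larsen for
#' Hodgkin-Huxley gates) and returns a uniformly sampled trace of membrane
#' potential, the drug-relevant currents (I_Kr, I_Na, I_CaL) and the
#' fractional block of I_Kr (drug-bound occupancy) and I_Na (bA + bI + bR).
#'
#' @param state initial state from [initial_state()] or a previous run.
#' @param params a [cell_params()] object.
#' @param drug optional [drug_spec()].
#' @param stimulus a [stimulus_spec()].
#' @param t_end simulation end (ms).
#' @param dt time step (ms, <= 0.02).
#' @param out_every output sampling interval (ms).
#' @return a `cell_trace`: list with `time`, `V`, `IKr`, `INa`, `ICaL`,
#'   `fbKr`, `fbNa`, `state` (final state vector) and the stimulus used.
#' @export
simulate_cell <- function(state = NULL, params = cell_params(), drug = NULL,
                          stimulus = stimulus_spec(), t_end = 1000,
                          dt = 0.005, out_every = 0.1) {
  if (dt > 0.02) stop("dt must be <= 0.02 ms for stability")
  pv <- build_pvec(params, drug)
  if (is.null(state)) state <- .cpp_init_state(pv)
  out <- .cpp_cell_run(state, pv, dt, t_end, stimulus$amplitude,
                       stimulus$duration, stimulus$period, stimulus$start,
                       out_every)
  out$stimulus <- stimulus
  out$dt <- out_every
  class(out) <- "cell_trace"
  out
}

#' Pace a myocyte to steady state
#'
#' Runs `n_beats` beats at the stimulus period without recording and
#' returns the final state, used as the pre-pacing stage before any
#' biomarker measurement (100 beats by default).
#'
#' @inheritParams simulate_cell
#' @param n_beats number of pre-pacing beats.
#' @export
prepace_cell <- function(params = cell_params(), drug = NULL,
                         stimulus = stimulus_spec(), n_beats = 100,
                         dt = 0.005, state = NULL) {
  pv <- build_pvec(params, drug)
  if (is.null(state)) state <- .cpp_init_state(pv)
  out <- .cpp_cell_run(state, pv, dt, stimulus$start + n_beats * stimulus$period,
                       stimulus$amplitude, stimulus$duration, stimulus$period,
                       stimulus$start, 0)
  out$state
}

#' One steady-state paced beat
#'
#' Convenience wrapper: pre-pace, then record one full cycle.
#'
#' @inheritParams prepace_cell
#' @param out_every sampling interval of the recorded beat (ms).
#' @export
steady_beat <- function(params = cell_params(), drug = NULL,
                        stimulus = stimulus_spec(), n_beats = 100,
                        dt = 0.005, out_every = 0.1, state = NULL) {
  st <- prepace_cell(params, drug, stimulus, n_beats, dt, state)
  stim2 <- stimulus
  stim2$start <- 10
  simulate_cell(st, params, drug, stim2, t_end = stimulus$period,
                dt = dt, out_every = out_every)
}
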