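#' Single-cell concentration sweep
#'
#' Paces the cell to steady state at each drug concentration (drug binding
#' equilibrates during pre-pacing) and extracts APD90, maximum upstroke
#' velocity and resting/peak potentials. A drug-free baseline row is always
#' included.
#'
#' @param drug_name "disopyramide" or "quinidine".
#' @param concentrations sorted concentrations (uM); may be empty for a
#'   baseline-only table.
#' @param params a [cell_params()] (condition and cell type).
#' @param cl pacing cycle length (ms).
#' @param n_beats pre-pacing beats per concentration.
#' @param actions drug action mask.
#' @param dt integration step (ms).
#' @return data frame: one row per concentration (first row drug-free).
#' @export
concentration_sweep <- function(drug_name, concentrations,
                                params = cell_params("ENDO", "SQT1"),
                                cl = 1000, n_beats = 100, actions = "all",
                                dt = 0.005) {
  if (is.unsorted(concentrations)) stop("concentrations must be sorted")
  conc <- c(0, concentrations)
  rows <- lapply(conc, function(D) {
    drug <- if (D > 0) drug_spec(drug_name, D, actions) else NULL
    tr <- steady_beat(params, drug, stimulus_spec(period = cl),
                      n_beats = n_beats, dt = dt)
    ve <- measure_v_extremes(tr)
    data.frame(drug = drug_name, concentration_uM = D,
               APD90 = as.numeric(measure_apd90(tr)),
               MUV = as.numeric(measure_muv(tr)),
               v_rest = ve[["rest"]], v_peak = ve[["peak"]],
               EAD = detect_ead(tr))
  })
  do.call(rbind, rows)
}

#' Dynamic APD restitution
#'
#' Steady-state APD90 at a range of cycle lengths (fixed pre-pacing per
#' cycle length). Points where the cell shows 2:1 block (no measurable AP
#' on the recorded beat) are flagged and omitted.
#'
#' @param drug optional [drug_spec()].
#' @param cycle_lengths cycle lengths (ms, >= 300).
#' @param params a [cell_params()].
#' @param n_beats pre-pacing beats per cycle length.
#' @param dt integration step (ms).
#' @return data frame with `CL` and `APD90` (NA rows dropped, reported in
#'   the `omitted` attribute).
#' @export
apd_restitution <- function(drug = NULL, cycle_lengths = c(400, 600, 1000, 2000),
                            params = cell_params("ENDO", "SQT1"),
                            n_beats = 50, dt = 0.005) {
  if (any(cycle_lengths < 300)) stop("cycle lengths must be >= 300 ms")
  apd <- vapply(cycle_lengths, function(cl) {
    tr <- steady_beat(params, drug, stimulus_spec(period = cl),
                      n_beats = n_beats, dt = dt)
    as.numeric(measure_apd90(tr))
  }, 0)
  omit <- is.na(apd)
  out <- data.frame(CL = cycle_lengths[!omit], APD90 = apd[!omit])
  attr(out, "omitted") <- cycle_lengths[omit]
  out
}

#' Early-afterdepolarization assay
#'
#' Slow pacing (0.5 Hz) of mid-myocardial cells over a grid of
#' repolarization-reserve modifiers (multiplicative scalings of I_Kr and
#' I_Ks and an I_CaL agonism factor), flagging EADs on the final beat.
#'
#' @param condition "WT" or "SQT1".
#' @param drug optional [drug_spec()].
#' @param modifiers named list of multiplier vectors for `Kr`, `Ks`, `CaL`.
#' @param cl pacing cycle length (ms); 2000 = 0.5 Hz.
#' @param n_beats pre-pacing beats.
#' @param dt integration step.
#' @return data frame: one row per modifier combination with an `EAD` flag.
#' @export
ead_assay <- function(condition = "SQT1", drug = NULL,
                      modifiers = list(Kr = c(0.5, 1), Ks = c(0.25, 0.5, 1),
                                       CaL = c(1, 1.5, 2)),
                      cl = 2000, n_beats = 20, dt = 0.005) {
  grid <- expand.grid(Kr = modifiers$Kr, Ks = modifiers$Ks,
                      CaL = modifiers$CaL)
  grid$EAD <- vapply(seq_len(nrow(grid)), function(i) {
    par <- cell_params("MCELL", condition,
                       scale = list(Kr = grid$Kr[i], Ks = grid$Ks[i],
                                    CaL = grid$CaL[i]))
    tr <- steady_beat(par, drug, stimulus_spec(period = cl),
                      n_beats = n_beats, dt = dt)
    detect_ead(tr)
  }, TRUE)
  grid
}
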