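#' @useDynLib sqtsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim fft rnorm runif approx median sd
#' @importFrom utils head tail modifyList
NULL

# conductance-scale slots understood by the compiled core, in pvec order
.scale_names <- c("Na", "NaL", "to", "CaL", "Kr", "Ks", "K1", "NaCa", "NaK", "Kb")

.cell_types <- c(ENDO = 0L, MCELL = 1L, EPI = 2L)
.conditions <- c(WT = 0, SQT1 = 0.5, N588K = 1)

#' Cell model parameters
#'
#' Construct the parameter set for one human ventricular myocyte of the
#' O'Hara-Rudy lineage used throughout the package. The fast sodium current
#' uses the Luo-Rudy m3hj formulation and I_Kr is carried by a two-population
#' Markov chain (wild-type and N588K kinetics) so that the heterozygous SQT1
#' condition is a 50/50 mix of the two populations.
#'
#' @param cell_type one of "ENDO", "MCELL", "EPI".
#' @param condition one of "WT" (both populations wild-type), "SQT1"
#'   (heterozygote, 50% N588K) or "N588K" (homozygous mutant).
#' @param scale named list of dimensionless multipliers on maximal
#'   conductances; names from `Na`, `NaL`, `to`, `CaL`, `Kr`, `Ks`, `K1`,
#'   `NaCa`, `NaK`, `Kb`. Applied on top of the package's calibrated
#'   default profile.
#' @param gkr_region extra transmural multiplier on I_Kr conductance
#'   (1.6 for EPI in the heterogeneous strand).
#' @return an object of class `cell_params`.
#' @export
cell_params <- function(cell_type = "ENDO", condition = "WT",
                        scale = list(), gkr_region = 1) {
  cell_type <- match.arg(cell_type, names(.cell_types))
  condition <- match.arg(condition, names(.conditions))
  sc <- sqtsim_profile()
  if (length(scale)) {
    bad <- setdiff(names(scale), .scale_names)
    if (length(bad)) stop("unknown scale name(s): ", paste(bad, collapse = ", "))
    for (nm in names(scale)) {
      if (scale[[nm]] < 0) stop("scale multipliers must be >= 0")
      sc[[nm]] <- sc[[nm]] * scale[[nm]]
    }
  }
  structure(list(cell_type = cell_type, condition = condition,
                 scale = sc, gkr_region = gkr_region),
            class = "cell_params")
}

#' Calibrated conductance-scale profile
#'
#' The package's default per-current conductance multipliers, calibrated so
#' that the drug-free transmural strand yields a wild-type QT interval of
#' about 350 ms and an SQT1 QT of about 241 ms at 1 Hz pacing (with the
#' endocardial SQT1 APD90 near 195 ms). See the methods vignette for the
#' calibration procedure.
#'
#' @return named list of multipliers keyed by current.
#' @export
sqtsim_profile <- function() {
  as.list(.sqtsim_defaults$profile)
}

#' Markov I_Kr rate parameters
#'
#' Voltage-dependent transition rates of the I_Kr Markov chain, each of the
#' form `r(V) = P * exp(Q * V)` (ms^-1). The chain is
#' C1 <-> C2 <-> C3 -> {O, I} with O -> C3 (beta2), I -> C3 (mu), O <-> I
#' (betai/alphai); `mu` is tied by microscopic reversibility
#' (mu = alphai * beta2 / betai). N588K differs from wild type only in the
#' inactivation-pathway rates (alphai, betai), reflecting attenuated
#' inactivation with unchanged activation voltage dependence.
#'
#' @param condition "WT" or "N588K".
#' @return numeric vector of 16 values: P,Q pairs for
#'   alpha, beta, alpha1, beta1, alpha2, beta2, alphai, betai.
#' @export
ikr_rate_params <- function(condition = "WT") {
  condition <- match.arg(condition, c("WT", "N588K"))
  .sqtsim_defaults$markov[[condition]]
}

#' hERG binding parameters for a drug
#'
#' Fitted binding (k, ms^-1 uM^-1) and unbinding (l, ms^-1) rate constants
#' for drug interaction with open and inactivated I_Kr channel states,
#' calibrated against the tail-current dose-response so that the re-simulated
#' half-maximal inhibitory concentrations match the reported values
#' (disopyramide: 10.77 uM WT, 15.77 uM N588K; quinidine: 0.62 uM WT,
#' 2.16 uM N588K).
#'
#' @param drug "disopyramide" or "quinidine".
#' @param condition "WT" or "N588K".
#' @return numeric vector `c(kA, lA, kI, lI)`.
#' @export
herg_binding_params <- function(drug, condition = "WT") {
  drug <- match.arg(drug, c("disopyramide", "quinidine"))
  condition <- match.arg(condition, c("WT", "N588K"))
  .sqtsim_defaults$herg_binding[[drug]][[condition]]
}

#' Guarded-receptor Na channel binding parameters
#'
#' Binding/unbinding rate constants of the guarded-receptor sodium channel
#' block model, per drug. Resting-state rates are calibrated so that the
#' simulated tonic-block dose response has the reported half-maximal
#' concentration (36 uM disopyramide, 17 uM quinidine); activated- and
#' inactivated-state rates shape use-dependent block accumulation.
#'
#' @param drug "disopyramide" or "quinidine".
#' @return numeric vector `c(kA, kI, kR, lA, lI, lR)` with k in
#'   ms^-1 uM^-1 and l in ms^-1.
#' @export
na_binding_params <- function(drug) {
  drug <- match.arg(drug, c("disopyramide", "quinidine"))
  .sqtsim_defaults$na_binding[[drug]]
}

#' Stimulus specification
#'
#' @param amplitude stimulus current in uA/uF; depolarizing stimuli are
#'   negative (inward) by the model convention.
#' @param duration pulse duration (ms).
#' @param period pacing period / cycle length (ms).
#' @param start time of the first pulse (ms).
#' @export
stimulus_spec <- function(amplitude = -80, duration = 1, period = 1000,
                          start = 10) {
  if (duration >= period) stop("stimulus duration must be < period")
  structure(list(amplitude = amplitude, duration = duration,
                 period = period, start = start), class = "stimulus_spec")
}

# assemble the flat parameter vector consumed by the compiled core
build_pvec <- function(params, drug = NULL) {
  stopifnot(inherits(params, "cell_params"))
  sc <- unlist(params$scale[.scale_names])
  wmut <- .conditions[[params$condition]]
  hb1 <- c(0, 0, 0, 0)
  hb2 <- c(0, 0, 0, 0)
  nb <- c(0, 0, 0, 0, 0, 0)
  D <- 0
  if (!is.null(drug) && drug$concentration > 0) {
    D <- drug$concentration
    if ("ikr" %in% drug$actions) {
      hb1 <- herg_binding_params(drug$name, "WT")
      hb2 <- herg_binding_params(drug$name,
                                 if (params$condition == "WT") "WT" else "N588K")
    }
    if ("ina" %in% drug$actions) nb <- na_binding_params(drug$name)
    if ("pore" %in% drug$actions) {
      for (nm in names(drug$pore)) {
        slot <- c(I_CaL = "CaL", I_to = "to", I_Ks = "Ks", I_K1 = "K1",
                  I_NaL = "NaL")[[nm]]
        sc[[slot]] <- pore_block_scale(sc[[slot]], D, drug$pore[[nm]])
      }
    }
  }
  mset <- function(cond) .sqtsim_defaults$markov[[cond]]
  mk1 <- mset("WT")
  mk2 <- mset(if (params$condition == "WT") "WT" else "N588K")
  px <- .sqtsim_defaults$profile_extra
  as.numeric(c(.cell_types[[params$cell_type]], sc,
               px[["KsM"]], px[["CaLM"]], px[["NaKM"]], px[["CaLE"]], wmut,
               params$gkr_region, D, hb1, hb2, nb, mk1, mk2))
}

#' Resting initial state
#'
#' A quiescent initial condition (gates at their steady state for the
#' resting potential, Markov chain in the deepest closed state, no block).
#' Use [prepace_cell()] to reach a paced steady state before measuring
#' biomarkers.
#'
#' @param params a [cell_params()] object.
#' @param drug optional [drug_spec()].
#' @return numeric state vector (V followed by the gating, concentration,
#'   Markov and block states).
#' @export
initial_state <- function(params = cell_params(), drug = NULL) {
  .cpp_init_state(build_pvec(params, drug))
}
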