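#' Drug specification
#'
#' Bundle a drug name, free concentration and action mask into the object
#' consumed by the simulation drivers. The action mask supports the
#' mechanistic-decomposition scenarios: I_Kr block alone, I_Na block alone,
#' combined I_Kr + I_Na, or all multi-channel actions (state-dependent I_Kr
#' and I_Na block plus Hill-type pore block of secondary currents).
#'
#' @param name "disopyramide" or "quinidine".
#' @param concentration free drug concentration in uM (>= 0).
#' @param actions character vector, subset of `c("ikr", "ina", "pore")`, or
#'   one of the shorthands "all", "ikr", "ina", "ikr+ina".
#' @return object of class `drug_spec`.
#' @export
drug_spec <- function(name, concentration, actions = "all") {
  name <- match.arg(name, c("disopyramide", "quinidine"))
  if (!is.numeric(concentration) || concentration < 0)
    stop("concentration must be a non-negative number (uM)")
  if (length(actions) == 1 && actions %in% c("all", "ikr", "ina", "ikr+ina")) {
    actions <- switch(actions,
                      all = c("ikr", "ina", "pore"),
                      ikr = "ikr", ina = "ina",
                      `ikr+ina` = c("ikr", "ina"))
  }
  bad <- setdiff(actions, c("ikr", "ina", "pore"))
  if (length(bad)) stop("unknown action(s): ", paste(bad, collapse = ", "))
  structure(list(name = name, concentration = concentration,
                 actions = actions, pore = pore_block_entries(name)),
            class = "drug_spec")
}

#' Secondary pore-block entries
#'
#' Half-maximal inhibitory concentrations for the secondary, non-state-
#' dependent channel actions of each drug (L-type Ca, transient outward K,
#' slow delayed rectifier K; for quinidine additionally inward rectifier K
#' and late Na). Hill coefficients default to 1 and can be overridden per
#' entry. Currents without a reported action are simply absent from the
#' list (no action, not an infinite IC50).
#'
#' @param drug "disopyramide" or "quinidine".
#' @return named list of `c(ic50 = , nh = )` entries keyed by current.
#' @export
pore_block_entries <- function(drug) {
  drug <- match.arg(drug, c("disopyramide", "quinidine"))
  if (drug == "disopyramide") {
    list(I_CaL = c(ic50 = 1036.7, nh = 1),
         I_to = c(ic50 = 20.9, nh = 1),
         I_Ks = c(ic50 = 88.1, nh = 1))
  } else {
    list(I_CaL = c(ic50 = 14.9, nh = 1),
         I_to = c(ic50 = 21.8, nh = 1),
         I_Ks = c(ic50 = 44.0, nh = 1),
         I_K1 = c(ic50 = 42.6, nh = 1),
         I_NaL = c(ic50 = 12.0, nh = 1))
  }
}

#' Hill-type pore block conductance scaling
#'
#' Scales a maximal conductance by `1 / (1 + (D / IC50)^nH)` so that the
#' conductance is unchanged at zero drug and halved at `D = IC50` when
#' `nH = 1`.
#'
#' @param g_control drug-free maximal conductance.
#' @param D drug concentration (uM, >= 0).
#' @param entry numeric vector with elements `ic50` (> 0) and `nh` (> 0).
#' @return scaled conductance, monotone non-increasing in `D`.
#' @export
pore_block_scale <- function(g_control, D, entry) {
  ic50 <- entry[["ic50"]]; nh <- entry[["nh"]]
  if (ic50 <= 0) stop("IC50 must be > 0")
  if (nh <= 0) stop("Hill coefficient must be > 0")
  if (D < 0) stop("concentration must be >= 0")
  g_control / (1 + (D / ic50)^nh)
}

#' Guarded-receptor block derivatives
#'
#' Time derivatives of the fractional block of activated, inactivated and
#' resting sodium channels. Access to each binding site is guarded by the
#' Hodgkin-Huxley gates: activated channels by `m^3 h j`, inactivated by
#' `(1 - h j)`, resting by `(1 - m^3) h j`; each binding flux draws on the
#' common unblocked fraction `1 - bA - bI - bR`.
#'
#' @param b numeric `c(bA, bI, bR)`.
#' @param m,h,j gate values in `[0, 1]`.
#' @param D drug concentration (uM).
#' @param p numeric `c(kA, kI, kR, lA, lI, lR)`.
#' @return numeric `c(dbA, dbI, dbR)` in ms^-1.
#' @export
guarded_na_rhs <- function(b, m, h, j, D, p) {
  u <- 1 - sum(b)
  gA <- m^3 * h * j
  gI <- 1 - h * j
  gR <- (1 - m^3) * h * j
  c(p[["kA"]] * D * gA * u - p[["lA"]] * b[[1]],
    p[["kI"]] * D * gI * u - p[["lI"]] * b[[2]],
    p[["kR"]] * D * gR * u - p[["lR"]] * b[[3]])
}

#' Fast Na current with guarded-receptor block
#'
#' @param m,h,j Hodgkin-Huxley gates.
#' @param b numeric `c(bA, bI, bR)` fractional block.
#' @param V membrane potential (mV).
#' @param g_na maximal conductance (mS/uF).
#' @param e_na Na reversal potential (mV).
#' @export
ina_current <- function(m, h, j, b, V, g_na, e_na) {
  g_na * (1 - sum(b)) * m^3 * h * j * (V - e_na)
}
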