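#' Transmural strand configuration
#'
#' Geometry and physics of the heterogeneous 1D transmural strand: 25
#' endocardial, 35 mid-myocardial and 40 epicardial cells over 15 mm, with
#' isotropic diffusion except for a five-fold reduction at the single
#' MCELL-EPI interface, an ENDO:MCELL:EPI I_Kr conductance ratio of
#' 1.0:1.0:1.6, endocardial stimulation and a virtual unipolar electrode
#' 2.0 cm beyond the epicardial end of the fiber.
#'
#' @param n_endo,n_m,n_epi cells per region.
#' @param length_mm total strand length (mm).
#' @param D diffusion coefficient (cm^2/ms); default calibrated to give a
#'   drug-free conduction velocity near 60 cm/s.
#' @param border_factor reduction factor of D at the MCELL-EPI border.
#' @param gkr_ratio I_Kr multipliers for (ENDO, MCELL, EPI).
#' @param electrode_cm electrode distance beyond the epicardial end (cm).
#' @export
strand_config <- function(n_endo = 25, n_m = 35, n_epi = 40,
                          length_mm = 15, D = NULL, border_factor = 5,
                          gkr_ratio = c(1, 1, 1.6), electrode_cm = 2.0) {
  if (is.null(D)) D <- .sqtsim_defaults$tissue$D
  n <- n_endo + n_m + n_epi
  dx <- length_mm / n / 10  # cm
  region <- c(rep(0L, n_endo), rep(1L, n_m), rep(2L, n_epi))
  gkrmult <- gkr_ratio[region + 1L]
  Dhalf <- rep(D, n - 1)
  Dhalf[n_endo + n_m] <- D / border_factor  # MCELL-EPI interface (one node)
  structure(list(n = n, n_endo = n_endo, n_m = n_m, n_epi = n_epi,
                 dx = dx, D = D, Dhalf = Dhalf, region = region,
                 gkrmult = gkrmult, electrode_cm = electrode_cm),
            class = "strand_config")
}

# per-region parameter matrix and prepaced initial states for a strand
strand_setup <- function(config, condition, drug = NULL, cl = 1000,
                         n_prepace = 100, dt = 0.005) {
  types <- c("ENDO", "MCELL", "EPI")
  first_of <- function(g) {
    i <- which(config$region == g - 1L)
    if (length(i)) config$gkrmult[i[1]] else 1
  }
  gkr_by_region <- c(first_of(1), first_of(2), first_of(3))
  pmat <- NULL
  states <- vector("list", 3)
  stim <- stimulus_spec(period = cl)
  for (g in 1:3) {
    par <- cell_params(types[g], condition, gkr_region = gkr_by_region[g])
    pv <- build_pvec(par, drug)
    states[[g]] <- prepace_cell(par, drug, stim, n_beats = n_prepace, dt = dt)
    # strand core applies per-cell gkrmult on top of the region pvec, so
    # strip the region factor from the pvec itself
    pv2 <- build_pvec(cell_params(types[g], condition), drug)
    pmat <- rbind(pmat, pv2)
  }
  state0 <- do.call(rbind, lapply(config$region + 1L,
                                  function(g) states[[g]]))
  list(pmat = pmat, state0 = state0)
}

#' Simulate the paced transmural strand
#'
#' Pre-paces each cell type to single-cell steady state (with the drug
#' present, so binding equilibrates cheaply), then paces the coupled strand
#' from the endocardial end. The final beat is recorded at fine resolution
#' for biomarker extraction.
#'
#' @param config a [strand_config()].
#' @param condition "WT", "SQT1" or "N588K".
#' @param drug optional [drug_spec()].
#' @param cl pacing cycle length (ms).
#' @param n_beats number of coupled-strand beats (the last is analyzed).
#' @param n_prepace single-cell pre-pacing beats per region.
#' @param dt integration step (ms).
#' @param out_every sampling of the final recorded beat (ms).
#' @return list with `time`, `V` (cells x samples, final beat), `pecg`,
#'   `config`, `stim_time` (stimulus onset in recorded-beat time) and the
#'   final full `state`.
#' @export
simulate_strand <- function(config = strand_config(), condition = "WT",
                            drug = NULL, cl = 1000, n_beats = 4,
                            n_prepace = 100, dt = 0.005, out_every = 0.05,
                            setup = NULL) {
  cfl <- config$dx^2 / (2 * max(config$Dhalf))
  if (dt > cfl) stop(sprintf("dt violates CFL bound; need dt <= %.4g ms", cfl))
  if (is.null(setup))
    setup <- strand_setup(config, condition, drug, cl, n_prepace, dt)
  stim_t0 <- 10
  s1 <- stim_t0 + (seq_len(n_beats) - 1) * cl
  none <- numeric(0)
  # settle beats, coarse output
  res1 <- if (n_beats > 1) {
    .cpp_strand_run(setup$state0, config$region, setup$pmat,
                    config$gkrmult, config$Dhalf, config$dx, dt,
                    (n_beats - 1) * cl, s1, 2, -80, 0L, 2L,
                    none, 0, 0, 0L, 0L, 1)
  } else list(state = setup$state0)
  # final beat, fine output
  res2 <- .cpp_strand_run(res1$state, config$region, setup$pmat,
                          config$gkrmult, config$Dhalf, config$dx, dt,
                          cl, stim_t0, 2, -80, 0L, 2L,
                          none, 0, 0, 0L, 0L, out_every)
  pecg <- compute_pecg(res2$V, res2$time, config)
  list(time = res2$time, V = res2$V, pecg = pecg, config = config,
       stim_time = stim_t0, state = res2$state, setup = setup,
       cl = cl, condition = condition, drug = drug, dt = dt)
}

#' Pseudo-ECG of a strand
#'
#' Far-field unipolar potential of the fiber,
#' `phi(t) = sum_i (-dV/dx)_i * d/dx(1/r_i) * dx`, with central-difference
#' spatial gradients and the electrode on the fiber axis beyond the
#' epicardial end (`d/dx(1/r) = 1/r^2` for an electrode ahead of the
#' fiber). Arbitrary units.
#'
#' @param V matrix (cells x samples) of membrane potential.
#' @param time sample times (ms).
#' @param config a [strand_config()].
#' @export
compute_pecg <- function(V, time, config) {
  n <- nrow(V)
  dx <- config$dx
  xe <- (n - 1) * dx + config$electrode_cm
  x <- (seq_len(n) - 1) * dx
  r <- xe - x
  if (any(r <= 0)) stop("electrode must lie outside the tissue")
  kern <- 1 / r^2
  # central differences; one-sided at the ends
  gv <- V
  gv[2:(n - 1), ] <- (V[3:n, ] - V[1:(n - 2), ]) / (2 * dx)
  gv[1, ] <- (V[2, ] - V[1, ]) / dx
  gv[n, ] <- (V[n, ] - V[n - 1, ]) / dx
  phi <- as.numeric(colSums(-gv * kern) * dx)
  list(time = time, phi = phi)
}

#' QT interval from a pseudo-ECG
#'
#' QRS onset is the first deflection from baseline after the stimulus; the
#' end of the T wave is the intersection with the baseline (the
#' pre-stimulus mean) of the tangent at the steepest point of the terminal
#' descending limb of the T wave -- the portion of the descent between
#' one third and 8% of the T-wave amplitude, i.e. the limb that actually
#' returns the signal to baseline.
#' Restricting the tangent to the terminal limb makes the measurement
#' robust to shouldered or multiphasic T waves, in the spirit of the
#' clinical tangent method, which uses the terminal downslope.
#'
#' @param pecg list with `time` and `phi`.
#' @param stim_time stimulus onset (ms).
#' @param qrs_skip blanking after QRS onset before T-wave search (ms).
#' @param hi_frac upper amplitude fraction bounding the terminal limb.
#' @param lo_frac settle threshold as a fraction of T amplitude.
#' @return QT interval (ms) or `NA` (unmeasurable) if no T wave is found.
#' @export
measure_qt <- function(pecg, stim_time = 10, qrs_skip = 80,
                       hi_frac = 1/3, lo_frac = 0.08) {
  tt <- pecg$time; phi <- pecg$phi
  base <- mean(phi[tt < stim_time])
  dev <- phi - base
  big <- max(abs(dev[tt > stim_time]))
  if (big < 1e-12) return(structure(NA_real_, unmeasurable = TRUE))
  on <- which(tt > stim_time & abs(dev) > 0.05 * big)
  if (!length(on)) return(structure(NA_real_, unmeasurable = TRUE))
  t0 <- tt[on[1]]
  # T wave: largest deflection after the blanking window
  tw <- which(tt > t0 + qrs_skip)
  if (length(tw) < 5) return(structure(NA_real_, unmeasurable = TRUE))
  ipk <- tw[which.max(abs(dev[tw]))]
  sgn <- sign(dev[ipk]); amp <- abs(dev[ipk])
  sd_ <- sgn * dev
  settle <- which(tt > tt[ipk] & sd_ > lo_frac * amp)
  if (!length(settle)) return(structure(NA_real_, unmeasurable = TRUE))
  t_settle <- tt[settle[length(settle)]]
  hi <- which(tt > tt[ipk] & tt <= t_settle & sd_ > hi_frac * amp)
  t_hi <- if (length(hi)) tt[hi[length(hi)]] else tt[ipk]
  win <- which(tt >= t_hi & tt <= t_settle)
  if (length(win) < 3) return(structure(NA_real_, unmeasurable = TRUE))
  slope <- diff(phi[win]) / diff(tt[win])
  ist <- which.min(sgn * slope)
  i <- win[ist]
  m <- slope[ist]
  if (sgn * m >= 0) return(structure(NA_real_, unmeasurable = TRUE))
  t_end <- tt[i] + (base - phi[i]) / m
  t_end - t0
}

#' Conduction velocity of a planar wave
#'
#' Activation-time difference (instant of maximal dV/dt) between two
#' interior cells at least 20 cells from the boundaries.
#'
#' @param V matrix (cells x samples).
#' @param time sample times (ms).
#' @param config a [strand_config()].
#' @param cells the two measurement cells (1-based).
#' @return conduction velocity in cm/s, or `NA` on conduction failure.
#' @export
measure_cv <- function(V, time, config, cells = NULL) {
  n <- nrow(V)
  if (is.null(cells)) cells <- c(26, n - 25)
  at <- activation_times(V, time)[cells]
  if (any(is.na(at))) return(structure(NA_real_, unmeasurable = TRUE))
  dtms <- at[2] - at[1]
  if (dtms <= 0) return(structure(NA_real_, unmeasurable = TRUE))
  dist_cm <- (cells[2] - cells[1]) * config$dx
  dist_cm / dtms * 1000
}

activation_times <- function(V, time, vthr = -30) {
  apply(V, 1, function(v) {
    dv <- diff(v)
    i <- which.max(dv)
    if (max(v) < vthr) return(NA_real_)
    time[i]
  })
}

repolarization_times <- function(V, time, stim_time = 10) {
  n <- nrow(V)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    v <- V[i, ]
    vrest <- v[which(time < stim_time)[sum(time < stim_time)]]
    vpeak <- max(v)
    if (vpeak < -30) next
    v90 <- vpeak - 0.9 * (vpeak - vrest)
    ipk <- which.max(v)
    below <- which(time > time[ipk] & v < v90)
    if (!length(below)) next
    i2 <- below[1]; i1 <- i2 - 1
    out[i] <- time[i1] + (v90 - v[i1]) * (time[i2] - time[i1]) / (v[i2] - v[i1])
  }
  out
}

#' Maximal transmural dispersion of repolarization
#'
#' Range of per-cell repolarization times (the APD90-end instant of each
#' cell, which includes activation delay).
#'
#' @inheritParams measure_cv
#' @param stim_time stimulus onset (ms).
#' @export
measure_tdr <- function(V, time, stim_time = 10) {
  rt <- repolarization_times(V, time, stim_time)
  if (any(is.na(rt))) return(structure(NA_real_, unmeasurable = TRUE))
  max(rt) - min(rt)
}

#' Re-entry wavelength
#'
#' `WL = CV x ERP`, returned in mm for CV in cm/s and ERP in ms.
#'
#' @param cv conduction velocity (cm/s).
#' @param erp effective refractory period (ms).
#' @export
wavelength <- function(cv, erp) cv * erp / 100

#' Effective refractory period of the strand
#'
#' ERP is the shortest S1-S2 coupling interval for which a premature
#' endocardial stimulus still propagates to the epicardial end, found by
#' bisection after an S1 conditioning train.
#'
#' @param config a [strand_config()].
#' @param condition,drug,cl as in [simulate_strand()].
#' @param n_s1 S1 conditioning beats in the coupled strand.
#' @param n_prepace single-cell pre-pacing beats.
#' @param resolution bisection resolution (ms).
#' @param bounds initial search bracket for the coupling interval (ms).
#' @param dt integration step (ms).
#' @return ERP in ms (attribute `flag` if the bracket never captures).
#' @export
measure_erp <- function(config = strand_config(), condition = "WT",
                        drug = NULL, cl = 1000, n_s1 = 5, n_prepace = 100,
                        resolution = 1, bounds = c(150, NULL), dt = 0.005,
                        setup = NULL, state0 = NULL) {
  if (is.null(setup))
    setup <- strand_setup(config, condition, drug, cl, n_prepace, dt)
  stim_t0 <- 10
  none <- numeric(0)
  if (is.null(state0)) state0 <- setup$state0
  if (n_s1 > 1) {
    s1 <- stim_t0 + (seq_len(n_s1) - 1) * cl
    cond <- .cpp_strand_run(state0, config$region, setup$pmat,
                            config$gkrmult, config$Dhalf, config$dx, dt,
                            (n_s1 - 1) * cl, s1, 2, -80, 0L, 2L,
                            none, 0, 0, 0L, 0L, 5)
  } else {
    cond <- list(state = state0)
  }
  probe <- config$n - 5L
  trial <- function(ci) {
    # one more S1 at stim_t0 then S2 at stim_t0 + ci
    res <- .cpp_strand_run(cond$state, config$region, setup$pmat,
                           config$gkrmult, config$Dhalf, config$dx, dt,
                           ci + 300, stim_t0, 2, -80, 0L, 2L,
                           stim_t0 + ci, 2, -80, 0L, 2L, 0.5)
    v <- res$V[probe, ]
    tt <- res$time
    win <- tt > stim_t0 + ci + 2
    vv <- v[win]
    any(vv[-1] > -30 & vv[-length(vv)] <= -30)
  }
  lo <- bounds[1]
  hi <- if (length(bounds) > 1 && !is.null(bounds[2])) bounds[2] else cl - 50
  if (!trial(hi)) return(structure(NA_real_, flag = "no capture in bracket"))
  if (trial(lo)) return(structure(lo, flag = "captures at lower bound"))
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (trial(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Strand biomarker report
#'
#' Runs the paced strand and extracts QT, CV and TDR; optionally ERP and
#' the wavelength `CV x ERP`.
#'
#' @inheritParams simulate_strand
#' @param erp logical: also measure the effective refractory period
#'   (re-uses the prepaced setup).
#' @param n_s1,erp_resolution forwarded to [measure_erp()].
#' @export
strand_biomarkers <- function(config = strand_config(), condition = "WT",
                              drug = NULL, cl = 1000, n_beats = 4,
                              n_prepace = 100, dt = 0.005, erp = FALSE,
                              n_s1 = 5, erp_resolution = 1) {
  setup <- strand_setup(config, condition, drug, cl, n_prepace, dt)
  run <- simulate_strand(config, condition, drug, cl, n_beats, n_prepace,
                         dt, setup = setup)
  out <- list(
    QT = measure_qt(run$pecg, run$stim_time),
    CV = measure_cv(run$V, run$time, config),
    TDR = measure_tdr(run$V, run$time, run$stim_time)
  )
  if (erp) {
    # the recorded run ends one cycle after its last stimulus, i.e. at a
    # paced steady state: use it as the conditioned S1 state directly
    out$ERP <- measure_erp(config, condition, drug, cl, n_s1, n_prepace,
                           erp_resolution, dt = dt, setup = setup,
                           state0 = if (n_s1 <= 1) run$state else NULL)
    out$WL <- wavelength(out$CV, out$ERP)
  }
  out$run <- run
  out
}
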