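#' Reference action-potential cycle
#'
#' Full state trajectory of one steady paced cycle of a cell, sampled
#' uniformly; used by the phase-distribution re-entry initiation, which
#' maps each tissue node's state to a point on this cycle.
#'
#' @param params a [cell_params()].
#' @param drug optional [drug_spec()].
#' @param cl cycle length of the reference beat (ms).
#' @param n_beats pre-pacing beats.
#' @param every sampling interval of the cycle (ms).
#' @param dt integration step.
#' @return matrix (state variables x phase samples).
#' @export
reference_cycle <- function(params, drug = NULL, cl = 400, n_beats = 20,
                            every = 1, dt = 0.005) {
  stim <- stimulus_spec(period = cl, start = 0)
  st <- prepace_cell(params, drug, stim, n_beats = n_beats, dt = dt)
  pv <- build_pvec(params, drug)
  .cpp_cell_record(st, pv, dt, cl, stim$amplitude, stim$duration,
                   cl, 0, every)
}

#' Phase-distribution initial state
#'
#' Maps a phase field in `[0, 1)` onto the reference cycle: each node's
#' full state vector is set to the cycle state at its phase. An
#' asymmetric (e.g. spiral) phase map creates an artificial conduction
#' pattern that develops into re-entry.
#'
#' @param phase numeric matrix (nx x ny) of phases in `[0, 1)`.
#' @param cycle a [reference_cycle()] matrix.
#' @return state matrix (nx*ny x n_state) for [simulate_sheet()].
#' @export
init_phase_distribution <- function(phase, cycle) {
  if (any(phase < 0 | phase >= 1)) stop("phases must lie in [0, 1)")
  ncyc <- ncol(cycle)
  idx <- pmin(ncyc, 1L + floor(phase * ncyc))
  t(cycle[, as.vector(idx), drop = FALSE])
}

#' Archimedean-spiral phase map
#'
#' `phase(x, y) = (theta / 2pi + r / lambda) mod 1` about the sheet
#' center: the classic seed for a single spiral wave.
#'
#' @param nx,ny grid dimensions.
#' @param lambda radial pitch in nodes.
#' @param x0,y0 core position (defaults to the center).
#' @export
spiral_phase_map <- function(nx, ny, lambda = 60, x0 = NULL, y0 = NULL) {
  if (is.null(x0)) x0 <- (nx + 1) / 2
  if (is.null(y0)) y0 <- (ny + 1) / 2
  ix <- matrix(seq_len(nx), nx, ny)
  iy <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  th <- atan2(iy - y0, ix - x0)
  r <- sqrt((ix - x0)^2 + (iy - y0)^2)
  (th / (2 * pi) + r / lambda) %% 1
}

#' Simulate a 2D tissue sheet
#'
#' Homogeneous monodomain sheet (5-point Laplacian, no-flux boundaries)
#' with a far-field unipolar pseudo-ECG computed on the fly and a grid of
#' voltage probes for lifespan analysis.
#'
#' @param state0 initial state matrix (nx*ny x n_state), e.g. from
#'   [init_phase_distribution()].
#' @param params a [cell_params()].
#' @param drug optional [drug_spec()].
#' @param nx,ny grid size.
#' @param dx node spacing (cm).
#' @param D diffusion coefficient (cm^2/ms).
#' @param t_end simulated time (ms).
#' @param dt step (ms); checked against the CFL bound.
#' @param electrode electrode position `c(x, y, z)` in cm; default ~3 cm
#'   from the sheet center, off-plane.
#' @param probes matrix of 0-based probe indices (ix, iy); default a 3x3
#'   interior grid.
#' @param out_every sampling of pECG and probes (ms).
#' @param snap_every voltage snapshot interval (ms; 0 = none).
#' @export
simulate_sheet <- function(state0, params, drug = NULL, nx, ny,
                           dx = 0.025, D = NULL, t_end = 2000, dt = 0.005,
                           electrode = NULL, probes = NULL,
                           out_every = 1, snap_every = 0) {
  if (is.null(D)) D <- .sqtsim_defaults$tissue$D
  cfl <- dx^2 / (4 * D)
  if (dt > cfl) stop(sprintf("dt violates CFL bound; need dt <= %.4g ms", cfl))
  if (is.null(electrode))
    electrode <- c(nx * dx / 2, ny * dx / 2, 3.0)
  if (is.null(probes)) {
    qs <- function(n) round(n * c(0.25, 0.5, 0.75))
    probes <- as.matrix(expand.grid(qs(nx), qs(ny)))
  }
  pv <- build_pvec(params, drug)
  res <- .cpp_sheet_run(state0, pv, as.integer(nx), as.integer(ny), D, dx,
                        dt, t_end, electrode, probes, out_every, snap_every)
  res$nx <- nx; res$ny <- ny; res$dx <- dx
  res
}

#' Scaled re-entry experiment
#'
#' Initiates a spiral wave on an SQT1 sheet by the phase-distribution
#' method and returns the dominant frequency of the pseudo-ECG and the
#' lifespan of re-entrant activity. This is a deliberately scaled-down
#' analog of whole-wedge re-entry simulations: trends with drug dose (not
#' absolute values) are the meaningful output.
#'
#' @param drug optional [drug_spec()].
#' @param condition tissue condition.
#' @param nx,ny,dx,t_end,dt,D forwarded to [simulate_sheet()].
#' @param lambda spiral pitch (nodes).
#' @param df_window portion of the record used for the spectrum (ms,
#'   from the start).
#' @export
reentry_experiment <- function(drug = NULL, condition = "SQT1",
                               nx = 100, ny = 100, dx = 0.025,
                               t_end = 2200, dt = 0.02, D = NULL,
                               lambda = 70, cl_ref = 400) {
  # scaled-down analog: coupling is reduced so that the re-entrant
  # wavelength fits the desk-scale domain; absolute frequencies are not
  # comparable to whole-wedge simulations, dose trends are
  if (is.null(D))
    D <- .sqtsim_defaults$tissue$D / .sqtsim_defaults$tissue$reentry_scale
  par <- cell_params("ENDO", condition)
  cyc <- reference_cycle(par, drug, cl = cl_ref)
  ph <- spiral_phase_map(nx, ny, lambda = lambda)
  st0 <- init_phase_distribution(ph, cyc)
  run <- simulate_sheet(st0, par, drug, nx, ny, dx = dx, D = D,
                        t_end = t_end, dt = dt)
  life <- reentry_lifespan(run$vprobe, run$time)
  # spectrum over the active portion of the record (>= 1 s where possible)
  t_hi <- max(1000, min(life * 1000, max(run$time)))
  seg <- run$pecg[run$time <= t_hi]
  df <- dominant_frequency(seg, dt = diff(run$time[1:2]))
  list(DF = df, lifespan = life, run = run)
}
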