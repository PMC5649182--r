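test_that("pseudo-ECG of spatially uniform tissue vanishes", {
  cfg <- strand_config()
  V <- matrix(-85, nrow = cfg$n, ncol = 10)
  p <- compute_pecg(V, seq_len(10), cfg)
  expect_equal(max(abs(p$phi)), 0)
})

test_that("pseudo-ECG matches a hand-computed discrete sum", {
  cfg <- strand_config(n_endo = 2, n_m = 2, n_epi = 2, length_mm = 0.9)
  # static two-compartment step: cells 1-3 at 0 mV, cells 4-6 at -80
  V <- matrix(c(0, 0, 0, -80, -80, -80), ncol = 1)
  p <- compute_pecg(V, 1, cfg)
  dx <- cfg$dx
  xe <- 5 * dx + 2.0
  x <- (0:5) * dx
  grad <- c((V[2] - V[1]) / dx,
            (V[3:6] - V[1:4]) / (2 * dx),
            (V[6] - V[5]) / dx)
  oracle <- sum(-grad / (xe - x)^2) * dx
  expect_equal(p$phi, oracle)
})

test_that("electrode inside the tissue is rejected", {
  cfg <- strand_config(electrode_cm = -1)
  V <- matrix(-85, nrow = cfg$n, ncol = 3)
  expect_error(compute_pecg(V, 1:3, cfg), "outside")
})

test_that("CFL-violating steps are refused with a suggestion", {
  fine <- strand_config(length_mm = 1.5)  # dx = 15 um
  expect_error(simulate_strand(fine, "WT", dt = 0.005,
                               n_prepace = 1, n_beats = 1),
               "CFL")
})

test_that("a single-cell strand reproduces the cell model", {
  cfg <- strand_config(n_endo = 1, n_m = 0, n_epi = 0, length_mm = 0.15)
  par <- cell_params("ENDO", "SQT1")
  st <- matrix(initial_state(par), nrow = 1)
  res <- sqtsim:::.cpp_strand_run(st, 0L, rbind(sqtsim:::build_pvec(par)),
                                  1.0, numeric(0), cfg$dx, 0.005, 400,
                                  10, 2, -80, 0L, 0L,
                                  numeric(0), 0, 0, 0L, 0L, 0.1)
  tr <- simulate_cell(initial_state(par), par,
                      stimulus = stimulus_spec(duration = 2, period = 1000),
                      t_end = 400, out_every = 0.1)
  expect_lt(max(abs(res$V[1, ] - tr$V)), 1e-6)
})

test_that("conduction velocity scales as the square root of coupling", {
  run_cv <- function(Dc) {
    cfg <- strand_config(n_endo = 60, n_m = 0, n_epi = 0, length_mm = 9,
                         D = Dc, gkr_ratio = c(1, 1, 1))
    run <- simulate_strand(cfg, "SQT1", n_prepace = 3, n_beats = 1,
                           out_every = 0.05)
    measure_cv(run$V, run$time, cfg, cells = c(16, 46))
  }
  cv1 <- run_cv(0.000937)
  cv2 <- run_cv(2 * 0.000937)
  expect_equal(cv2 / cv1, sqrt(2), tolerance = 0.05)
  # uniform-strand CV exceeds the heterogeneous-strand value (which is
  # dragged by the reduced-coupling MCELL-EPI border) but stays in range
  expect_gt(cv1, 55); expect_lt(cv1, 75)
})

test_that("wavelength is the CV x ERP product in consistent units", {
  expect_equal(wavelength(60.2, 235), 141.47)
  expect_equal(wavelength(0, 300), 0)
  expect_equal(wavelength(40.3, 481), 193.8, tolerance = 1e-3)
})

test_that("ERP bisection is insensitive to resolution refinement", {
  cfg <- strand_config(n_endo = 10, n_m = 10, n_epi = 10, length_mm = 4.5)
  e2 <- measure_erp(cfg, "SQT1", n_s1 = 2, n_prepace = 10, resolution = 2,
                    bounds = c(120, 600))
  e1 <- measure_erp(cfg, "SQT1", n_s1 = 2, n_prepace = 10, resolution = 1,
                    bounds = c(120, 600))
  expect_lt(abs(e2 - e1), 2 + 1e-9)
})

test_that("homogeneous strand TDR is bounded by conduction delay", {
  cfg <- strand_config(n_endo = 40, n_m = 0, n_epi = 0, length_mm = 6,
                       gkr_ratio = c(1, 1, 1))
  run <- simulate_strand(cfg, "SQT1", n_prepace = 10, n_beats = 2)
  tdr <- measure_tdr(run$V, run$time)
  # without cell-type heterogeneity the dispersion is only the activation
  # spread (~8 ms here) plus electrotonic APD modulation along the cable
  # (stimulated-end shortening, mid-cable lengthening) -- well below the
  # ~40-50 ms of the heterogeneous transmural strand
  expect_lt(tdr, 30)
})
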