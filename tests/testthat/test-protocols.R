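test_that("drug-free restitution shows rate adaptation, flattened in SQT1", {
  wt <- apd_restitution(NULL, c(500, 2000), cell_params("ENDO", "WT"),
                        n_beats = 25)
  sq <- apd_restitution(NULL, c(500, 2000), cell_params("ENDO", "SQT1"),
                        n_beats = 25)
  # APD90 lengthens with cycle length
  expect_gt(diff(wt$APD90), 0)
  expect_gt(diff(sq$APD90), 0)
  # mutant kinetics reduce rate adaptation (flatter restitution)
  expect_lt(diff(sq$APD90), diff(wt$APD90))
})

test_that("cycle lengths below capture range are rejected", {
  expect_error(apd_restitution(NULL, c(200, 400)), ">= 300")
})

test_that("baseline wild type shows no EADs under slow pacing", {
  grid <- ead_assay("WT", NULL, modifiers = list(Kr = 1, Ks = 1, CaL = 1),
                    n_beats = 10)
  expect_false(any(grid$EAD))
})

test_that("phase-distribution initiation maps states onto the cycle", {
  cyc <- matrix(rnorm(53 * 100), nrow = 53)
  ph <- matrix(c(0, 0.25, 0.5, 0.999), 2, 2)
  st <- init_phase_distribution(ph, cyc)
  expect_equal(st[1, ], cyc[, 1])
  expect_equal(st[4, ], cyc[, 100])
  expect_error(init_phase_distribution(matrix(1.2, 1, 1), cyc), "phases")
  # constant phase map = uniform state
  stc <- init_phase_distribution(matrix(0.3, 3, 3), cyc)
  expect_equal(nrow(unique(stc)), 1)
  # spiral map covers the full phase range
  sp <- spiral_phase_map(40, 40, lambda = 30)
  expect_true(all(sp >= 0 & sp < 1))
  expect_gt(diff(range(sp)), 0.95)
})
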