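test_that("an unstimulated cell rests quietly", {
  tr <- simulate_cell(params = cell_params("ENDO", "WT"),
                      stimulus = stimulus_spec(amplitude = 0),
                      t_end = 5000, out_every = 1)
  expect_lt(diff(range(tr$V)), 1)
  # near-equilibrium: late drift is tiny
  late <- tr$V[tr$time > 4000]
  expect_lt(abs(late[length(late)] - late[1]), 0.05)
})

test_that("zero drug concentration reproduces the drug-free model exactly", {
  par <- cell_params("ENDO", "SQT1")
  tr0 <- simulate_cell(params = par, t_end = 2000)
  tr1 <- simulate_cell(params = par, drug = drug_spec("quinidine", 0, "all"),
                       t_end = 2000)
  expect_identical(tr0$V, tr1$V)
  expect_identical(tr0$state, tr1$state)
})

test_that("step halving changes APD90 by less than 1 ms", {
  par <- cell_params("ENDO", "SQT1")
  a1 <- measure_apd90(steady_beat(par, n_beats = 15, dt = 0.005))
  a2 <- measure_apd90(steady_beat(par, n_beats = 15, dt = 0.0025))
  expect_lt(abs(a1 - a2), 1)
})

test_that("paced cell is periodic after pre-pacing", {
  par <- cell_params("ENDO", "SQT1")
  st <- prepace_cell(par, n_beats = 60)
  b1 <- simulate_cell(st, par, t_end = 1000)
  b2 <- simulate_cell(b1$state, par, t_end = 1000)
  expect_lt(abs(measure_apd90(b1) - measure_apd90(b2)), 0.5)
})

test_that("mutant kinetics shorten the APD at every rate tested", {
  for (cl in c(600, 1000)) {
    wt <- measure_apd90(acc_beat("WT", cl = cl, n_beats = 40))
    sq <- measure_apd90(acc_beat("SQT1", cl = cl, n_beats = 40))
    ho <- measure_apd90(acc_beat("N588K", cl = cl, n_beats = 40))
    expect_lt(sq, wt)
    expect_lt(ho, sq)
  }
})

test_that("Markov occupancies stay conserved and non-negative over 10 s", {
  par <- cell_params("ENDO", "SQT1")
  drug <- drug_spec("quinidine", 5, "all")
  st <- prepace_cell(par, drug, n_beats = 10)  # 10 beats at 1 Hz = 10 s
  occ1 <- st[1 + 36:42]; occ2 <- st[1 + 43:49]
  expect_lt(abs(sum(occ1) - 1), 1e-6)
  expect_lt(abs(sum(occ2) - 1), 1e-6)
  expect_gt(min(occ1, occ2), -1e-9)
  # Na block pools remain a physical fraction
  b <- st[1 + 50:52]
  expect_gt(min(b), -1e-12)
  expect_lt(sum(b), 1)
})

test_that("instability is reported with a diagnostic", {
  par <- cell_params("ENDO", "WT")
  expect_error(
    simulate_cell(params = par,
                  stimulus = stimulus_spec(amplitude = -8000, duration = 50,
                                           period = 100),
                  t_end = 300),
    "unstable")
  expect_error(simulate_cell(params = par, dt = 0.05), "dt")
})
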