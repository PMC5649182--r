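test_that("Hill fitting recovers exact dose-response parameters", {
  conc <- exp(seq(log(0.2), log(100), length.out = 8))
  blocks <- 1 / (1 + (5 / conc)^1)
  fit <- ic50_from_curve(conc, blocks)
  expect_equal(fit$ic50, 5, tolerance = 1e-6)
  expect_equal(fit$nh, 1, tolerance = 1e-5)
  expect_true(fit$ok)
  # saturated-flat data are flagged
  flat <- ic50_from_curve(conc, rep(0.97, 8) + 1e-3 * seq_len(8))
  expect_false(flat$ok)
})

test_that("bounded Nelder-Mead respects bounds and is seed-deterministic", {
  fn <- function(x) sum((x - c(0.3, 2))^2)
  f1 <- nm_bounded(fn, c(0.5, 1), lower = c(0, 0.5), upper = c(1, 5),
                   n_starts = 3, seed = 7)
  f2 <- nm_bounded(fn, c(0.5, 1), lower = c(0, 0.5), upper = c(1, 5),
                   n_starts = 3, seed = 7)
  expect_identical(f1$par, f2$par)
  expect_true(all(f1$par >= c(0, 0.5) & f1$par <= c(1, 5)))
  expect_equal(f1$par, c(0.3, 2), tolerance = 1e-3)
  # minimum outside the box lands on the boundary region
  f3 <- nm_bounded(function(x) (x - 10)^2, 0.5, lower = 0, upper = 1,
                   n_starts = 2, seed = 1)
  expect_lte(f3$par, 1)
  expect_gt(f3$par, 0.99)
})

test_that("noise-free Na dataset is refit to a near-zero objective", {
  truth <- na_binding_params("quinidine")
  ds <- gen_block_dataset("na", truth, sigma = 0, seed = 1)
  fit <- fit_na_binding(ds, x0 = as.numeric(truth), n_starts = 1)
  expect_lt(fit$objective, 1e-8)
  expect_equal(fit$tonic_ic50, 17, tolerance = 0.02)
})

test_that("noisy round trip recovers the Na tonic IC50 within 5%", {
  truth <- na_binding_params("disopyramide")
  ds <- gen_block_dataset("na", truth, sigma = 0.02, seed = 11,
                          drug = "disopyramide")
  fit <- fit_na_binding(ds, n_starts = 2, seed = 3)
  expect_equal(fit$tonic_ic50, 36, tolerance = 0.05)
})

test_that("noisy round trip recovers the hERG IC50 within 5%", {
  truth <- herg_binding_params("disopyramide", "WT")
  ds <- gen_block_dataset("herg", truth, condition = "WT", sigma = 0.02,
                          seed = 5, drug = "disopyramide")
  fit <- fit_herg_binding(ds, "WT", n_starts = 2, seed = 2)
  # the generator's truth re-simulates to ~the disopyramide WT IC50
  expect_equal(fit$ic50, 10.77, tolerance = 0.05)
})
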