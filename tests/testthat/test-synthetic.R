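test_that("generators are seed-reproducible", {
  truth <- herg_binding_params("quinidine", "WT")
  d1 <- gen_block_dataset("herg", truth, sigma = 0.02, seed = 3)
  d2 <- gen_block_dataset("herg", truth, sigma = 0.02, seed = 3)
  expect_identical(d1, d2)
  d3 <- gen_block_dataset("herg", truth, sigma = 0.02, seed = 4)
  expect_false(identical(d1$fractional_block, d3$fractional_block))
})

test_that("noise-free datasets equal the simulated block exactly", {
  truth <- na_binding_params("quinidine")
  ds <- gen_block_dataset("na", truth, sigma = 0)
  ton <- ds[ds$pulse_index == 0 & ds$concentration_uM > 0, ]
  direct <- vapply(ton$concentration_uM,
                   function(D) na_tonic_block(truth, D), 0)
  expect_equal(ton$fractional_block, direct)
  # drug-free row present and exactly zero
  expect_true(any(ds$concentration_uM == 0 & ds$fractional_block == 0))
})

test_that("noisy block values are clipped to [0,1] with a reported rate", {
  truth <- na_binding_params("disopyramide")
  ds <- gen_block_dataset("na", truth, sigma = 0.4, seed = 2)
  expect_true(all(ds$fractional_block >= 0 & ds$fractional_block <= 1))
  expect_gt(attr(ds, "clip_rate"), 0)
})

test_that("generator leaves the global RNG stream untouched", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(gen_block_dataset("na", na_binding_params("quinidine"), seed = 5))
  after <- runif(1)
  expect_identical(before, after)
})
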