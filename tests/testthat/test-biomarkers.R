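test_that("trapezoid fixture has its analytic APD90 and upstroke velocity", {
  fx <- gen_fixture_waveform("trapezoid_ap", dt = 0.05)
  apd <- measure_apd90(fx, stim_time = fx$stimulus$start)
  expect_equal(as.numeric(apd), fx$truth[["APD90"]], tolerance = 0.002)
  muv <- measure_muv(fx)
  expect_equal(as.numeric(muv), fx$truth[["MUV"]], tolerance = 0.05)
})

test_that("a pure ramp has its slope as upstroke velocity", {
  tr <- list(time = seq(0, 10, by = 0.1), V = seq(-50, 50, length.out = 101))
  expect_equal(as.numeric(measure_muv(tr)), 10, tolerance = 1e-9)
})

test_that("two-Gaussian pseudo-ECG yields the closed-form tangent QT", {
  fx <- gen_fixture_waveform("gaussian_pecg", dt = 0.25)
  qt <- measure_qt(fx, stim_time = 20, qrs_skip = 100)
  expect_equal(as.numeric(qt), fx$truth[["QT"]], tolerance = 0.02)
})

test_that("dominant frequency finds the spectral peak", {
  tt <- seq(0, 4000, by = 1)
  expect_equal(dominant_frequency(sin(2 * pi * 5 * tt / 1000) + 2, dt = 1),
               5, tolerance = 0.01)
  two <- sin(2 * pi * 4 * tt / 1000) + 0.3 * sin(2 * pi * 7 * tt / 1000)
  expect_equal(dominant_frequency(two, dt = 1), 4, tolerance = 0.01)
  fx <- gen_fixture_waveform("am_sine", list(freq = 6), dt = 1)
  expect_equal(dominant_frequency(fx$phi, dt = 1), 6, tolerance = 0.01)
  expect_true(is.na(dominant_frequency(rep(1, 4000), dt = 1)))
})

test_that("re-entry lifespan is the last upstroke at any site", {
  tt <- seq(0, 3000, by = 1)
  v1 <- rep(-80, length(tt))
  v1[tt > 100 & tt < 300] <- 0
  v1[tt > 1100 & tt < 1200] <- 0   # quiescent after 1.2 s
  v2 <- rep(-80, length(tt))
  v2[tt > 500 & tt < 700] <- 0
  expect_equal(reentry_lifespan(rbind(v1, v2), tt), 1.101, tolerance = 1e-3)
  # sustained activity is capped at the window length
  v3 <- -40 + 30 * sin(2 * pi * 5 * tt / 1000)
  expect_equal(reentry_lifespan(rbind(v3), tt), 2.811, tolerance = 0.02)
})

test_that("EAD detection flags a depolarizing bump during repolarization", {
  tt <- seq(0, 500, by = 0.5)
  ap <- function(bump) {
    V <- -85 + 115 * (tt > 50) * pmax(0, 1 - (tt - 50) / 300)
    if (bump) V <- V + 15 * exp(-((tt - 250) / 10)^2)
    list(time = tt, V = V)
  }
  expect_false(detect_ead(ap(FALSE)))
  expect_true(detect_ead(ap(TRUE)))
})
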