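test_that("guarded-receptor derivatives reduce to pure unbinding without drug", {
  p <- na_binding_params("disopyramide")
  b <- c(0.1, 0.2, 0.3)
  d <- guarded_na_rhs(b, m = 0.5, h = 0.6, j = 0.7, D = 0, p = p)
  expect_equal(d, -c(p[["lA"]], p[["lI"]], p[["lR"]]) * b)
})

test_that("resting block matches the frozen-gate closed form", {
  p <- na_binding_params("quinidine")
  for (D in c(5, 17, 60)) {
    sim <- na_tonic_block(p, D, v_hold = -100)
    # closed form at frozen steady-state gates: the equilibrium of the
    # linear block system with guards g_A ~ 0, g_I, g_R
    am <- 0.32 * (-100 + 47.13) / (1 - exp(-0.1 * (-100 + 47.13)))
    bm <- 0.08 * exp(100 / 11)
    m <- am / (am + bm)
    ah <- 0.135 * exp((80 - 100) / -6.8)
    bh <- 3.56 * exp(0.079 * -100) + 3.1e5 * exp(0.35 * -100)
    h <- ah / (ah + bh)
    aj <- (-1.2714e5 * exp(0.2444 * -100) - 3.474e-5 * exp(-0.04391 * -100)) *
      (-100 + 37.78) / (1 + exp(0.311 * (-100 + 79.23)))
    bj <- 0.1212 * exp(-0.01052 * -100) / (1 + exp(-0.1378 * (-100 + 40.14)))
    j <- aj / (aj + bj)
    gA <- m^3 * h * j; gI <- 1 - h * j; gR <- (1 - m^3) * h * j
    S <- p[["kA"]] * gA / p[["lA"]] + p[["kI"]] * gI / p[["lI"]] +
      p[["kR"]] * gR / p[["lR"]]
    expect_equal(sim, S * D / (1 + S * D), tolerance = 1e-3)
  }
})

test_that("tonic dose-response is monotone and crosses 50% at the IC50", {
  for (dg in c("disopyramide", "quinidine")) {
    p <- na_binding_params(dg)
    conc <- exp(seq(log(1), log(600), length.out = 12))
    blocks <- vapply(conc, function(D) na_tonic_block(p, D), 0)
    expect_true(all(diff(blocks) > 0))
    fit <- ic50_from_curve(conc, blocks)
    target <- c(disopyramide = 36, quinidine = 17)[[dg]]
    expect_equal(fit$ic50, target, tolerance = 0.02)
  }
})

test_that("block is use dependent and stronger at faster pacing", {
  p <- na_binding_params("disopyramide")
  ud2 <- simulate_na_block(na_pulse_protocol(), p, D = 20)
  # block accumulates monotonically to a plateau over the pulse train
  expect_true(all(diff(ud2$block) > -1e-6))
  expect_gt(ud2$block[30], ud2$block[1])
  expect_lt(ud2$block[30] - ud2$block[25], 0.01)
  # availability stays a physical fraction throughout
  expect_true(all(ud2$block >= 0 & ud2$block <= 1))
  # 1 Hz version of the same pulse train develops less block
  p1hz <- clamp_protocol(rbind(c(-100, 950), c(-20, 50)), nrep = 30,
                         measure = 2)
  ud1 <- simulate_na_block(p1hz, p, D = 20)
  expect_gte(ud2$block[30], ud1$block[30])
})

test_that("fractional Na block develops on the upstroke and recovers in diastole", {
  tr <- acc_beat("SQT1", "disopyramide", 10, n_beats = 30)
  fb <- tr$fbNa
  up <- which.max(diff(tr$V))
  # block rises from the upstroke through the plateau
  expect_gt(max(fb[up:(up + 3000)]), fb[up] + 0.005)
  # and partially recovers by the end of diastole
  expect_lt(fb[length(fb)], max(fb) - 0.002)
})

test_that("pore block scaling follows the Hill form", {
  e <- c(ic50 = 14.9, nh = 1)
  expect_equal(pore_block_scale(2, 0, e), 2)
  expect_equal(pore_block_scale(2, 14.9, e), 1)
  expect_equal(pore_block_scale(1, 14.9, c(ic50 = 14.9, nh = 1)), 0.5)
  doses <- seq(0, 100, by = 5)
  g <- vapply(doses, function(D) pore_block_scale(1, D, e), 0)
  expect_true(all(diff(g) < 0))
  expect_error(pore_block_scale(1, 5, c(ic50 = -1, nh = 1)), "IC50")
})

test_that("I_Na current respects the unblocked fraction", {
  expect_equal(ina_current(0.9, 0.8, 0.7, c(0.3, 0.3, 0.4), -20, 23, 70), 0)
  free <- ina_current(0.9, 0.8, 0.7, c(0, 0, 0), -20, 23, 70)
  expect_equal(free, 23 * 0.9^3 * 0.8 * 0.7 * (-90))
  half <- ina_current(0.9, 0.8, 0.7, c(0.25, 0.25, 0), -20, 23, 70)
  expect_equal(half, free / 2)
})

test_that("quinidine-only targets are absent from the disopyramide registry", {
  pd <- pore_block_entries("disopyramide")
  pq <- pore_block_entries("quinidine")
  expect_false(any(c("I_K1", "I_NaL") %in% names(pd)))
  expect_true(all(c("I_K1", "I_NaL") %in% names(pq)))
})
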