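test_that("Markov chain is conservative for random states and voltages", {
  set.seed(42)
  for (k in 1:250) {
    V <- runif(1, -120, 80)
    cond <- sample(c("WT", "N588K"), 1)
    D <- sample(c(0, runif(1, 0, 30)), 1)
    binding <- herg_binding_params("quinidine", cond)
    s <- runif(7); s <- s / sum(s)
    A <- ikr_rate_matrix(V, ikr_rate_params(cond), binding, D)
    expect_lt(max(abs(colSums(A))), 1e-12)
    expect_lt(abs(sum(ikr_markov_rhs(s, V, ikr_rate_params(cond),
                                     binding, D))), 1e-12)
  }
})

test_that("without drug the bound states are inert", {
  s <- c(0.2, 0.2, 0.2, 0.2, 0.2, 0, 0)
  d <- ikr_markov_rhs(s, -20, ikr_rate_params("WT"),
                      herg_binding_params("disopyramide", "WT"), D = 0)
  expect_identical(d[6], 0)
  expect_identical(d[7], 0)
})

test_that("time-integrated steady state matches the null-space oracle", {
  for (case in list(list(V = -20, D = 0), list(V = 0, D = 5),
                    list(V = 20, D = 0))) {
    rates <- ikr_rate_params("WT")
    binding <- herg_binding_params("disopyramide", "WT")
    # independent route: explicit Euler integration of the rhs
    s <- c(1, 0, 0, 0, 0, 0, 0)
    A <- ikr_rate_matrix(case$V, rates, binding, case$D)
    dt <- 0.5
    for (k in 1:120000) s <- s + dt * as.numeric(A %*% s)
    oracle <- ikr_steady_state(case$V, rates, binding, case$D)
    expect_lt(max(abs(s - oracle)), 1e-6)
  }
})

test_that("only the open state conducts", {
  expect_equal(ikr_current(c(0, 0, 0, 0.3, 0.7, 0, 0), V = -88, 1, -88), 0)
  expect_equal(ikr_current(c(1, 0, 0, 0, 0, 0, 0), V = 40, 1, -88), 0)
  expect_equal(ikr_current(c(0, 0, 0, 0.5, 0, 0, 0), V = -78, 1, -88), 5)
})

test_that("heterozygote current mixes and bounds the two populations", {
  rates_wt <- ikr_rate_params("WT")
  rates_mut <- ikr_rate_params("N588K")
  # an AP-like piecewise clamp: rest, upstroke, plateau, repolarization
  segs <- rbind(c(-88, 50), c(30, 2), c(20, 150), c(-10, 80), c(-50, 60),
                c(-88, 100))
  evolve <- function(rates) {
    s <- ikr_steady_state(-88, rates)
    out <- NULL
    for (i in seq_len(nrow(segs))) {
      A <- ikr_rate_matrix(segs[i, 1], rates)
      E <- as.matrix(Matrix::expm(A * 5))
      for (k in seq_len(ceiling(segs[i, 2] / 5))) {
        s <- as.numeric(E %*% s)
        out <- rbind(out, c(segs[i, 1], s[4]))
      }
    }
    out
  }
  wt <- evolve(rates_wt); mut <- evolve(rates_mut)
  iw <- 1 * wt[, 2] * (wt[, 1] + 88)
  im <- 1 * mut[, 2] * (mut[, 1] + 88)
  het <- 0.5 * iw + 0.5 * im
  for (k in seq_along(het)) {
    expect_gte(het[k], min(iw[k], im[k]) - 1e-12)
    expect_lte(het[k], max(iw[k], im[k]) + 1e-12)
  }
  # degenerate weights reproduce the pure populations
  s1 <- c(0, 0, 0, 0.4, 0.6, 0, 0); s2 <- c(0, 0, 0, 0.1, 0.9, 0, 0)
  expect_equal(heterozygote_current(s1, s2, 0, 1, -88, w_mut = 0),
               ikr_current(s1, 0, 1, -88))
  expect_equal(heterozygote_current(s1, s2, 0, 1, -88, w_mut = 1),
               ikr_current(s2, 0, 1, -88))
  expect_error(heterozygote_current(s1, s2, 0, c(1, 2), -88), "single")
})

test_that("N588K attenuated inactivation is a gain of function", {
  ss_wt <- ikr_steady_state(20, ikr_rate_params("WT"))
  ss_mut <- ikr_steady_state(20, ikr_rate_params("N588K"))
  expect_gt(ss_mut[4], ss_wt[4])
})

test_that("drug-bound fraction grows monotonically with concentration", {
  binding <- herg_binding_params("quinidine", "N588K")
  doses <- c(0, 0.5, 1, 2, 5, 10, 30)
  bound <- vapply(doses, function(D) {
    ss <- ikr_steady_state(0, ikr_rate_params("N588K"), binding, D)
    ss[6] + ss[7]
  }, 0)
  expect_true(all(diff(bound) >= -1e-12))
  expect_gt(bound[length(bound)], 0.5)
})
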