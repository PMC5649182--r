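#' Bounded Nelder-Mead minimization
#'
#' Nelder-Mead simplex search with box bounds enforced by a smooth logistic
#' transform of the search space (the simplex moves in an unconstrained
#' space; parameters are mapped into `[lower, upper]` before each objective
#' evaluation). Multi-start: `n_starts` initial points (the supplied `x0`
#' plus Latin-ish random restarts inside the bounds) and the best objective
#' wins. Deterministic for a fixed seed.
#'
#' @param fn objective taking a numeric vector, returning a scalar.
#' @param x0 initial point (within bounds).
#' @param lower,upper finite bounds.
#' @param n_starts number of starts (>= 1).
#' @param seed RNG seed for the restarts.
#' @param maxit maximum iterations per start.
#' @param tol convergence tolerance (`reltol`).
#' @return list with `par`, `value`, `convergence` (TRUE if any start
#'   converged), `bounds`.
#' @export
nm_bounded <- function(fn, x0, lower, upper, n_starts = 3, seed = 1,
                       maxit = 2000, tol = 1e-8) {
  stopifnot(all(is.finite(lower)), all(is.finite(upper)),
            all(upper > lower), all(x0 >= lower), all(x0 <= upper))
  to_unc <- function(x) {
    p <- (x - lower) / (upper - lower)
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    log(p / (1 - p))
  }
  to_box <- function(z) lower + (upper - lower) / (1 + exp(-z))
  wrapped <- function(z) {
    v <- fn(to_box(z))
    if (!is.finite(v)) 1e12 else v
  }
  starts <- list(to_unc(x0))
  if (n_starts > 1) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    for (k in seq_len(n_starts - 1)) {
      starts[[k + 1]] <- to_unc(lower + runif(length(x0)) * (upper - lower))
    }
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  best <- NULL
  conv <- FALSE
  for (z0 in starts) {
    fit <- suppressWarnings(
      optim(z0, wrapped, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = tol)))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0) conv <- TRUE
  }
  list(par = to_box(best$par), value = best$value, convergence = conv,
       bounds = list(lower = lower, upper = upper))
}

#' Fit a Hill dose-response curve
#'
#' Least-squares fit of `block = 1 / (1 + (IC50 / D)^nH)` to fractional
#' block observations.
#'
#' @param concentrations drug concentrations (uM), at least 4 spanning the
#'   transition.
#' @param blocks fractional block in `[0, 1]`.
#' @return list with `ic50`, `nh`, `sse` and `ok` (fit-failure flag when
#'   the data are non-monotone in trend or do not span the transition).
#' @export
ic50_from_curve <- function(concentrations, blocks) {
  stopifnot(length(concentrations) == length(blocks))
  if (length(concentrations) < 4)
    stop("need >= 4 concentrations spanning the transition")
  ok <- TRUE
  r <- range(blocks)
  if (r[2] - r[1] < 0.2) ok <- FALSE   # saturated-flat data
  if (stats::cor(log(concentrations), blocks, method = "spearman") < 0.5)
    ok <- FALSE                        # not monotone in trend
  obj <- function(p) {
    pred <- 1 / (1 + (exp(p[1]) / concentrations)^exp(p[2]))
    sum((pred - blocks)^2)
  }
  # initial IC50 guess: interpolate the 50% crossing
  i <- which.min(abs(blocks - 0.5))
  fit <- optim(c(log(concentrations[i]), 0), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(ic50 = exp(fit$par[1]), nh = exp(fit$par[2]), sse = fit$value,
       ok = ok && fit$convergence == 0)
}

#' Fit hERG drug-binding rates
#'
#' Fits the open/inactivated-state binding and unbinding rate constants of
#' the drug-bound Markov I_Kr model to a fractional-block dose-response
#' dataset by bounded Nelder-Mead on log-scaled rates, minimizing the sum
#' of squared residuals of the re-simulated tail-current block.
#'
#' @param dataset data frame with columns `concentration_uM` and
#'   `fractional_block` (drug-free rows with concentration 0 are ignored by
#'   the objective, which pins block(0) = 0 by construction).
#' @param condition "WT" or "N588K" (selects the Markov kinetics).
#' @param protocol the clamp protocol (default [herg_tail_protocol()]).
#' @param x0 initial `c(kA, lA, kI, lI)`; defaults to the center of the
#'   bounds.
#' @param lower,upper bounds on `c(kA, lA, kI, lI)`.
#' @param n_starts,seed forwarded to [nm_bounded()].
#' @return list: `par` (named rates), `objective`, `convergence`, `bounds`,
#'   and `ic50` of the re-simulated dose-response.
#' @export
fit_herg_binding <- function(dataset, condition = "WT",
                             protocol = herg_tail_protocol(),
                             x0 = NULL,
                             lower = c(1e-6, 1e-5, 1e-6, 1e-5),
                             upper = c(0.1, 0.05, 0.1, 0.05),
                             n_starts = 3, seed = 1) {
  d <- dataset[dataset$concentration_uM > 0, ]
  conc <- d$concentration_uM
  obs <- d$fractional_block
  llo <- log10(lower); lup <- log10(upper)
  if (is.null(x0)) x0 <- 10^((llo + lup) / 2)
  fn <- function(p) {
    b <- c(p[1], p[2], p[3], p[4])
    pred <- vapply(conc, function(D)
      simulate_fractional_block(protocol, condition, b, D), 0)
    sum((pred - obs)^2)
  }
  fit <- nm_bounded(function(lp) fn(10^lp), log10(x0), llo, lup,
                    n_starts = n_starts, seed = seed, maxit = 400,
                    tol = 1e-10)
  par <- 10^fit$par
  names(par) <- c("kA", "lA", "kI", "lI")
  # re-simulate and refit the Hill curve for the achieved IC50
  sim <- vapply(conc, function(D)
    simulate_fractional_block(protocol, condition, par, D), 0)
  hill <- ic50_from_curve(conc, sim)
  list(par = par, objective = fit$value, convergence = fit$convergence,
       bounds = fit$bounds, ic50 = hill$ic50, nh = hill$nh)
}

#' Simulated Na-channel block under voltage clamp
#'
#' Integrates the guarded-receptor model with Luo-Rudy gate dynamics under
#' a piecewise-constant clamp protocol.
#'
#' @param protocol a [clamp_protocol()]; `measure` names the test-pulse
#'   segment.
#' @param binding numeric `c(kA, kI, kR, lA, lI, lR)`.
#' @param D concentration (uM).
#' @param dt step (ms).
#' @return data frame: one row per repetition with `pulse`, `bA`, `bI`,
#'   `bR`, `block` (peak block during the test pulse = 1 - min availability).
#' @export
simulate_na_block <- function(protocol, binding, D, dt = 0.05) {
  segs <- protocol$segments
  res <- .cpp_na_clamp(segs, protocol$nrep, as.numeric(binding), D, dt)
  rec <- res$pulse
  data.frame(pulse = seq_len(nrow(rec)), bA = rec[, 1], bI = rec[, 2],
             bR = rec[, 3], block = 1 - rec[, 4])
}

#' Equilibrium tonic block of Na channels
#'
#' Holds the guarded-receptor model at a fixed (hyperpolarized) potential
#' with frozen steady-state gates until the block pools equilibrate, and
#' returns the total fractional block.
#'
#' @param binding numeric `c(kA, kI, kR, lA, lI, lR)`.
#' @param D concentration (uM).
#' @param v_hold holding potential (mV).
#' @param t_hold equilibration time (ms).
#' @export
na_tonic_block <- function(binding, D, v_hold = -100, t_hold = 60000) {
  proto <- clamp_protocol(rbind(c(v_hold, t_hold)), nrep = 1, measure = 1)
  res <- .cpp_na_clamp(proto$segments, 1, as.numeric(binding), D, 0.5)
  sum(res$final[1:3])
}

#' Fit guarded-receptor Na binding rates
#'
#' Fits the six binding/unbinding rate constants to a combined dataset of
#' tonic-block dose-response points (pulse_index 0) and a 30-pulse
#' use-dependence series, by bounded Nelder-Mead on log-scaled rates.
#'
#' @param dataset data frame with columns `concentration_uM`,
#'   `pulse_index` (0 = tonic equilibrium) and `fractional_block`.
#' @param x0,lower,upper initial point and bounds for
#'   `c(kA, kI, kR, lA, lI, lR)`.
#' @param protocol use-dependence protocol (default [na_pulse_protocol()]).
#' @param n_starts,seed forwarded to [nm_bounded()].
#' @return list: `par`, `objective`, `convergence`, `bounds`, and
#'   `tonic_ic50` from Hill-fitting the re-simulated equilibrium block.
#' @export
fit_na_binding <- function(dataset, x0 = NULL,
                           lower = c(1e-5, 1e-6, 1e-7, 1e-5, 1e-5, 1e-5),
                           upper = c(0.1, 0.01, 0.01, 0.1, 0.1, 0.1),
                           protocol = na_pulse_protocol(),
                           n_starts = 3, seed = 1) {
  ton <- dataset[dataset$pulse_index == 0, ]
  use <- dataset[dataset$pulse_index > 0, ]
  llo <- log10(lower); lup <- log10(upper)
  if (is.null(x0)) x0 <- 10^((llo + lup) / 2)
  fn <- function(b) {
    sse <- 0
    if (nrow(ton)) {
      pred <- vapply(ton$concentration_uM, function(D)
        na_tonic_block(b, D), 0)
      sse <- sse + sum((pred - ton$fractional_block)^2)
    }
    if (nrow(use)) {
      for (D in unique(use$concentration_uM)) {
        sub <- use[use$concentration_uM == D, ]
        sim <- simulate_na_block(protocol, b, D)
        pred <- sim$block[sub$pulse_index]
        sse <- sse + sum((pred - sub$fractional_block)^2)
      }
    }
    sse
  }
  fit <- nm_bounded(function(lp) fn(10^lp), log10(x0), llo, lup,
                    n_starts = n_starts, seed = seed, maxit = 600,
                    tol = 1e-10)
  par <- 10^fit$par
  names(par) <- c("kA", "kI", "kR", "lA", "lI", "lR")
  conc <- exp(seq(log(2), log(600), length.out = 8))
  blocks <- vapply(conc, function(D) na_tonic_block(par, D), 0)
  hill <- ic50_from_curve(conc, blocks)
  list(par = par, objective = fit$value, convergence = fit$convergence,
       bounds = fit$bounds, tonic_ic50 = hill$ic50)
}

#' Fit drug binding rates to a block dataset
#'
#' Dispatcher over the two binding-model families: `model = "herg"`
#' (open/inactivated-state Markov binding, tail-current dose response) or
#' `model = "na"` (guarded-receptor tonic + use-dependent block).
#'
#' @param dataset tidy data frame (see the specific fitters).
#' @param model "herg" or "na".
#' @param ... forwarded to [fit_herg_binding()] / [fit_na_binding()].
#' @export
fit_binding_rates <- function(dataset, model = c("herg", "na"), ...) {
  model <- match.arg(model)
  if (model == "herg") fit_herg_binding(dataset, ...) else
    fit_na_binding(dataset, ...)
}
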