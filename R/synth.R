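#' Synthetic fractional-block dataset
#'
#' Generates the voltage-clamp block observations that the calibration
#' module fits: a tail-current dose-response (hERG family) or a tonic +
#' use-dependence dataset (Na family), simulated from known "true" binding
#' parameters with additive Gaussian noise on the fractional block
#' (sigma = 0.02 by default, comparable to published scatter), clipped to
#' [0, 1] with the clipping rate reported as an attribute.
#'
#' @param family "herg" or "na".
#' @param truth true binding parameter vector (`c(kA, lA, kI, lI)` for
#'   hERG, `c(kA, kI, kR, lA, lI, lR)` for Na).
#' @param condition Markov kinetics for the hERG family.
#' @param concentrations concentrations (uM); defaults to 9 log-spaced
#'   points around the family's transition.
#' @param pulses pulse indices recorded for the Na use-dependence series
#'   (ignored for hERG).
#' @param sigma noise s.d. on fractional block.
#' @param seed RNG seed (datasets are reproducible).
#' @return tidy data frame with columns `condition`, `drug`,
#'   `concentration_uM`, `pulse_index` (0 = equilibrium/tail measurement),
#'   `fractional_block`.
#' @export
gen_block_dataset <- function(family = c("herg", "na"), truth,
                              condition = "WT", concentrations = NULL,
                              pulses = c(1, 2, 3, 5, 10, 20, 30),
                              sigma = 0.02, seed = 1, drug = "drug") {
  family <- match.arg(family)
  if (sigma < 0) stop("sigma must be >= 0")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  if (family == "herg") {
    if (is.null(concentrations)) {
      # center the sweep on the model's own half-block point
      probe <- vapply(10^seq(-2, 3, by = 0.5), function(D)
        simulate_fractional_block(herg_tail_protocol(), condition, truth, D), 0)
      ic <- 10^seq(-2, 3, by = 0.5)[which.min(abs(probe - 0.5))]
      concentrations <- exp(seq(log(ic / 30), log(ic * 30), length.out = 9))
    }
    block <- vapply(concentrations, function(D)
      simulate_fractional_block(herg_tail_protocol(), condition, truth, D), 0)
    out <- data.frame(condition = condition, drug = drug,
                      concentration_uM = c(0, concentrations),
                      pulse_index = 0,
                      fractional_block = c(0, block))
  } else {
    if (is.null(concentrations))
      concentrations <- exp(seq(log(2), log(600), length.out = 8))
    ton <- vapply(concentrations, function(D) na_tonic_block(truth, D), 0)
    out <- data.frame(condition = condition, drug = drug,
                      concentration_uM = c(0, concentrations),
                      pulse_index = 0,
                      fractional_block = c(0, ton))
    ud_conc <- concentrations[c(3, 5)]
    for (D in ud_conc) {
      sim <- simulate_na_block(na_pulse_protocol(), truth, D)
      out <- rbind(out, data.frame(condition = condition, drug = drug,
                                   concentration_uM = D,
                                   pulse_index = pulses,
                                   fractional_block = sim$block[pulses]))
    }
  }
  raw <- out$fractional_block + rnorm(nrow(out), 0, sigma)
  clipped <- mean(raw < 0 | raw > 1)
  out$fractional_block <- pmin(pmax(raw, 0), 1)
  attr(out, "clip_rate") <- clipped
  attr(out, "seed") <- seed
  out
}

#' Analytic fixture waveforms with known biomarkers
#'
#' Parameterized waveforms whose ground-truth biomarkers are computable in
#' closed form, for unit-testing the extraction routines:
#' \describe{
#'   \item{`trapezoid_ap`}{an AP-like trapezoid: instantaneous-ish upstroke,
#'     flat plateau, linear fall; APD90 known analytically.}
#'   \item{`gaussian_pecg`}{a QRS + T-wave pair of Gaussians; the tangent
#'     at the steepest descending point of the T wave has a closed-form
#'     baseline intersection, giving the true QT.}
#'   \item{`am_sine`}{amplitude-modulated sinusoid with known carrier
#'     frequency (the dominant frequency).}
#' }
#'
#' @param kind one of "trapezoid_ap", "gaussian_pecg", "am_sine".
#' @param params named list overriding the waveform defaults.
#' @param dt sample interval (ms).
#' @return list with `time`, the waveform (`V` or `phi`), and `truth`
#'   (named ground-truth biomarker values).
#' @export
gen_fixture_waveform <- function(kind = c("trapezoid_ap", "gaussian_pecg",
                                          "am_sine"),
                                 params = list(), dt = 0.1) {
  kind <- match.arg(kind)
  if (kind == "trapezoid_ap") {
    p <- modifyList(list(v_rest = -85, v_peak = 35, t_up = 50, rise = 1,
                         plateau = 200, fall = 50, t_end = 500), params)
    tt <- seq(0, p$t_end, by = dt)
    V <- rep(p$v_rest, length(tt))
    up <- tt >= p$t_up & tt < p$t_up + p$rise
    V[up] <- p$v_rest + (p$v_peak - p$v_rest) * (tt[up] - p$t_up) / p$rise
    pl <- tt >= p$t_up + p$rise & tt < p$t_up + p$rise + p$plateau
    V[pl] <- p$v_peak
    fa <- tt >= p$t_up + p$rise + p$plateau &
      tt < p$t_up + p$rise + p$plateau + p$fall
    V[fa] <- p$v_peak - (p$v_peak - p$v_rest) *
      (tt[fa] - p$t_up - p$rise - p$plateau) / p$fall
    # APD90 truth: from the upstroke (constant max dV/dt over the linear
    # rise, first sample at t_up) to the 90% crossing on the linear fall
    truth <- c(APD90 = p$rise + p$plateau + 0.9 * p$fall,
               MUV = (p$v_peak - p$v_rest) / p$rise)
    list(time = tt, V = V, truth = truth,
         stimulus = list(start = p$t_up - 5))
  } else if (kind == "gaussian_pecg") {
    p <- modifyList(list(qrs_t = 50, qrs_amp = 1, qrs_sd = 8,
                         t_t = 300, t_amp = 0.5, t_sd = 25,
                         t_end = 600), params)
    tt <- seq(0, p$t_end, by = dt)
    phi <- p$qrs_amp * exp(-(tt - p$qrs_t)^2 / (2 * p$qrs_sd^2)) +
      p$t_amp * exp(-(tt - p$t_t)^2 / (2 * p$t_sd^2))
    # terminal-limb tangent on a Gaussian T wave: the limb starts at the
    # one-third-amplitude point u0 = sqrt(2 log 3) (in sd units); the
    # tangent intersection u + 1/u is increasing there, so the steepest
    # terminal point is u0 and the intersection sits at mu + (u0 + 1/u0)*sd
    u0 <- sqrt(2 * log(3))
    t_tend <- p$t_t + (u0 + 1 / u0) * p$t_sd
    # QRS onset by the 5%-of-peak deflection convention used by the QT
    # measurement: the Gaussian QRS crosses 5% of its amplitude at
    # mu - sd * sqrt(2 log 20)
    t_on <- p$qrs_t - p$qrs_sd * sqrt(2 * log(20))
    truth <- c(QT = t_tend - t_on, t_end = t_tend)
    list(time = tt, phi = phi, truth = truth)
  } else {
    p <- modifyList(list(freq = 6, mod_freq = 0.5, t_end = 4000,
                         offset = 1), params)
    tt <- seq(0, p$t_end, by = dt)
    x <- (1 + 0.3 * sin(2 * pi * p$mod_freq * tt / 1000)) *
      sin(2 * pi * p$freq * tt / 1000) + p$offset
    list(time = tt, phi = x, truth = c(DF = p$freq))
  }
}
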