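# Seeded synthetic experiments. Two presets mirror the bench (silicone
# membrane) and ex vivo (enucleated rabbit eye) filling set-ups; a third
# generator produces clinical-style bleb observations for the grading chart.

#' Configuration of a synthetic filling experiment
#'
#' Bundles the physical system, sampling protocol and noise model for one
#' simulated experiment. Height noise is multiplicative Gaussian (a relative
#' photographic measurement error); pressure noise is additive Gaussian
#' (a transducer error, in Pa).
#'
#' @param system a [flow_system()] object.
#' @param membrane a [membrane_properties()] object.
#' @param h0 initial height, m (>= 0).
#' @param duration recording duration, s (> 0).
#' @param sample_rate sampling frequency, Hz (> 0).
#' @param noise_h_rel relative standard deviation of height noise; default 0.02.
#' @param noise_p_abs standard deviation of additive pressure noise, Pa;
#'   default 2% of the equilibrium pressure (0 when `q_in` = 0).
#' @param seed integer RNG seed, stored verbatim.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(system, membrane, h0 = 0, duration, sample_rate,
                              noise_h_rel = 0.02, noise_p_abs = NULL, seed = 1L) {
  stopifnot(inherits(system, "flow_system"), inherits(membrane, "membrane_properties"),
            is.numeric(h0), h0 >= 0,
            is.numeric(duration), duration > 0,
            is.numeric(sample_rate), sample_rate > 0,
            is.numeric(noise_h_rel), noise_h_rel >= 0)
  if (is.null(noise_p_abs)) {
    noise_p_abs <- if (system$q_in > 0) 0.02 * system$k * system$q_in else 0
  }
  stopifnot(is.numeric(noise_p_abs), noise_p_abs >= 0)
  structure(
    list(system = system, membrane = membrane, h0 = h0, duration = duration,
         sample_rate = sample_rate, noise_h_rel = noise_h_rel,
         noise_p_abs = noise_p_abs, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Synthetic filling experiment:\n")
  print(x$system)
  print(x$membrane)
  cat("  h0 =", format(m_to_mm(x$h0), digits = 4), "mm;",
      "duration =", x$duration, "s @", x$sample_rate, "Hz;",
      "noise: H", paste0(100 * x$noise_h_rel, "%"), "rel,",
      "P", format(x$noise_p_abs, digits = 3), "Pa;",
      "seed =", x$seed, "\n")
  invisible(x)
}

#' Bench (silicone membrane) experiment preset
#'
#' A circular silicone sheet (thickness 0.8 mm, Young's modulus 1.24 MPa)
#' clamped over a 20 mm radius hole, inflated from empty through a fixed
#' outflow resistance of 2.6e10 Pa s m^-3, sampled at 1.875 Hz. Inflow
#' rates of 5000, 8000 and 10000 ul/min are the standard operating points.
#'
#' @param q_in_ul_min inflow rate in ul/min (> 0); default 5000.
#' @param seed integer RNG seed.
#' @param duration recording duration, s; default 180 (several relaxation
#'   times at every standard inflow rate).
#' @param noise_h_rel,noise_p_abs noise levels, as in [experiment_config()].
#' @return an `experiment_config`.
#' @export
preset_in_vitro <- function(q_in_ul_min = 5000, seed = 1L, duration = 180,
                            noise_h_rel = 0.02, noise_p_abs = NULL) {
  if (!is.numeric(q_in_ul_min) || q_in_ul_min <= 0) {
    stop("inflow rate must be positive")
  }
  experiment_config(
    system = flow_system(ulmin_to_m3s(q_in_ul_min), k = 2.6e10, r = 20e-3),
    membrane = membrane_properties(1.24e6, 0.8e-3),
    h0 = 0, duration = duration, sample_rate = 1.875,
    noise_h_rel = noise_h_rel, noise_p_abs = noise_p_abs, seed = seed
  )
}

#' Ex vivo (enucleated eye) experiment preset
#'
#' Conjunctival bleb raised on an enucleated eye: stiff thin membrane
#' (E = 28 MPa, T = 0.1 mm), slow physiological inflow (5 ul/min), sampled
#' at 1 Hz for up to 4 hours. Unlike the bench preset the recording starts
#' with a small volume of fluid already in the pocket (surgical closure
#' cannot be performed on an empty bleb), so `h0` defaults to 15% of the
#' equilibrium height. The planform radius (4 mm) and outflow resistance
#' (1.6e13 Pa s m^-3, placing the equilibrium pressure at 10 mmHg) are
#' synthetic conventions at human scale: the tissue drainage resistance is
#' not directly controllable in this preparation.
#'
#' @param seed integer RNG seed.
#' @param duration recording duration, s; default 1800, must not exceed
#'   14400 (4 h).
#' @param h0_frac initial height as a fraction of equilibrium height;
#'   default 0.15.
#' @param noise_h_rel,noise_p_abs noise levels, as in [experiment_config()].
#' @return an `experiment_config`.
#' @export
preset_ex_vivo <- function(seed = 1L, duration = 1800, h0_frac = 0.15,
                           noise_h_rel = 0.02, noise_p_abs = NULL) {
  if (duration > 14400) stop("ex vivo recordings run for at most 4 hours (14400 s)")
  system <- flow_system(ulmin_to_m3s(5), k = 1.6e13, r = 4e-3)
  membrane <- membrane_properties(28e6, 0.1e-3)
  h0 <- h0_frac * characteristic_scales(system, membrane)$h_max
  experiment_config(
    system = system, membrane = membrane, h0 = h0,
    duration = duration, sample_rate = 1,
    noise_h_rel = noise_h_rel, noise_p_abs = noise_p_abs, seed = seed
  )
}

#' Generate a noisy sampled trajectory from an experiment configuration
#'
#' Simulates the filling ODE on the configured sampling grid and applies
#' seeded measurement noise: multiplicative Gaussian on height, additive
#' Gaussian on pressure. Heights are clipped at zero; the number of clipped
#' samples is recorded in the `n_clipped` attribute. Deterministic given
#' the seed.
#'
#' @param config an [experiment_config()].
#' @return a tibble with columns `time_s`, `height_m`, `pressure_pa`;
#'   attributes `config` (the generating configuration) and `n_clipped`.
#' @export
generate_timeseries <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  times <- seq(0, config$duration, by = 1 / config$sample_rate)
  sim <- simulate_bleb(config$system, config$membrane, config$h0, times)
  n <- nrow(sim)
  out <- withr::with_seed(config$seed, {
    h <- sim$height_m * (1 + stats::rnorm(n, 0, config$noise_h_rel))
    p <- sim$pressure_pa + stats::rnorm(n, 0, config$noise_p_abs)
    list(h = h, p = p)
  })
  n_clipped <- sum(out$h < 0)
  res <- tibble::tibble(
    time_s = sim$time_s,
    height_m = pmax(out$h, 0),
    pressure_pa = out$p
  )
  attr(res, "config") <- config
  attr(res, "n_clipped") <- n_clipped
  res
}

#' Generate synthetic clinical bleb observations
#'
#' Samples bleb geometries uniformly over the clinically observed ranges
#' (effective radius 1-8 mm, height 0.2-4 mm) and assigns each an IOP from
#' the purse-law chart pressure plus Gaussian measurement noise. Glaucoma
#' drops are assigned preferentially to blebs whose model pressure exceeds
#' the green band (mirroring the clinical observation that medicated
#' patients hold an acceptable IOP despite adverse bleb geometry); a small
#' fraction is flagged as leaking.
#'
#' @param n number of observations (>= 1).
#' @param calib a [calibrate_chart()] calibration.
#' @param seed integer RNG seed.
#' @param thresholds a [zone_thresholds()] object; default [zone_thresholds()].
#' @param iop_noise_mmhg SD of IOP measurement noise in mmHg; default 1.
#' @param leak_fraction expected fraction of leaking blebs; default 0.05.
#' @return a tibble with columns `id`, `radius_mm`, `height_mm`,
#'   `iop_mmHg`, `n_drop_types` (0-4), `leaking` (logical).
#' @export
generate_clinical_blebs <- function(n, calib, seed = 1L,
                                    thresholds = zone_thresholds(),
                                    iop_noise_mmhg = 1, leak_fraction = 0.05) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive integer")
  }
  stopifnot(inherits(calib, "chart_calibration"), inherits(thresholds, "zone_thresholds"))
  n <- as.integer(n)
  withr::with_seed(as.integer(seed), {
    radius <- stats::runif(n, 1, 8)
    height <- stats::runif(n, 0.2, 4)
    p_model <- chart_pressure(radius, height, calib)
    iop <- pmax(p_model + stats::rnorm(n, 0, iop_noise_mmhg), 0)
    p_drops <- ifelse(p_model > thresholds$green_high, 0.8, 0.15)
    on_drops <- stats::rbinom(n, 1, p_drops) == 1
    n_drops <- ifelse(on_drops, 1L + stats::rbinom(n, 3, 0.3), 0L)
    leaking <- stats::runif(n) < leak_fraction
    tibble::tibble(
      id = seq_len(n),
      radius_mm = radius,
      height_mm = height,
      iop_mmHg = iop,
      n_drop_types = as.integer(n_drops),
      leaking = leaking
    )
  })
}
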