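# Purse-law algebra: spherical-cap volume, cubic pressure law, resistive
# outflow, characteristic scales, and the constant-inflow filling ODE.

#' Spherical-cap volume of a bleb
#'
#' The bleb is a shallow spherical cap over a circular planform of radius
#' `r`: V = c1 * pi * r^2 * h, with c1 ~ 1/2.
#'
#' @param r planform radius, m (> 0).
#' @param h cap height, m (>= 0); may be a vector.
#' @param c1 cap volume constant; default 0.5.
#' @return volume in m^3, same length as `h`.
#' @examples
#' bleb_volume(4e-3, 1e-3)  # ~2.513e-8 m^3 = 25.13 ul
#' @export
bleb_volume <- function(r, h, c1 = 0.5) {
  if (!is.numeric(r) || any(r <= 0)) stop("planform radius `r` must be positive")
  if (any(h < 0)) stop("height `h` must be non-negative")
  c1 * pi * r^2 * h
}

#' Bleb pressure from height (the purse law)
#'
#' Static balance of a pressurised clamped elastic sheet gives the cubic
#' law P = c2 * E * T * h^3 / r^4: pressure rises steeply with height
#' (power 3) and falls even more steeply with extent (power 4).
#'
#' @param h bleb height, m (>= 0); may be a vector.
#' @param r planform radius, m (> 0).
#' @param membrane a [membrane_properties()] object.
#' @return pressure in Pa.
#' @export
pressure_from_height <- function(h, r, membrane) {
  stopifnot(inherits(membrane, "membrane_properties"))
  if (!is.numeric(r) || any(r <= 0)) stop("planform radius `r` must be positive")
  if (any(h < 0)) stop("height `h` must be non-negative")
  membrane$c2 * membrane$youngs_modulus * membrane$thickness * h^3 / r^4
}

#' Bleb height from pressure (inverse purse law)
#'
#' Exact algebraic inverse of [pressure_from_height()]:
#' h = (P * r^4 / (c2 * E * T))^(1/3).
#'
#' @param p pressure, Pa (>= 0); may be a vector.
#' @inheritParams pressure_from_height
#' @return height in m.
#' @export
height_from_pressure <- function(p, r, membrane) {
  stopifnot(inherits(membrane, "membrane_properties"))
  if (!is.numeric(r) || any(r <= 0)) stop("planform radius `r` must be positive")
  if (any(p < 0)) stop("pressure `p` must be non-negative")
  (p * r^4 / (membrane$c2 * membrane$youngs_modulus * membrane$thickness))^(1 / 3)
}

#' Resistive outflow from the bleb
#'
#' Viscous drainage at low Reynolds number: Q_out = P / k.
#'
#' @param p bleb pressure, Pa; may be a vector.
#' @param k outflow resistance, Pa s m^-3 (> 0).
#' @return volumetric outflow in m^3/s.
#' @export
outflow <- function(p, k) {
  if (!is.numeric(k) || any(k <= 0)) stop("outflow resistance `k` must be positive")
  p / k
}

#' Characteristic scales of the filling dynamics
#'
#' Balancing inflow against resistive outflow at the purse-law pressure
#' yields the equilibrium height, pressure, and the relaxation time:
#' \deqn{H_{max} = (Q_{in} K r^4 / (c_2 E T))^{1/3}, \quad
#'       P_{max} = K Q_{in}, \quad
#'       T_c = c_1 \pi r^2 H_{max} / Q_{in}.}
#' These nondimensionalise every trajectory onto a single universal curve.
#'
#' @param system a [flow_system()] object with `q_in > 0`.
#' @param membrane a [membrane_properties()] object.
#' @return an object of class `bleb_scales`: list with `t_c` (s),
#'   `h_max` (m), `p_max` (Pa).
#' @examples
#' sys <- flow_system(ulmin_to_m3s(5000), 2.6e10, 20e-3)
#' mem <- membrane_properties(1.24e6, 0.8e-3)
#' characteristic_scales(sys, mem)  # P_max ~ 2167 Pa, H_max ~ 4.23 mm
#' @export
characteristic_scales <- function(system, membrane) {
  stopifnot(inherits(system, "flow_system"), inherits(membrane, "membrane_properties"))
  if (system$q_in <= 0) {
    stop("degenerate flow system: q_in = 0 has no finite equilibrium scales")
  }
  et <- membrane$c2 * membrane$youngs_modulus * membrane$thickness
  h_max <- (system$q_in * system$k * system$r^4 / et)^(1 / 3)
  p_max <- system$k * system$q_in
  t_c <- membrane$c1 * pi * system$r^2 * h_max / system$q_in
  structure(list(t_c = t_c, h_max = h_max, p_max = p_max), class = "bleb_scales")
}

#' Estimated time to fill a bleb
#'
#' Ratio of the approximate final bleb volume (c1 * pi * r^2 * h_max, by
#' which time about 82% of the equilibrium height is reached) to the
#' filling rate. Identical to the `t_c` of [characteristic_scales()] when
#' `h_max` is the equilibrium height.
#'
#' @param r planform radius, m.
#' @param h_max final (equilibrium) bleb height, m.
#' @param q_in inflow rate, m^3/s (> 0).
#' @param c1 cap volume constant; default 0.5.
#' @return fill time in seconds.
#' @examples
#' # post-operative human bleb: R ~ 4 mm, H_max ~ 1 mm, Q_in ~ 1 ul/min
#' fill_time_estimate(4e-3, 1e-3, ulmin_to_m3s(1))  # ~1508 s (~25 min)
#' @export
fill_time_estimate <- function(r, h_max, q_in, c1 = 0.5) {
  stopifnot(is.numeric(r), r > 0, is.numeric(h_max), h_max >= 0)
  if (!is.numeric(q_in) || q_in <= 0) {
    stop("degenerate input: fill time requires q_in > 0")
  }
  c1 * pi * r^2 * h_max / q_in
}

#' Prefactors of the equilibrium scaling relations
#'
#' Eliminating K and Q_in from the characteristic scales in favour of
#' P_max expresses both equilibrium ratios as power laws in the loading
#' parameter P_max * r / (E T):
#' \deqn{H_{max}/r = c_2^{-1/3} \, (P_{max} r / (E T))^{1/3}}
#' \deqn{Q_{in} T_c / (\pi r^3) = c_1 c_2^{-1/3} \, (P_{max} r / (E T))^{1/3}}
#' With the defaults c1 = 0.5, c2 = 4.63 the prefactors are 0.600 and
#' 0.300.
#'
#' @param c1 cap volume constant (> 0); default 0.5.
#' @param c2 pressure-law constant (> 0); default 4.63.
#' @return named numeric vector `c(prefactor_h = c2^(-1/3),
#'   prefactor_t = c1 * c2^(-1/3))`.
#' @export
scaling_prefactors <- function(c1 = 0.5, c2 = 4.63) {
  stopifnot(is.numeric(c1), c1 > 0, is.numeric(c2), c2 > 0)
  pf_h <- c2^(-1 / 3)
  c(prefactor_h = pf_h, prefactor_t = c1 * pf_h)
}

#' Simulate bleb filling by numerical ODE integration
#'
#' Integrates the mass balance
#' \deqn{c_1 \pi r^2 \, dH/dt = Q_{in} - c_2 E T H^3 / (K r^4)}
#' from `h0` on the supplied time grid with an adaptive solver
#' (`deSolve::ode`, lsoda, relative tolerance 1e-9). For `h0 < H_max` the
#' trajectory rises monotonically towards `H_max`; for `h0 > H_max`
#' (overfilled bleb) it decays towards it; `h0 = H_max` is the fixed point.
#'
#' @param system a [flow_system()] object.
#' @param membrane a [membrane_properties()] object.
#' @param h0 initial height, m (>= 0).
#' @param times strictly increasing time grid starting at 0, s.
#' @return a tibble with columns `time_s`, `height_m`, `pressure_pa`.
#' @examples
#' sys <- flow_system(ulmin_to_m3s(5000), 2.6e10, 20e-3)
#' mem <- membrane_properties(1.24e6, 0.8e-3)
#' sim <- simulate_bleb(sys, mem, h0 = 0, times = seq(0, 180, by = 1 / 1.875))
#' @export
simulate_bleb <- function(system, membrane, h0 = 0, times) {
  stopifnot(inherits(system, "flow_system"), inherits(membrane, "membrane_properties"))
  if (!is.numeric(h0) || length(h0) != 1L || h0 < 0) {
    stop("initial height `h0` must be a non-negative scalar")
  }
  if (length(times) < 2L || times[1] != 0 || any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing from 0")
  }
  area <- membrane$c1 * pi * system$r^2
  stiff <- membrane$c2 * membrane$youngs_modulus * membrane$thickness /
    (system$k * system$r^4)
  rhs <- function(t, y, parms) {
    list((system$q_in - stiff * y[1]^3) / area)
  }
  h_ref <- if (system$q_in > 0) {
    max(h0, characteristic_scales(system, membrane)$h_max)
  } else {
    max(h0, 1e-6)
  }
  sol <- deSolve::ode(
    y = c(h = h0), times = times, func = rhs, parms = NULL,
    method = "lsoda", rtol = 1e-9, atol = h_ref * 1e-12
  )
  h <- pmax(as.numeric(sol[, "h"]), 0)
  tibble::tibble(
    time_s = as.numeric(sol[, "time"]),
    height_m = h,
    pressure_pa = pressure_from_height(h, system$r, membrane)
  )
}

#' Collapse a dimensional trajectory onto the universal curve
#'
#' Pure rescaling by the characteristic scales: tau = t / T_c,
#' hhat = H / H_max, p_ratio = P / P_max. Trajectories at any inflow rate
#' collapse onto the single curve [hhat_of_tau()].
#'
#' @param series a tibble with columns `time_s`, `height_m`, `pressure_pa`
#'   (as returned by [simulate_bleb()] or [read_timeseries()]).
#' @param scales a `bleb_scales` object (or list with positive `t_c`,
#'   `h_max`, `p_max`).
#' @return a tibble with columns `tau`, `hhat`, `p_ratio`.
#' @export
collapse_series <- function(series, scales) {
  need <- c("time_s", "height_m", "pressure_pa")
  if (!all(need %in% names(series))) {
    stop("`series` must have columns time_s, height_m, pressure_pa")
  }
  if (any(c(scales$t_c, scales$h_max, scales$p_max) <= 0)) {
    stop("all characteristic scales must be strictly positive")
  }
  tibble::tibble(
    tau = series$time_s / scales$t_c,
    hhat = series$height_m / scales$h_max,
    p_ratio = series$pressure_pa / scales$p_max
  )
}
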