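#' Elastic membrane properties of the conjunctival sheet
#'
#' The bleb wall is modelled as a clamped thin elastic sheet of Young's
#' modulus `E` and thickness `T`. Two dimensionless constants close the
#' geometry: `c1` relates cap volume to planform area and height
#' (V = c1 * pi * R^2 * H, spherical-cap value ~ 1/2) and `c2` sets the
#' stiffness of the pressure law P = c2 * E * T * H^3 / R^4.
#'
#' @param youngs_modulus Young's modulus E of the sheet, Pa.
#' @param thickness sheet thickness T, m.
#' @param c1 cap volume constant, dimensionless; default 0.5.
#' @param c2 pressure-law constant, dimensionless; default 4.63.
#' @return an object of class `membrane_properties`.
#' @examples
#' membrane_properties(1.24e6, 0.8e-3)  # bench silicone sheet
#' membrane_properties(28e6, 0.1e-3)    # ex vivo conjunctiva
#' @export
membrane_properties <- function(youngs_modulus, thickness, c1 = 0.5, c2 = 4.63) {
  stopifnot(
    is.numeric(youngs_modulus), length(youngs_modulus) == 1L, youngs_modulus > 0,
    is.numeric(thickness), length(thickness) == 1L, thickness > 0,
    is.numeric(c1), length(c1) == 1L, c1 > 0,
    is.numeric(c2), length(c2) == 1L, c2 > 0
  )
  structure(
    list(youngs_modulus = youngs_modulus, thickness = thickness, c1 = c1, c2 = c2),
    class = "membrane_properties"
  )
}

#' @export
print.membrane_properties <- function(x, ...) {
  cat("Membrane: E =", format(x$youngs_modulus, digits = 4), "Pa,",
      "T =", format(x$thickness, digits = 4), "m,",
      "C1 =", x$c1, ", C2 =", x$c2, "\n")
  invisible(x)
}

#' Flow system feeding and draining the bleb
#'
#' A constant aqueous inflow `q_in` enters the pocket; the outflow is
#' resistive, Q_out = P / k. Together with the planform radius `r` this
#' fully determines the filling dynamics.
#'
#' @param q_in inflow rate, m^3/s (>= 0; 0 is a decay-only regime).
#' @param k outflow resistance, Pa s m^-3 (> 0).
#' @param r planform radius of the bleb, m (> 0).
#' @return an object of class `flow_system`.
#' @examples
#' flow_system(ulmin_to_m3s(5000), 2.6e10, 20e-3)  # bench configuration
#' @export
flow_system <- function(q_in, k, r) {
  stopifnot(
    is.numeric(q_in), length(q_in) == 1L, q_in >= 0,
    is.numeric(k), length(k) == 1L, k > 0,
    is.numeric(r), length(r) == 1L, r > 0
  )
  structure(list(q_in = q_in, k = k, r = r), class = "flow_system")
}

#' @export
print.flow_system <- function(x, ...) {
  cat("Flow system: Q_in =", format(m3s_to_ulmin(x$q_in), digits = 4), "ul/min,",
      "K =", format(x$k, digits = 4), "Pa.s.m^-3,",
      "R =", format(m_to_mm(x$r), digits = 4), "mm\n")
  invisible(x)
}

#' @export
print.bleb_scales <- function(x, ...) {
  cat("Characteristic scales:\n",
      "  T_c   =", format(x$t_c, digits = 6), "s\n",
      "  H_max =", format(m_to_mm(x$h_max), digits = 6), "mm\n",
      "  P_max =", format(x$p_max, digits = 6), "Pa (",
      format(pa_to_mmhg(x$p_max), digits = 4), "mmHg )\n")
  invisible(x)
}
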