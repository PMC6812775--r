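# All internal computation is SI (m, s, Pa, m^3/s). Conversions live only at
# I/O boundaries: clinical pressures arrive in mmHg, lab flow rates in ul/min,
# bleb dimensions in mm.

.MMHG_PA <- 133.322       # Pa per mmHg
.ULMIN_M3S <- 1e-9 / 60   # m^3/s per ul/min

#' Unit conversions between clinical/lab units and SI
#'
#' Pressure is converted with 1 mmHg = 133.322 Pa; volumetric flow with
#' 1 ul/min = 1e-9/60 m^3/s. All conversions are exact scalings and mutually
#' inverse.
#'
#' @param p_mmhg,p_pa pressure in mmHg / Pa.
#' @param q_ulmin,q_m3s volumetric flow in ul/min / m^3/s.
#' @param x_mm,x_m length in mm / m.
#' @return the converted numeric vector.
#' @examples
#' mmhg_to_pa(10)        # ~1333 Pa
#' pa_to_mmhg(2167)      # ~16.25 mmHg
#' ulmin_to_m3s(5000)    # ~8.33e-8 m^3/s
#' @name units
NULL

#' @rdname units
#' @export
mmhg_to_pa <- function(p_mmhg) p_mmhg * .MMHG_PA

#' @rdname units
#' @export
pa_to_mmhg <- function(p_pa) p_pa / .MMHG_PA

#' @rdname units
#' @export
ulmin_to_m3s <- function(q_ulmin) q_ulmin * .ULMIN_M3S

#' @rdname units
#' @export
m3s_to_ulmin <- function(q_m3s) q_m3s / .ULMIN_M3S

#' @rdname units
#' @export
mm_to_m <- function(x_mm) x_mm * 1e-3

#' @rdname units
#' @export
m_to_mm <- function(x_m) x_m * 1e3
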