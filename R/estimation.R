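# Parameter recovery from sampled height/pressure trajectories: the cubic
# pressure-height fit, the three-parameter filling-curve fit, resistance
# inference, and the multi-run equilibrium scaling check.

#' Origin-constrained cubic fit of pressure against height
#'
#' The purse law predicts P linear in H^3 through the origin. The
#' least-squares slope k of P ~ H^3 identifies the lumped membrane
#' stiffness: E*T = k * r^4 / c2.
#'
#' @param h heights, m.
#' @param p pressures, Pa (same length as `h`, n >= 3).
#' @param r planform radius, m.
#' @param c2 pressure-law constant; default 4.63.
#' @return an object of class `cubic_fit`: list with `slope` (Pa m^-3),
#'   `inferred_et` (Pa m, the product E*T), `r_squared` (uncentred, on the
#'   origin-constrained model).
#' @export
fit_pressure_height_cubic <- function(h, p, r, c2 = 4.63) {
  stopifnot(length(h) == length(p), length(h) >= 3L, is.numeric(r), r > 0, c2 > 0)
  if (any(h < 0)) stop("heights must be non-negative")
  x <- h^3
  if (all(x == 0)) stop("degenerate fit: all heights are zero")
  slope <- sum(p * x) / sum(x^2)
  ss_res <- sum((p - slope * x)^2)
  ss_tot <- sum(p^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(slope = slope, inferred_et = slope * r^4 / c2, r_squared = r2, n = length(h)),
    class = "cubic_fit"
  )
}

#' @export
print.cubic_fit <- function(x, ...) {
  cat("Cubic pressure-height fit (n =", x$n, "):\n",
      "  slope       =", format(x$slope, digits = 6), "Pa m^-3\n",
      "  E*T         =", format(x$inferred_et, digits = 6), "Pa m\n",
      "  R-squared   =", format(x$r_squared, digits = 6), "\n")
  invisible(x)
}

#' Fit the universal filling curve to a height time series
#'
#' Nonlinear least squares of the three-parameter model
#' H(t) = H_max * hhat((t + t0) / T_c), where hhat is the exact
#' dimensionless solution [hhat_of_tau()] and t0 is a virtual time offset
#' accounting for fluid already present when recording started (t0 = 0 for
#' a bleb filled from empty). Fitted with a bounded Levenberg-Marquardt
#' solver (`minpack.lm::nlsLM`); bounds H_max > 0, T_c > 0, t0 >= 0.
#'
#' Starting values: H_max from 1.05 * max(H); T_c from the first time H
#' exceeds 82% of its maximum (the one-time-constant level of the universal
#' curve); t0 from inverting the universal curve at the first sample.
#'
#' @param t sample times, s, strictly increasing (n >= 5).
#' @param h sampled heights, m, non-negative.
#' @return an object of class `filling_fit`: list with `h_max` (m),
#'   `t_c` (s), `t0` (s), `residual_rms` (m), `n`, and the underlying
#'   `nls` object as `fit`.
#' @export
fit_filling_curve <- function(t, h) {
  stopifnot(length(t) == length(h), length(t) >= 5L)
  if (any(diff(t) <= 0)) stop("`t` must be strictly increasing")
  if (any(h < 0)) stop("heights must be non-negative")
  if (stats::sd(h) == 0) {
    stop("cannot fit a constant height series: no filling transient to identify")
  }
  # gate on the coarse trend, not per-sample ranks: a noisy plateau has no
  # rank correlation but is a perfectly good filling record
  nb <- 5L
  bins <- split(h, cut(seq_along(h), nb, labels = FALSE))
  bm <- vapply(bins, mean, numeric(1))
  if (bm[nb] <= bm[1] || max(bm) > bm[nb] + (bm[nb] - bm[1])) {
    stop("height series is not dominantly increasing in time; ",
         "the filling model does not apply (check units and ordering)")
  }

  hmax0 <- 1.05 * max(h)
  i82 <- which(h > 0.82 * max(h))[1]
  tc0 <- max(t[i82] - t[1], diff(range(t)) / 20)
  t00 <- tc0 * tau_of_hhat(min(h[1] / hmax0, 0.99))
  dat <- data.frame(tt = t - t[1], hh = h)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      hh ~ hmax * hhat_of_tau((tt + t0) / tc),
      data = dat,
      start = list(hmax = hmax0, tc = tc0, t0 = t00),
      lower = c(hmax = max(h) * 1e-6, tc = diff(range(t)) * 1e-9, t0 = 0),
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-14, ptol = 1e-12
      )
    ),
    error = function(e) {
      stop("filling-curve fit failed to converge: ", conditionMessage(e),
           " (n = ", length(t), ", height range = ",
           format(diff(range(h)), digits = 3), " m)", call. = FALSE)
    }
  )
  cf <- stats::coef(fit)
  structure(
    list(
      h_max = unname(cf["hmax"]),
      t_c = unname(cf["tc"]),
      t0 = unname(cf["t0"]),
      residual_rms = sqrt(mean(stats::residuals(fit)^2)),
      n = length(t),
      fit = fit
    ),
    class = "filling_fit"
  )
}

#' @export
print.filling_fit <- function(x, ...) {
  cat("Filling-curve fit (n =", x$n, "):\n",
      "  H_max =", format(m_to_mm(x$h_max), digits = 6), "mm\n",
      "  T_c   =", format(x$t_c, digits = 6), "s\n",
      "  t0    =", format(x$t0, digits = 6), "s\n",
      "  RMS residual =", format(m_to_mm(x$residual_rms), digits = 4), "mm\n")
  invisible(x)
}

#' Infer outflow resistance from equilibrium pressure
#'
#' At steady state inflow equals outflow, so P_max = K * Q_in and
#' K = P_max / Q_in.
#'
#' @param p_max equilibrium pressure, Pa.
#' @param q_in inflow rate, m^3/s (> 0).
#' @return outflow resistance in Pa s m^-3. A zero `p_max` returns 0 with
#'   a warning (a degenerate, resistance-free system).
#' @export
infer_resistance <- function(p_max, q_in) {
  if (!is.numeric(q_in) || q_in <= 0) stop("resistance inference requires q_in > 0")
  if (p_max == 0) warning("p_max = 0: degenerate (resistance-free) estimate")
  p_max / q_in
}

#' Check the equilibrium scaling relations across runs
#'
#' Pools fitted equilibria from several experiments and regresses, on
#' log-log axes with a shared exponent, both H_max/r and
#' Q_in*T_c/(pi r^3) against the loading parameter x = P_max * r / (E T).
#' The model predicts a shared exponent of 1/3 with prefactors
#' c2^(-1/3) (~0.6) and c1 * c2^(-1/3) (~0.3).
#'
#' @param runs a list of at least 3 runs, each a list with elements `fit`
#'   (a `filling_fit`), `system` (a [flow_system()]), and `membrane`
#'   (a [membrane_properties()]). Runs must span distinct loading values.
#' @return list with `prefactor_h`, `prefactor_t`, `exponent`.
#' @export
scaling_check <- function(runs) {
  if (length(runs) < 3L) {
    stop("insufficient data: scaling check needs at least 3 runs")
  }
  rows <- lapply(runs, function(run) {
    stopifnot(inherits(run$fit, "filling_fit"),
              inherits(run$system, "flow_system"),
              inherits(run$membrane, "membrane_properties"))
    sys <- run$system
    mem <- run$membrane
    p_max <- pressure_from_height(run$fit$h_max, sys$r, mem)
    x <- p_max * sys$r / (mem$youngs_modulus * mem$thickness)
    data.frame(
      log_x = log(x),
      log_y = log(c(run$fit$h_max / sys$r,
                    sys$q_in * run$fit$t_c / (pi * sys$r^3))),
      which = c("h", "t")
    )
  })
  dat <- do.call(rbind, rows)
  if (diff(range(dat$log_x)) < 1e-8) {
    stop("insufficient spread: runs do not span distinct loading values ",
         "P_max * r / (E T); vary the inflow rate or geometry")
  }
  fit <- stats::lm(log_y ~ log_x + which, data = dat)
  cf <- stats::coef(fit)
  list(
    prefactor_h = unname(exp(cf["(Intercept)"])),
    prefactor_t = unname(exp(cf["(Intercept)"] + cf["whicht"])),
    exponent = unname(cf["log_x"])
  )
}
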