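# Exact solution of the dimensionless filling equation dH/dtau = 1 - H^3.

# tau at which the asymptote 1 - hhat = exp(-3 (tau - tau0)) becomes exact
# to double precision: beyond it 1 - hhat < 1e-13 and the closed form is
# numerically indistinguishable from its expansion about hhat = 1.
.TAU0 <- log(3) / 6 + pi / (6 * sqrt(3))
.TAU_ASYMPTOTE <- .TAU0 + 13 * log(10) / 3   # ~ 10.46

#' Dimensionless time to reach a given dimensionless height
#'
#' Closed-form solution of dH/dtau = 1 - H^3 started from H = 0: the
#' antiderivative of 1/(1 - x^3),
#' \deqn{\tau(\hat H) = \frac{1}{6}\ln\frac{\hat H^2 + \hat H + 1}{(1-\hat H)^2}
#'  + \frac{1}{\sqrt 3}\left[\arctan\frac{2\hat H + 1}{\sqrt 3}
#'  - \arctan\frac{1}{\sqrt 3}\right].}
#' Strictly increasing on \[0, 1) and diverging logarithmically as
#' hhat -> 1 (equilibrium is approached but never reached in finite time).
#'
#' @param hhat dimensionless height H / H_max, in \[0, 1); may be a vector.
#' @return dimensionless time tau, same length as `hhat`.
#' @examples
#' tau_of_hhat(c(0, 0.5, 0.82))  # 0, ~0.517, ~0.993
#' @export
tau_of_hhat <- function(hhat) {
  if (any(hhat < 0)) stop("`hhat` must be non-negative")
  if (any(hhat >= 1)) stop("`hhat` must be below 1: equilibrium is reached only as tau -> Inf")
  .tau_of_hhat_unchecked(hhat)
}

.tau_of_hhat_unchecked <- function(h) {
  log((h^2 + h + 1) / (1 - h)^2) / 6 +
    (atan((2 * h + 1) / sqrt(3)) - atan(1 / sqrt(3))) / sqrt(3)
}

#' Dimensionless height reached at a given dimensionless time
#'
#' Numerical inverse of [tau_of_hhat()]: the unique hhat in \[0, 1) with
#' tau(hhat) = tau. Solved by safeguarded Newton iteration on the closed
#' form (the derivative d tau / d hhat = 1/(1 - hhat^3) is known exactly);
#' for large tau, where 1 - hhat falls below double-precision resolution,
#' the exact exponential asymptote 1 - hhat = exp(-3 (tau - tau0)) is used.
#' Accurate to better than 1e-10 absolute everywhere.
#'
#' @param tau dimensionless time, >= 0; may be a vector.
#' @return dimensionless height in \[0, 1), same length as `tau`.
#' @examples
#' hhat_of_tau(1)  # ~0.823: ~82% of the final height (and volume) at t = T_c
#' @export
hhat_of_tau <- function(tau) {
  if (any(tau < 0)) stop("`tau` must be non-negative")
  h <- numeric(length(tau))
  far <- tau > .TAU_ASYMPTOTE
  # clamp to the largest double below 1: the contract is hhat in [0, 1)
  h[far] <- pmin(1 - exp(-3 * (tau[far] - .TAU0)), 1 - .Machine$double.eps / 2)
  near <- !far & tau > 0
  if (any(near)) {
    target <- tau[near]
    # tau(h) >= h, so the root lies in [0, min(tau, 1)); tau is convex in h,
    # hence after the first step Newton descends monotonically to the root.
    x <- pmin(target, 0.9)
    for (i in seq_len(100L)) {
      step <- (.tau_of_hhat_unchecked(x) - target) * (1 - x^3)
      x <- pmin(pmax(x - step, 0), 1 - 1e-15)
      if (max(abs(step)) < 1e-14) break
    }
    h[near] <- x
  }
  h
}

#' Pressure ratio along the universal curve
#'
#' The purse law makes pressure cubic in height, so along any trajectory
#' P / P_max = (H / H_max)^3 = hhat^3.
#'
#' @param hhat dimensionless height, in \[0, 1\].
#' @return P / P_max.
#' @export
pressure_ratio <- function(hhat) {
  if (any(hhat < 0 | hhat > 1)) stop("`hhat` must lie in [0, 1]")
  hhat^3
}
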