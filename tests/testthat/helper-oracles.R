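# Independent oracles, kept separate from the implementation paths they check.

# Fixed-step RK4 integration of dH/dtau = 1 - H^3 from H(0) = 0.
rk4_hhat <- function(tau_end, dt = 1e-4) {
  f <- function(h) 1 - h^3
  n <- ceiling(tau_end / dt)
  dt <- tau_end / n
  h <- 0
  for (i in seq_len(n)) {
    k1 <- f(h)
    k2 <- f(h + dt / 2 * k1)
    k3 <- f(h + dt / 2 * k2)
    k4 <- f(h + dt * k3)
    h <- h + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  h
}

# Adaptive quadrature of the filling integral tau = int_0^h dx / (1 - x^3).
quad_tau <- function(h) {
  stats::integrate(function(x) 1 / (1 - x^3), 0, h,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# Standard bench experiment pieces reused across tests.
in_vitro_system <- function(q_ul_min = 5000) {
  flow_system(ulmin_to_m3s(q_ul_min), k = 2.6e10, r = 20e-3)
}
in_vitro_membrane <- function() membrane_properties(1.24e6, 0.8e-3)
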