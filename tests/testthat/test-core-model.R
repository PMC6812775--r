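# Purse-law algebra and characteristic scales.

test_that("spherical-cap volume is c1*pi*r^2*h with the expected behaviour", {
  # human-scale example: R = 4 mm, H = 1 mm -> 25.13 ul
  expect_equal(bleb_volume(4e-3, 1e-3), 0.5 * pi * 16e-6 * 1e-3, tolerance = 1e-12)
  expect_equal(bleb_volume(4e-3, 1e-3) * 1e9, 25.13, tolerance = 1e-3)
  expect_identical(bleb_volume(4e-3, 0), 0)
  expect_equal(bleb_volume(4e-3, 2e-3), 2 * bleb_volume(4e-3, 1e-3))
  expect_error(bleb_volume(0, 1e-3), "positive")
  expect_error(bleb_volume(-1, 1e-3), "positive")
})

test_that("pressure-height law has cubic/quartic exponents and exact inverse", {
  mem <- in_vitro_membrane()
  expect_identical(pressure_from_height(0, 20e-3, mem), 0)
  # power-law exponents
  p1 <- pressure_from_height(2e-3, 20e-3, mem)
  expect_equal(pressure_from_height(4e-3, 20e-3, mem) / p1, 8)
  expect_equal(pressure_from_height(2e-3, 40e-3, mem) / p1, 1 / 16)
  # algebraic inverse round-trips to 1e-12 relative
  h <- c(1e-4, 5e-4, 2e-3, 4.23e-3)
  expect_equal(height_from_pressure(pressure_from_height(h, 20e-3, mem), 20e-3, mem),
               h, tolerance = 1e-12)
  expect_identical(height_from_pressure(0, 20e-3, mem), 0)
  expect_error(pressure_from_height(1e-3, 0, mem), "positive")
})

test_that("resistive outflow balances the inflow at the equilibrium pressure", {
  sys <- in_vitro_system(5000)
  expect_identical(outflow(0, sys$k), 0)
  # P = 2167 Pa across K = 2.6e10 carries 5000 ul/min
  expect_equal(m3s_to_ulmin(outflow(2166.67, 2.6e10)), 5000, tolerance = 1e-4)
  expect_equal(outflow(sys$k * sys$q_in, sys$k), sys$q_in, tolerance = 1e-15)
  expect_error(outflow(100, 0), "positive")
})

test_that("characteristic scales match the bench configuration and its identities", {
  sys <- in_vitro_system(5000)
  mem <- in_vitro_membrane()
  sc <- characteristic_scales(sys, mem)
  # equilibrium of the bench set-up: P_max = K*Q_in ~ 2167 Pa, H_max ~ 4.23 mm
  expect_equal(sc$p_max, 2.6e10 * 5000 * 1e-9 / 60, tolerance = 1e-12)
  expect_equal(sc$p_max, 2166.67, tolerance = 1e-5)
  expect_equal(m_to_mm(sc$h_max), 4.23, tolerance = 1e-3)
  # structural identities, randomized inputs
  set.seed(7)
  for (i in 1:20) {
    s <- flow_system(10^stats::runif(1, -11, -7), 10^stats::runif(1, 8, 14),
                     10^stats::runif(1, -3, -1.5))
    m <- membrane_properties(10^stats::runif(1, 5, 8), 10^stats::runif(1, -4.5, -3))
    sci <- characteristic_scales(s, m)
    expect_equal(sci$p_max, pressure_from_height(sci$h_max, s$r, m), tolerance = 1e-12)
    expect_equal(sci$t_c, m$c1 * pi * s$r^2 * sci$h_max / s$q_in, tolerance = 1e-12)
  }
  # 1/3 power: x8 in flow doubles the equilibrium height
  sc8 <- characteristic_scales(in_vitro_system(5000 * 8), mem)
  expect_equal(sc8$h_max / sc$h_max, 2, tolerance = 1e-12)
  expect_error(characteristic_scales(flow_system(0, 1e10, 1e-2), mem), "degenerate")
})

test_that("fill time estimate reproduces the human worked example", {
  # R = 4 mm, H_max = 1 mm, Q_in = 1 ul/min -> 480*pi ~ 1508 s (~25 min)
  tc <- fill_time_estimate(4e-3, 1e-3, ulmin_to_m3s(1))
  expect_equal(tc, 480 * pi, tolerance = 1e-12)
  expect_equal(fill_time_estimate(4e-3, 1e-3, ulmin_to_m3s(2)), tc / 2)
  # matches the characteristic time when h_max is the model equilibrium
  sys <- in_vitro_system(8000)
  mem <- in_vitro_membrane()
  sc <- characteristic_scales(sys, mem)
  expect_equal(fill_time_estimate(sys$r, sc$h_max, sys$q_in, mem$c1), sc$t_c,
               tolerance = 1e-12)
  expect_error(fill_time_estimate(4e-3, 1e-3, 0), "degenerate")
})

test_that("scaling prefactors evaluate to 0.6 and 0.3 at the default constants", {
  pf <- scaling_prefactors(0.5, 4.63)
  expect_equal(round(unname(pf), 1), c(0.6, 0.3))
  expect_equal(unname(scaling_prefactors(1, 1)), c(1, 1))
  set.seed(11)
  for (i in 1:10) {
    c1 <- stats::runif(1, 0.1, 2)
    c2 <- stats::runif(1, 0.1, 10)
    pfi <- scaling_prefactors(c1, c2)
    expect_equal(unname(pfi["prefactor_t"]), c1 * unname(pfi["prefactor_h"]),
                 tolerance = 1e-14)
  }
})

test_that("simulated trajectories match the analytic solution and conserve mass", {
  sys <- in_vitro_system(5000)
  mem <- in_vitro_membrane()
  sc <- characteristic_scales(sys, mem)
  times <- seq(0, 180, by = 1 / 1.875)
  sim <- simulate_bleb(sys, mem, h0 = 0, times = times)

  # analytic-solution oracle: H(t) = H_max * hhat(t / T_c)
  analytic <- sc$h_max * hhat_of_tau(times / sc$t_c)
  rel <- abs(sim$height_m[-1] - analytic[-1]) / analytic[-1]
  expect_lt(max(rel), 1e-6)

  # strictly increasing, bounded above by the equilibrium
  expect_true(all(diff(sim$height_m) > 0))
  expect_true(all(sim$height_m < sc$h_max))

  # mass balance: volume change equals net integrated in/outflow (trapezoid)
  net <- sys$q_in - sim$pressure_pa / sys$k
  dt <- diff(times)
  influx <- cumsum(c(0, (net[-1] + net[-length(net)]) / 2 * dt))
  vol <- bleb_volume(sys$r, sim$height_m, mem$c1)
  # residual is the trapezoid quadrature error, O((dt/T_c)^2) ~ 2e-5 here
  expect_equal(vol, influx, tolerance = 1e-4)
})

test_that("equilibrium start stays put and an overfilled bleb decays to it", {
  sys <- in_vitro_system(5000)
  mem <- in_vitro_membrane()
  sc <- characteristic_scales(sys, mem)
  times <- seq(0, 120, by = 2)
  at_eq <- simulate_bleb(sys, mem, h0 = sc$h_max, times = times)
  expect_equal(at_eq$height_m, rep(sc$h_max, length(times)), tolerance = 1e-9)
  expect_equal(at_eq$pressure_pa, rep(sc$p_max, length(times)), tolerance = 1e-8)

  over <- simulate_bleb(sys, mem, h0 = 1.5 * sc$h_max, times = times)
  expect_true(all(diff(over$height_m) < 0))
  expect_true(all(over$height_m > sc$h_max))
  expect_equal(over$height_m[length(times)], sc$h_max, tolerance = 1e-4)

  expect_error(simulate_bleb(sys, mem, h0 = -1e-3, times = times), "non-negative")
  expect_error(simulate_bleb(sys, mem, h0 = 0, times = c(1, 2, 3)), "from 0")
})

test_that("collapse rescales onto the universal curve for all flow rates", {
  mem <- in_vitro_membrane()
  for (q in c(5000, 8000, 10000)) {
    sys <- in_vitro_system(q)
    sc <- characteristic_scales(sys, mem)
    sim <- simulate_bleb(sys, mem, 0, seq(0, 6 * sc$t_c, length.out = 200))
    col <- collapse_series(sim, sc)
    expect_lt(max(abs(col$hhat - hhat_of_tau(col$tau))), 1e-6)
    expect_equal(col$p_ratio, col$hhat^3, tolerance = 1e-9)
  }
  # unit scales: collapse is the identity
  sys <- in_vitro_system(5000)
  sim <- simulate_bleb(sys, mem, 0, seq(0, 10, by = 1))
  ident <- collapse_series(sim, list(t_c = 1, h_max = 1, p_max = 1))
  expect_identical(ident$tau, sim$time_s)
  expect_identical(ident$hhat, sim$height_m)
  expect_error(collapse_series(sim, list(t_c = 0, h_max = 1, p_max = 1)), "positive")
})
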