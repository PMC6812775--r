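# Parameter recovery from simulated trajectories.

test_that("cubic pressure-height fit recovers the lumped stiffness exactly", {
  sys <- in_vitro_system(5000)
  mem <- in_vitro_membrane()
  sim <- simulate_bleb(sys, mem, 0, seq(0, 180, by = 1 / 1.875))
  cub <- fit_pressure_height_cubic(sim$height_m, sim$pressure_pa, sys$r)
  # generator round-trip: E*T = 1.24e6 * 0.8e-3 = 992 Pa m
  expect_equal(cub$inferred_et, 992, tolerance = 1e-9)
  expect_gt(cub$r_squared, 1 - 1e-12)

  # all-zero pressures give slope zero; all-zero heights are degenerate
  expect_equal(fit_pressure_height_cubic(sim$height_m, rep(0, nrow(sim)), sys$r)$slope, 0)
  expect_error(fit_pressure_height_cubic(rep(0, 10), rep(0, 10), sys$r), "degenerate")
})

test_that("cubic fit tolerates transducer noise at the stated level", {
  sys <- in_vitro_system(5000)
  mem <- in_vitro_membrane()
  sc <- characteristic_scales(sys, mem)
  sim <- simulate_bleb(sys, mem, 0, seq(0, 6 * sc$t_c, length.out = 200))
  withr::with_seed(42, {
    p_noisy <- sim$pressure_pa + stats::rnorm(200, 0, 0.02 * sc$p_max)
  })
  cub <- fit_pressure_height_cubic(sim$height_m, p_noisy, sys$r)
  expect_equal(cub$inferred_et, 992, tolerance = 0.05)
})

test_that("cubic fit slope is invariant under consistent SI input", {
  # the same physical data expressed via a mmHg/mm detour must come back
  # identical once converted to SI before fitting
  sys <- in_vitro_system(8000)
  mem <- in_vitro_membrane()
  sim <- simulate_bleb(sys, mem, 0, seq(0, 120, by = 2))
  h_via_mm <- mm_to_m(m_to_mm(sim$height_m))
  p_via_mmhg <- mmhg_to_pa(pa_to_mmhg(sim$pressure_pa))
  a <- fit_pressure_height_cubic(sim$height_m, sim$pressure_pa, sys$r)
  b <- fit_pressure_height_cubic(h_via_mm, p_via_mmhg, sys$r)
  expect_equal(a$slope, b$slope, tolerance = 1e-12)
})

test_that("filling-curve fit recovers noiseless generating parameters", {
  sys <- in_vitro_system(5000)
  mem <- in_vitro_membrane()
  sc <- characteristic_scales(sys, mem)
  sim <- simulate_bleb(sys, mem, 0, seq(0, 180, by = 1 / 1.875))
  ff <- fit_filling_curve(sim$time_s, sim$height_m)
  expect_equal(ff$h_max, sc$h_max, tolerance = 1e-3)
  expect_equal(ff$t_c, sc$t_c, tolerance = 1e-3)
  expect_lt(ff$t0, 1e-3 * sc$t_c)
  expect_lt(ff$residual_rms, 1e-6 * sc$h_max)
})

test_that("a pre-filled bleb is absorbed into the fitted time offset", {
  sys <- in_vitro_system(5000)
  mem <- in_vitro_membrane()
  sc <- characteristic_scales(sys, mem)
  sim <- simulate_bleb(sys, mem, h0 = 0.3 * sc$h_max, times = seq(0, 180, by = 1 / 1.875))
  ff <- fit_filling_curve(sim$time_s, sim$height_m)
  expect_equal(ff$h_max, sc$h_max, tolerance = 1e-3)
  expect_equal(ff$t_c, sc$t_c, tolerance = 1e-3)
  # analytic offset oracle: t0 = T_c * tau(0.3)
  expect_equal(ff$t0, sc$t_c * tau_of_hhat(0.3), tolerance = 5e-3)

  # relabelling the clock leaves the physical parameters unchanged
  shifted <- fit_filling_curve(sim$time_s + 0.1 * sc$t_c, sim$height_m)
  expect_equal(shifted$h_max, ff$h_max, tolerance = 1e-6)
  expect_equal(shifted$t_c, ff$t_c, tolerance = 1e-6)
})

test_that("filling-curve fit survives photographic noise at the stated level", {
  # 4 h of once-a-minute photographs, 2% multiplicative height noise
  sys <- flow_system(ulmin_to_m3s(5), k = 1.6e13, r = 4e-3)
  mem <- membrane_properties(28e6, 0.1e-3)
  sc <- characteristic_scales(sys, mem)
  times <- seq(0, 239) * 60 / 24  # 240 samples across ~ 6.7 T_c
  sim <- simulate_bleb(sys, mem, 0, times)
  withr::with_seed(1234, {
    h_noisy <- pmax(sim$height_m * (1 + stats::rnorm(240, 0, 0.02)), 0)
  })
  ff <- fit_filling_curve(times, h_noisy)
  expect_equal(ff$h_max, sc$h_max, tolerance = 0.05)
  expect_equal(ff$t_c, sc$t_c, tolerance = 0.05)
})

test_that("degenerate height series are rejected with a diagnostic", {
  t <- seq(0, 100, by = 1)
  expect_error(fit_filling_curve(t, rep(1e-3, 101)), "constant")
  expect_error(fit_filling_curve(t, 1e-3 * exp(-t / 30)), "not dominantly increasing")
  expect_error(fit_filling_curve(c(1, 2, 2, 3, 4), rep(1:5) * 1e-4), "increasing")
})

test_that("resistance inference inverts the equilibrium relation", {
  # bench value: 2167 Pa at 5000 ul/min -> K ~ 2.6e10 Pa s m^-3
  expect_equal(infer_resistance(2166.67, ulmin_to_m3s(5000)), 2.6e10, tolerance = 1e-5)
  expect_warning(k0 <- infer_resistance(0, ulmin_to_m3s(5)), "degenerate")
  expect_identical(k0, 0)
  expect_error(infer_resistance(100, 0), "q_in > 0")
  set.seed(3)
  for (i in 1:10) {
    s <- flow_system(10^stats::runif(1, -11, -7), 10^stats::runif(1, 9, 13), 1e-2)
    sc <- characteristic_scales(s, in_vitro_membrane())
    expect_equal(infer_resistance(sc$p_max, s$q_in), s$k, tolerance = 1e-12)
  }
})

test_that("scaling check recovers the 1/3 exponent and 0.6/0.3 prefactors", {
  mem <- in_vitro_membrane()
  runs <- lapply(c(5000, 8000, 10000), function(q) {
    sys <- in_vitro_system(q)
    sc <- characteristic_scales(sys, mem)
    sim <- simulate_bleb(sys, mem, 0, seq(0, 8 * sc$t_c, length.out = 300))
    list(fit = fit_filling_curve(sim$time_s, sim$height_m),
         system = sys, membrane = mem)
  })
  chk <- scaling_check(runs)
  expect_equal(chk$exponent, 1 / 3, tolerance = 5e-3)
  expect_equal(chk$prefactor_h, 4.63^(-1 / 3), tolerance = 5e-3)
  expect_equal(chk$prefactor_t, 0.5 * 4.63^(-1 / 3), tolerance = 5e-3)
  expect_equal(chk$prefactor_t / chk$prefactor_h, 0.5, tolerance = 5e-3)

  expect_error(scaling_check(runs[1:2]), "at least 3")
  same_q <- list(runs[[1]], runs[[1]], runs[[1]])
  expect_error(scaling_check(same_q), "insufficient spread")
})
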