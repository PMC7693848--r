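fl <- fluid_props(1000, 1e-3)

test_that("net lift force follows the quadratic-velocity quartic-size law", {
  expect_equal(net_lift_force(fl, 0, 17e-6, 150e-6), 0)
  # direct evaluation: 2 * 1000 * 0.667^2 * (17e-6)^4 * 0.5 / (150e-6)^2
  expect_equal(net_lift_force(fl, 0.667, 17e-6, 150e-6, c_l = 0.5),
               1.6514e-9, tolerance = 1e-4)
  f17 <- net_lift_force(fl, 0.667, 17e-6, 150e-6)
  f10 <- net_lift_force(fl, 0.667, 10e-6, 150e-6)
  expect_equal(f17 / f10, 1.7^4, tolerance = 1e-12)
  # randomized scaling properties
  set.seed(7)
  for (k in 1:10) {
    u <- runif(1, 0.1, 2); a <- runif(1, 2e-6, 2e-5)
    expect_equal(net_lift_force(fl, 2 * u, a, 150e-6) /
                   net_lift_force(fl, u, a, 150e-6), 4, tolerance = 1e-12)
  }
})

test_that("Dean drag is Stokes-linear in diameter and Dean velocity", {
  expect_equal(dean_drag_force(fl, 0, 17e-6), 0)
  expect_equal(dean_drag_force(fl, 0.0188, 17e-6), 3.012e-9,
               tolerance = 1e-3)
  expect_equal(dean_drag_force(fl, 0.02, 20e-6) /
                 dean_drag_force(fl, 0.02, 10e-6), 2, tolerance = 1e-12)
})

test_that("lift-to-drag ratio scales exactly with the cube of size", {
  r <- force_ratio(fl, 0.667, 0.0188, 17e-6, 150e-6) /
    force_ratio(fl, 0.667, 0.0188, 10e-6, 150e-6)
  expect_equal(r, 1.7^3, tolerance = 1e-12)
  expect_equal(force_ratio(fl, 1, 0.01, 5e-6, 1e-4) /
                 force_ratio(fl, 1, 0.01, 5e-6, 1e-4), 1)
  # brute-force property oracle over random parameter sets
  set.seed(42)
  for (k in 1:20) {
    u <- runif(1, 0.05, 3); ud <- runif(1, 1e-3, 0.1)
    dh <- runif(1, 5e-5, 3e-4); cl <- runif(1, 0.1, 1)
    a1 <- runif(1, 2e-6, 3e-5); a2 <- runif(1, 2e-6, 3e-5)
    rr <- force_ratio(fl, u, ud, a1, dh, cl) /
      force_ratio(fl, u, ud, a2, dh, cl)
    expect_equal(rr, (a1 / a2)^3, tolerance = 1e-12)
  }
  expect_error(force_ratio(fl, 1, 0, 1e-5, 1e-4), "Dean velocity")
})

test_that("channel dimensionless numbers match hand arithmetic", {
  dn <- dimensionless_numbers(fl, 1.2, 300, 100)
  expect_equal(dn$u_avg, 2e-8 / 3e-8, tolerance = 1e-12)
  expect_equal(dn$re, 100, tolerance = 1e-3)
  expect_equal(dn$de, 0)  # straight duct limit
  dn0 <- dimensionless_numbers(fl, 0, 300, 100)
  expect_equal(dn0$u_avg, 0)
  expect_equal(dn0$re, 0)
  dnc <- dimensionless_numbers(fl, 1.2, 300, 100, radius = 3000)
  expect_equal(dnc$de, 100 * sqrt(150e-6 / (2 * 3000e-6)), tolerance = 1e-3)
})

test_that("Dean velocity power law is anchored and monotone", {
  expect_equal(dean_velocity(0), 0)
  expect_equal(dean_velocity(17.32), 1.8e-4 * 17.32^1.63)
  expect_equal(dean_velocity(17.32), 0.0188, tolerance = 0.01)
  de <- sort(runif(50, 0, 50))
  expect_true(all(diff(dean_velocity(de)) >= 0))
})

test_that("wall shear stress matches the wide-slot formula", {
  expect_equal(wall_shear_stress(fl, 0, 300, 100)$pa, 0)
  tau <- wall_shear_stress(fl, 1.2, 300, 100)
  expect_equal(tau$pa, 40, tolerance = 1e-6)
  expect_equal(tau$dyn_cm2, 400, tolerance = 1e-6)
  expect_equal(wall_shear_stress(fl, 2.4, 300, 100)$pa, 2 * tau$pa)
})

test_that("design rules gate on the downstream resolution", {
  r <- evaluate_design_rules(1.0, 30.46)
  expect_true(r$upstream$within_band)
  expect_true(r$downstream$pass)
  r2 <- evaluate_design_rules(2.24, 2.24)
  expect_false(r2$downstream$pass)
  expect_true(evaluate_design_rules(0, 10)$downstream$pass)
})
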