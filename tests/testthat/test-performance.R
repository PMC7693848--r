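test_that("bead recovery and purity match direct arithmetic", {
  expect_equal(bead_recovery(bead_counts(90, 10)), 90)
  expect_equal(bead_recovery(bead_counts(123, 0)), 100)
  expect_equal(bead_purity(bead_counts(95, 0, 5, 0)), 95)
  expect_equal(bead_purity(bead_counts(50, 0, 0, 0)), 100)
  expect_equal(bead_purity(bead_counts(7, 0, 7, 0)), 50)
  expect_error(bead_recovery(bead_counts(0, 0)), "undefined")
  # enumeration oracle on random counts
  set.seed(2)
  for (k in 1:20) {
    n <- rpois(4, 200) + 1
    b <- bead_counts(n[1], n[2], n[3], n[4])
    expect_identical(bead_recovery(b), 100 * n[1] / (n[1] + n[2]))
    expect_identical(bead_purity(b), 100 * n[1] / (n[1] + n[3]))
  }
})

test_that("WBC depletion and CTC recovery reproduce the two-cycle numbers", {
  cc <- cycle_counts(wbc_inlet = 1e6, wbc_ctc_c1 = 369000,
                     wbc_ctc_c2 = 117000, mcf7_inlet = 1000,
                     mcf7_waste_c1 = 229, mcf7_waste_c2 = 345)
  expect_equal(wbc_depletion(cc, 1), 63.1, tolerance = 1e-9)
  expect_equal(wbc_depletion(cc, 2), 88.3, tolerance = 1e-9)
  expect_equal(ctc_recovery(cc, 1), 77.1, tolerance = 1e-9)
  expect_equal(ctc_recovery(cc, 2), 65.5, tolerance = 1e-9)
  # limits
  cc2 <- cycle_counts(1000, 1000, 0, 100, 0, 100)
  expect_equal(wbc_depletion(cc2, 1), 0)
  expect_equal(wbc_depletion(cc2, 2), 100)
  expect_equal(ctc_recovery(cc2, 1), 100)
  expect_equal(ctc_recovery(cc2, 2), 0)
  # recovery + escape = 100
  expect_equal(ctc_recovery(cc, 1) + 100 * cc$mcf7_waste_c1 /
                 cc$mcf7_inlet, 100, tolerance = 1e-12)
  expect_warning(cycle_counts(100, 200, 10), "ordering")
})

test_that("viability losses reproduce the cycle-1 worked example", {
  v <- viability_counts(viable_inlet = 843, total_inlet = 1000,
                        viable_outlets = 711, total_outlets = 847)
  cl <- cell_loss(v)
  expect_equal(cl$viable_loss, 15.7, tolerance = 0.05)
  expect_equal(cl$total_loss, 15.3, tolerance = 0.05)
  expect_equal(cl$viability_in, 84.3)
  # no loss and complete loss limits
  v0 <- viability_counts(800, 1000, 800, 1000)
  expect_equal(cell_loss(v0)$viable_loss, 0)
  expect_equal(cell_loss(v0)$total_loss, 0)
  v1 <- viability_counts(800, 1000, 0, 0)
  expect_equal(cell_loss(v1)$viable_loss, 100)
  expect_error(viability_counts(10, 5, 1, 2), "viable_inlet")
})

test_that("through-origin linear fit matches the closed-form solution", {
  s <- spiking_series(c(100, 500, 1000), c(50, 250, 500))
  fit <- linear_fit_recovery(s)
  expect_equal(fit$rate, 50)
  expect_equal(fit$r_squared, 1)
  # closed-form normal-equation oracle on random data
  set.seed(9)
  for (k in 1:10) {
    x <- sample(50:3500, 8)
    y <- 0.7 * x + rnorm(8, 0, 20)
    f <- linear_fit_recovery(spiking_series(x, pmax(y, 0)))
    expect_equal(f$slope, sum(x * pmax(y, 0)) / sum(x^2), tolerance = 1e-12)
  }
  expect_error(linear_fit_recovery(spiking_series(c(5, 5, 5), c(1, 2, 3))),
               "degenerate")
})

test_that("enrichment factor inverts the remaining WBC fraction", {
  ef <- enrichment_factor(88.3)
  expect_equal(as.numeric(ef), 100 / 11.7, tolerance = 1e-9)
  expect_equal(as.numeric(ef), 8.5, tolerance = 0.05)
  expect_equal(as.numeric(enrichment_factor(0)), 1)
  expect_equal(as.numeric(enrichment_factor(50)), 2)
  expect_true(is.infinite(enrichment_factor(100)))
})

test_that("cycle bookkeeping conserves volume and reproduces the protocol", {
  bk <- cycle_bookkeeping(9.0, c(2, 3), 1.2)
  expect_equal(bk$ctc_volume_ml, 3.6)
  expect_equal(bk$waste_volume_ml, 5.4)
  expect_equal(bk$process_time_min, 7.5)
  expect_equal(cycle_bookkeeping(3.6, c(2, 3), 1.2)$process_time_min, 3)
  expect_lt(cycle_bookkeeping(10, c(2, 3), 1.2)$process_time_min, 9)
  # volume conservation property
  set.seed(4)
  for (k in 1:10) {
    v <- runif(1, 0.5, 20); r <- runif(2, 0.5, 5)
    b <- cycle_bookkeeping(v, r, 1.2)
    expect_equal(b$ctc_volume_ml + b$waste_volume_ml, v, tolerance = 1e-12)
  }
})
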