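test_that("generators are reproducible per seed and vary across seeds", {
  cfg <- synth_config(seed = 42)
  p1 <- gen_intensity_profile(cfg)
  p2 <- gen_intensity_profile(cfg)
  expect_identical(p1$intensity, p2$intensity)
  p3 <- gen_intensity_profile(synth_config(seed = 43))
  expect_false(identical(p1$intensity, p3$intensity))
  s1 <- gen_spiking_series(cfg)
  s2 <- gen_spiking_series(cfg)
  expect_identical(s1$n_recovered, s2$n_recovered)
  # underlying means identical across seeds: noiseless profiles agree
  q1 <- gen_intensity_profile(synth_config(seed = 1, noise_sd = 0))
  q2 <- gen_intensity_profile(synth_config(seed = 2, noise_sd = 0))
  expect_identical(q1$intensity, q2$intensity)
})

test_that("spiking series respects degenerate capture probabilities", {
  all_cfg <- synth_config(seed = 1, capture_probs = c(1, 1))
  s <- gen_spiking_series(all_cfg, 1)
  expect_identical(s$n_recovered, s$n_spiked)
  none <- synth_config(seed = 1, capture_probs = c(0, 0))
  s0 <- gen_spiking_series(none, 1)
  expect_true(all(s0$n_recovered == 0))
  expect_equal(length(s$n_spiked), 15)
  expect_equal(range(s$n_spiked), c(50, 3500))
})

test_that("linear-fit estimator recovers the binomial capture rate", {
  # Monte-Carlo consistency: mean estimate over 100 replicate seeds within
  # 1% of the generating 77.1%
  est <- vapply(1:100, function(seed) {
    s <- gen_spiking_series(synth_config(seed = seed), 1)
    linear_fit_recovery(s)$rate
  }, numeric(1))
  expect_equal(mean(est), 77.1, tolerance = 0.01 * 77.1)
  # cycle 2 uses the cumulative two-cycle probability
  est2 <- vapply(1:100, function(seed) {
    s <- gen_spiking_series(synth_config(seed = seed), 2)
    linear_fit_recovery(s)$rate
  }, numeric(1))
  expect_equal(mean(est2), 65.5, tolerance = 0.015 * 65.5)
})

test_that("two-cycle WBC carryover reproduces the depletion means", {
  # product of carryovers: 1 - 0.369 * 0.317 = 0.883
  dep <- vapply(1:200, function(seed) {
    cc <- gen_cycle_counts(synth_config(seed = seed), wbc_inlet = 1e7,
                           mcf7_inlet = 1000)
    wbc_depletion(cc, 2)
  }, numeric(1))
  expect_equal(mean(dep), 100 * (1 - 0.369 * (1 - 0.883) / (1 - 0.631)),
               tolerance = 0.005)
  expect_equal(mean(dep), 88.3, tolerance = 0.5)
  # degenerate carryover: everything depleted in cycle 1
  cc0 <- gen_cycle_counts(synth_config(seed = 1,
                                       wbc_carryover = c(0, 0.5)),
                          wbc_inlet = 1e6, mcf7_inlet = 100)
  expect_equal(wbc_depletion(cc0, 1), 100)
  # perfect capture: full recovery in both cycles
  cc1 <- gen_cycle_counts(synth_config(seed = 1,
                                       capture_probs = c(1, 1)),
                          wbc_inlet = 1e6, mcf7_inlet = 100)
  expect_equal(ctc_recovery(cc1, 1), 100)
  expect_equal(ctc_recovery(cc1, 2), 100)
  expect_warning(gen_cycle_counts(synth_config(seed = 1), 1000, 100),
                 "orders of magnitude")
})

test_that("viability thinning preserves viable <= total and the loss mean", {
  for (seed in 1:50) {
    vc <- gen_viability_counts(synth_config(seed = seed), 1000, 0.157)
    expect_lte(vc$viable_outlets, vc$total_outlets)
    expect_lte(vc$viable_inlet, vc$total_inlet)
  }
  vc0 <- gen_viability_counts(synth_config(seed = 1), 1000, 0)
  expect_equal(cell_loss(vc0)$viable_loss, 0)
  loss <- vapply(1:200, function(seed) {
    cell_loss(gen_viability_counts(synth_config(seed = seed), 5000,
                                   0.157))$viable_loss
  }, numeric(1))
  expect_equal(mean(loss), 15.7, tolerance = 0.5)
})

test_that("fixture writer is byte-reproducible and manifest round-trips", {
  cfg <- synth_config(seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic_fixtures(cfg, d1)
  write_synthetic_fixtures(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  cfg_back <- synth_config(seed = man$seed,
                           peaks = unlist(man$peaks),
                           fwhms = unlist(man$fwhms),
                           noise_sd = man$noise_sd)
  d3 <- withr::local_tempdir()
  write_synthetic_fixtures(cfg_back, d3)
  expect_identical(readLines(file.path(d1, "intensity_profile.csv")),
                   readLines(file.path(d3, "intensity_profile.csv")))
})
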