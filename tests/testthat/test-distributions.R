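test_that("half-height width equals the Gaussian FWHM identity", {
  d <- stream_distribution(100, sigma = 6.71)
  expect_equal(d$fwhm, 2 * sqrt(2 * log(2)) * 6.71, tolerance = 1e-9)
  d2 <- stream_distribution(100, fwhm = 15.8)
  expect_equal(d2$sigma * 2.3548, 15.8, tolerance = 1e-4)
  expect_error(stream_distribution(100), "exactly one")
})

test_that("separation resolution reproduces the focused-stream value", {
  d1 <- stream_distribution(100, fwhm = 15.8)
  d2 <- stream_distribution(160, fwhm = 15.8)
  r <- resolution(d1, d2)
  expect_equal(r$R, 1.18 * 60 / 31.6, tolerance = 1e-12)
  expect_equal(r$R, 2.24, tolerance = 0.005)
  expect_equal(r$s_p, 60)
  # identical peaks
  expect_equal(resolution(d1, d1)$R, 0)
  # scaling laws: doubling separation doubles R, doubling widths halves it
  d3 <- stream_distribution(220, fwhm = 15.8)
  expect_equal(resolution(d1, d3)$R, 2 * r$R, tolerance = 1e-12)
  dw1 <- stream_distribution(100, fwhm = 31.6)
  dw2 <- stream_distribution(160, fwhm = 31.6)
  expect_equal(resolution(dw1, dw2)$R, r$R / 2, tolerance = 1e-12)
  # translation invariance
  ds1 <- stream_distribution(130, fwhm = 15.8)
  ds2 <- stream_distribution(190, fwhm = 15.8)
  expect_equal(resolution(ds1, ds2)$R, r$R, tolerance = 1e-12)
})

test_that("discretization produces normalized symmetric weights", {
  d <- stream_distribution(150, sigma = 10)
  one <- discretize(d, n_bins = 1)
  expect_equal(unname(one$bins[, "position"]), 150)
  expect_equal(unname(one$bins[, "weight"]), 1)
  for (nb in c(3, 11, 50)) {
    for (span in c(1, 2.5, 3)) {
      dd <- discretize(d, nb, span)
      expect_equal(sum(dd$bins[, "weight"]), 1, tolerance = 1e-9)
      w <- dd$bins[, "weight"]
      expect_equal(w, rev(w), tolerance = 1e-12)
    }
  }
  # clipping against the channel renormalizes with a warning
  dn <- stream_distribution(10, sigma = 10)
  expect_warning(dc <- discretize(dn, 50, 3, channel_width = 300),
                 "clipped")
  expect_equal(sum(dc$bins[, "weight"]), 1, tolerance = 1e-9)
  expect_true(all(dc$bins[, "position"] >= 0))
})

test_that("two-Gaussian fit recovers noiseless generating parameters", {
  cfg <- synth_config(noise_sd = 0)
  prof <- gen_intensity_profile(cfg)
  fit <- fit_two_gaussians(prof)
  expect_false(attr(fit, "degenerate"))
  expect_equal(fit[[1]]$peak, 100, tolerance = 0.1)
  expect_equal(fit[[2]]$peak, 160, tolerance = 0.1)
  s <- 15.8 / 2.3548
  expect_equal(fit[[1]]$sigma, s, tolerance = 0.02 * s)
  expect_equal(fit[[2]]$sigma, s, tolerance = 0.02 * s)
  # and with mild noise the peaks stay close
  fitn <- fit_two_gaussians(gen_intensity_profile(synth_config(seed = 3)))
  expect_equal(fitn[[1]]$peak, 100, tolerance = 1)
  expect_equal(fitn[[2]]$peak, 160, tolerance = 1)
})

test_that("single-peak profiles take the degenerate path", {
  x <- seq(1, 299, length.out = 128)
  y <- 0.1 + exp(-(x - 150)^2 / (2 * 12^2))
  prof <- intensity_profile(x, y)
  expect_warning(fit <- fit_two_gaussians(prof), "single-peak")
  expect_true(attr(fit, "degenerate"))
  expect_length(fit, 1)
  expect_equal(fit[[1]]$peak, 150, tolerance = 0.5)
})

test_that("downstream histogram distribution locates a known Gaussian", {
  set.seed(11)
  pos <- rnorm(4000, 120, 8)
  d <- downstream_distribution(pos, bin_width = 2)
  expect_equal(d$peak, 120, tolerance = 2)
  expect_equal(d$fwhm, 2.3548 * 8, tolerance = 0.25 * 2.3548 * 8)
  # two well-separated tight clusters resolve with R > 1
  d1 <- downstream_distribution(rnorm(500, 40, 1), bin_width = 2)
  d2 <- downstream_distribution(rnorm(500, 200, 1), bin_width = 2)
  expect_gt(resolution(d1, d2)$R, 1)
  # all weight in one bin floors the width at the bin width
  expect_warning(dd <- downstream_distribution(rep(50, 10), bin_width = 2),
                 "floored")
  expect_equal(dd$fwhm, 2)
})

test_that("intensity profile CSV round-trips", {
  prof <- gen_intensity_profile(synth_config(seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_intensity_profile(prof, path)
  back <- read_intensity_profile(path)
  expect_equal(back$position, prof$position)
  expect_equal(back$intensity, prof$intensity)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1:20, b = 1:20), bad, row.names = FALSE)
  expect_error(read_intensity_profile(bad), "position_um")
})
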