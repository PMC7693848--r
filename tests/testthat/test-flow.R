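test_that("open channel recovers the plane-Poiseuille limit", {
  fld <- empty_field()
  expect_true(fld$converged)
  # transverse velocity negligible
  expect_lt(max(abs(fld$v)), 1e-3 * fld$u_avg)
  # axial profile symmetric about mid-channel
  mid_u <- fld$u[round(fld$nx / 2), ]
  expect_equal(mid_u, rev(mid_u), tolerance = 1e-6)
  # centerline speed within 2% of the analytic maximum 1.5 U
  vmax <- velocity_at(fld, 150, 150)
  expect_equal(unname(vmax[1, "u"]), 1.5 * fld$u_avg, tolerance = 0.02)
  # flux conservation at every station
  for (x in seq(0, fld$length_um, by = 60)) {
    expect_equal(flux_across(fld, x), fld$flux_in, tolerance = 0.01)
  }
})

test_that("velocity interpolation honors nodes and boundaries", {
  fld <- empty_field()
  h <- fld$h_um
  # grid node point returns exactly the stored vector
  i <- 20; j <- 25
  expect_identical(unname(velocity_at(fld, (i - 1) * h, (j - 0.5) * h)[1, "u"]),
                   fld$u[i, j])
  # on the no-slip wall the magnitude is below the interpolation tolerance
  vwall <- velocity_at(fld, 150, 0)
  expect_lt(abs(vwall[1, "u"]), 0.12 * fld$u_avg)
  expect_error(velocity_at(fld, -5, 150), "outside")
})

test_that("section fluxes add up across a divided outlet", {
  study <- full_study()
  fld <- study$field_reference
  q_ctc <- flux_across(fld, fld$length_um, c(0, 75))
  q_waste <- flux_across(fld, fld$length_um, c(125, 300))
  expect_equal(q_ctc + q_waste, fld$flux_in, tolerance = 0.01)
  # empty channel: half-section symmetry
  fe <- empty_field()
  expect_equal(flux_across(fe, 150, c(0, 150)), fe$flux_in / 2,
               tolerance = 0.01)
  expect_warning(flux_across(fld, 790, c(50, 150)), "solid")
})

test_that("mass is conserved at every station around the immersed solids", {
  study <- full_study()
  for (fld in list(study$field_reference, study$field_hydrofoil)) {
    for (x in seq(20, fld$length_um - 20, by = 60)) {
      expect_equal(suppressWarnings(flux_across(fld, x)), fld$flux_in,
                   tolerance = 0.01)
    }
  }
})

test_that("outlet flow split is grid-convergent", {
  dom <- build_downstream_domain(spiral_spec(), NULL,
                                 separation_wall_spec(), length = 800)
  s_coarse <- solve_flow(dom, flow_config(resolution = 10,
                                          max_steps = 12000))$split_ctc
  s_fine <- solve_flow(dom, flow_config(resolution = 5,
                                        max_steps = 20000))$split_ctc
  expect_lt(abs(s_fine - s_coarse), 0.02)
})

test_that("solver validates geometry and reports divergence", {
  # a wall spanning the full channel is infeasible
  expect_error(
    build_downstream_domain(spiral_spec(), NULL,
                            separation_wall_spec(minor_diameter = 300,
                                                 center_offset = 150)),
    "no open outlet")
  expect_error(solve_flow(build_downstream_domain(length = 801),
                          flow_config(resolution = 2)), "divide")
})

test_that("field export carries data and metadata", {
  fld <- empty_field()
  path <- withr::local_tempfile(fileext = ".csv")
  write_flow_field(fld, path)
  first <- readLines(path, n = 1)
  expect_match(first, "^# downstream domain")
  d <- utils::read.csv(path, comment.char = "#")
  expect_named(d, c("x_um", "y_um", "u_mps", "v_mps"))
  expect_equal(nrow(d), fld$nx * fld$ny)
})
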