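test_that("NACA 4-digit codes parse and invalid codes are rejected", {
  p <- parse_naca4("9730")
  expect_equal(p$m, 0.09)
  expect_equal(p$p, 0.7)
  expect_equal(p$t, 0.30)
  expect_error(parse_naca4("97a0"), "malformed")
  expect_error(parse_naca4("973"), "malformed")
  expect_error(parse_naca4("9030"), "camber position")
})

test_that("symmetric section has zero camber and mirror-symmetric surfaces", {
  poly <- naca4_profile("0030", 300, 100)
  # pair each upper-surface point with the lower point at the same x
  up <- poly[poly[, 2] > 1e-12, , drop = FALSE]
  for (i in seq_len(nrow(up))) {
    x <- up[i, 1]
    lower <- poly[abs(poly[, 1] - x) < 1e-9 & poly[, 2] < 0, , drop = FALSE]
    expect_equal(nrow(lower), 1)
    expect_equal(lower[1, 2], -up[i, 2], tolerance = 1e-9)
  }
  cam <- spiralfoil:::naca4_camber(seq(0, 1, 0.01), 0, 0.5)
  expect_true(all(cam$yc == 0))
})

test_that("cambered 9730 section has the analytic camber and thickness", {
  # camber maximum: m * chord at p * chord
  cam <- spiralfoil:::naca4_camber(0.7, 0.09, 0.7)
  expect_equal(cam$yc * 300, 27, tolerance = 1e-12)
  xs <- seq(0, 1, length.out = 20001)
  camv <- spiralfoil:::naca4_camber(xs, 0.09, 0.7)$yc
  expect_equal(xs[which.max(camv)], 0.7, tolerance = 1e-3)
  # thickness maximum: brute-force over a dense sampling of the polynomial
  th <- spiralfoil:::naca4_thickness(xs, 0.30)
  expect_equal(2 * max(th) * 300, 90, tolerance = 0.02)
  expect_equal(xs[which.max(th)], 0.30, tolerance = 0.005)
  poly <- naca4_profile("9730", 300, 200)
  expect_true(polygon_is_simple(poly))
  expect_equal(poly[1, ], poly[nrow(poly), ])
})

test_that("profile generation rejects degenerate requests", {
  expect_error(naca4_profile("9730", 300, 10), "n_points")
})

test_that("hydrofoil placement is a rigid motion", {
  poly <- naca4_profile("9730", 300, 120)
  a0 <- abs(polygon_area(poly))
  sp0 <- hydrofoil_spec(attack_angle = 0, anchor = c(0, 100))
  shifted <- poly; shifted[, 2] <- shifted[, 2] + 100
  expect_equal(place_hydrofoil(poly, sp0, channel_width = 1e6),
               shifted, ignore_attr = TRUE)
  sp30 <- hydrofoil_spec(attack_angle = 30, anchor = c(300, 195))
  placed <- place_hydrofoil(poly, sp30)
  expect_equal(abs(polygon_area(placed)), a0, tolerance = 1e-9)
  # brute-force vertex transform oracle for the rotated extent
  a <- -30 * pi / 180
  vx <- poly[, 1] * cos(a) - poly[, 2] * sin(a) + 300
  vy <- poly[, 1] * sin(a) + poly[, 2] * cos(a) + 195
  expect_equal(range(placed[, 1]), range(vx), tolerance = 1e-9)
  expect_equal(range(placed[, 2]), range(vy), tolerance = 1e-9)
})

test_that("placement outside the channel fails", {
  poly <- naca4_profile("9730", 300, 100)
  expect_error(place_hydrofoil(poly, hydrofoil_spec(anchor = c(300, 140))),
               "exits channel")
})

test_that("downstream domain partitions the outlet as specified", {
  dom <- build_downstream_domain()
  expect_equal(unname(dom$outlet_widths), c(75, 50, 175))
  expect_equal(sum(dom$outlet_widths), dom$width)
  # wall omitted: single outlet spanning the full width
  dom0 <- build_downstream_domain(wall = NULL)
  expect_equal(unname(dom0$outlet_widths), c(300, 0, 0))
  # centered wall: symmetric partition
  domc <- build_downstream_domain(
    wall = separation_wall_spec(center_offset = 150))
  expect_equal(unname(domc$outlet_widths), c(125, 50, 125))
})

test_that("solids are simple polygons inside the channel and disjoint", {
  dom <- build_downstream_domain()
  for (poly in list(dom$foil, dom$wall)) {
    expect_true(polygon_is_simple(poly))
    expect_true(all(poly[, 2] >= 0 & poly[, 2] <= dom$width))
  }
  expect_false(any(point_in_polygon(dom$foil[, 1], dom$foil[, 2],
                                    dom$wall)))
  expect_false(any(point_in_polygon(dom$wall[, 1], dom$wall[, 2],
                                    dom$foil)))
})

test_that("spiral metrics match closed forms and a polyline oracle", {
  m <- spiral_metrics(spiral_spec(width = 300, depth = 100))
  expect_equal(m$hydraulic_diameter, 150)
  expect_equal(m$pitch, 450)
  msq <- spiral_metrics(spiral_spec(width = 120, depth = 120))
  expect_equal(msq$hydraulic_diameter, 120)
  # pitch property over assorted specs
  for (g in c(0, 75, 150)) {
    expect_equal(spiral_metrics(spiral_spec(gap = g))$pitch, 300 + g)
  }
  # arc length against brute-force polyline summation
  sp <- spiral_spec(loops = 4, gap = 150, start_radius = 1000)
  th <- seq(0, 4 * 2 * pi, length.out = 1e5)
  b <- spiral_metrics(sp)$pitch / (2 * pi)
  r <- 1000 + b * th
  x <- r * cos(th); y <- r * sin(th)
  poly_len <- sum(sqrt(diff(x)^2 + diff(y)^2))
  expect_equal(spiral_metrics(sp)$centerline_length, poly_len,
               tolerance = 1e-3)
})

test_that("geometry export writes polygon CSVs and a JSON descriptor", {
  dir <- withr::local_tempdir()
  dom <- build_downstream_domain()
  paths <- write_domain_geometry(dom, dir)
  expect_true(file.exists(file.path(dir, "foil.csv")))
  expect_true(file.exists(file.path(dir, "domain.json")))
  desc <- jsonlite::read_json(file.path(dir, "domain.json"))
  expect_equal(desc$outlet_widths_um$ctc, 75)
  foil <- utils::read.csv(file.path(dir, "foil.csv"))
  expect_equal(nrow(foil), nrow(dom$foil))
})
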