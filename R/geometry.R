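# ---- spec constructors -------------------------------------------------

#' Spiral channel specification
#'
#' Describes the Archimedean spiral channel that pre-focuses particles before
#' the downstream separation region: a rectangular cross-section channel wound
#' into `loops` turns with a fixed spacing between adjacent loops.
#'
#' @param width Channel width (µm), default 300.
#' @param depth Channel depth (µm), default 100.
#' @param loops Number of spiral loops, default 4.
#' @param gap Spacing between adjacent loops (µm), default 150.
#' @param start_radius Innermost centerline radius (µm), default 1000.
#' @return An object of class `spiral_spec`.
#' @export
spiral_spec <- function(width = 300, depth = 100, loops = 4, gap = 150,
                        start_radius = 1000) {
  stopifnot(width > 0, depth > 0, loops >= 1, gap >= 0, start_radius > 0)
  structure(list(width = width, depth = depth, loops = loops, gap = gap,
                 start_radius = start_radius),
            class = "spiral_spec")
}

#' Hydrofoil specification
#'
#' A NACA 4-digit hydrofoil section placed in the downstream channel at an
#' attack angle. The anchor is the leading-edge position in channel
#' coordinates (x along flow, y across the channel measured from the
#' reference wall, the wall nearest the large-particle focal axis).
#'
#' The default anchor puts the leading edge at y = 195 µm, above both bead
#' focal axes (100 and 160 µm), so that at a 30 degree nose-down attack
#' angle (i) the passage under the trailing edge stays wider than the
#' largest particle diameter and (ii) the under-foil passage captures the
#' whole 17 µm stream's share of the flux while the 10 µm stream passes
#' over the suction side.
#'
#' @param naca 4-digit NACA code as a string, default "9730".
#' @param chord Chord length (µm), default 300.
#' @param attack_angle Attack angle in degrees (nose-down rotation of the
#'   chord relative to the flow), default 30.
#' @param anchor Leading-edge position `c(x, y)` in µm, default `c(300, 195)`.
#' @return An object of class `hydrofoil_spec`.
#' @export
hydrofoil_spec <- function(naca = "9730", chord = 300, attack_angle = 30,
                           anchor = c(300, 195)) {
  stopifnot(chord > 0, length(anchor) == 2)
  parse_naca4(naca)  # validates
  structure(list(naca = naca, chord = chord, attack_angle = attack_angle,
                 anchor = as.numeric(anchor)),
            class = "hydrofoil_spec")
}

#' Separation wall specification
#'
#' A half-elliptic divider wall splitting the downstream channel into a CTC
#' outlet passage (between the reference wall and the divider) and a waste
#' (WBC) outlet passage. The nose is the half-ellipse tip; downstream of the
#' nose the wall continues as a straight divider of constant thickness equal
#' to `minor_diameter` up to the outlet boundary.
#'
#' @param minor_diameter Wall thickness across the channel (µm), default 50.
#' @param center_offset Distance of the wall centerline from the reference
#'   wall (µm), default 100 (coinciding with the 17 µm focal axis).
#' @param axial_position Axial position of the nose tip (µm), default 700.
#' @param nose_aspect Semi-major / semi-minor axis ratio of the elliptic
#'   nose, default 2 (a 50 µm long nose for a 25 µm semi-minor axis).
#' @return An object of class `separation_wall_spec`.
#' @export
separation_wall_spec <- function(minor_diameter = 50, center_offset = 100,
                                 axial_position = 700, nose_aspect = 2) {
  stopifnot(minor_diameter > 0, center_offset > 0, axial_position > 0,
            nose_aspect > 0)
  structure(list(minor_diameter = minor_diameter,
                 center_offset = center_offset,
                 axial_position = axial_position,
                 nose_aspect = nose_aspect),
            class = "separation_wall_spec")
}

# ---- NACA 4-digit section ----------------------------------------------

#' Parse a NACA 4-digit code
#'
#' @param code 4-digit string, e.g. "9730": max camber m = 9% of chord,
#'   camber position p = 70% of chord, thickness t = 30% of chord.
#' @return List with elements `m`, `p`, `t` (fractions of chord).
#' @export
parse_naca4 <- function(code) {
  if (!is.character(code) || length(code) != 1 ||
      !grepl("^[0-9]{4}$", code)) {
    stop("malformed NACA 4-digit code: ", deparse(code))
  }
  d <- as.integer(strsplit(code, "")[[1]])
  m <- d[1] / 100
  p <- d[2] / 10
  t <- (10 * d[3] + d[4]) / 100
  if (m > 0 && (p <= 0 || p >= 1)) {
    stop("cambered NACA code requires camber position digit in 1..9: ", code)
  }
  if (m > 0.095) stop("camber out of range: ", code)
  if (t <= 0 || t > 0.4) stop("thickness out of supported range: ", code)
  list(m = m, p = p, t = t)
}

# camber line y_c(x) and slope dy_c/dx for x in [0,1] chord units
naca4_camber <- function(x, m, p) {
  yc <- numeric(length(x))
  dyc <- numeric(length(x))
  if (m > 0) {
    fore <- x < p
    yc[fore] <- m / p^2 * (2 * p * x[fore] - x[fore]^2)
    dyc[fore] <- 2 * m / p^2 * (p - x[fore])
    aft <- !fore
    yc[aft] <- m / (1 - p)^2 * ((1 - 2 * p) + 2 * p * x[aft] - x[aft]^2)
    dyc[aft] <- 2 * m / (1 - p)^2 * (p - x[aft])
  }
  list(yc = yc, dyc = dyc)
}

# closed-trailing-edge thickness distribution (last coefficient -0.1036)
naca4_thickness <- function(x, t) {
  5 * t * (0.2969 * sqrt(x) - 0.1260 * x - 0.3516 * x^2 +
           0.2843 * x^3 - 0.1036 * x^4)
}

#' NACA 4-digit surface polygon
#'
#' Builds the standard NACA 4-digit section: piecewise-quadratic camber line
#' with its break at `p * chord`, thickness applied perpendicular to the
#' camber line, closed trailing edge. Points are cosine-spaced so the nose is
#' well resolved.
#'
#' @param code 4-digit NACA code string.
#' @param chord Chord length (µm).
#' @param n_points Number of chordwise stations per surface (>= 20).
#' @return A closed simple polygon: numeric matrix with columns `x`, `y`
#'   (µm), first vertex repeated as the last. Leading edge at the origin,
#'   chord along +x.
#' @export
naca4_profile <- function(code, chord, n_points = 100) {
  par <- parse_naca4(code)
  if (n_points < 20) stop("n_points too small for a non-degenerate polygon")
  stopifnot(chord > 0)
  beta <- seq(0, pi, length.out = n_points)
  x <- (1 - cos(beta)) / 2                      # cosine spacing in [0,1]
  cam <- naca4_camber(x, par$m, par$p)
  yt <- naca4_thickness(x, par$t)
  th <- atan(cam$dyc)
  xu <- x - yt * sin(th); yu <- cam$yc + yt * cos(th)
  xl <- x + yt * sin(th); yl <- cam$yc - yt * cos(th)
  # upper surface TE -> LE, then lower surface LE -> TE
  px <- c(rev(xu), xl[-1])
  py <- c(rev(yu), yl[-1])
  poly <- cbind(x = px * chord, y = py * chord)
  poly <- poly[!duplicated(round(poly, 10)), , drop = FALSE]
  poly <- rbind(poly, poly[1, ])
  if (!polygon_is_simple(poly)) stop("generated surface is self-intersecting")
  poly
}

# ---- polygon utilities --------------------------------------------------

#' Signed polygon area (shoelace)
#' @param poly Closed polygon matrix (first vertex == last vertex).
#' @return Signed area; positive for counter-clockwise orientation.
#' @export
polygon_area <- function(poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

# O(n^2) proper-intersection test between non-adjacent edges
polygon_is_simple <- function(poly, tol = 1e-9) {
  p <- poly[-nrow(poly), , drop = FALSE]
  n <- nrow(p)
  if (n < 3) return(FALSE)
  seg <- cbind(p, p[c(2:n, 1), ])
  cross2 <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(n - 2)) {
    j <- seq(i + 2, n)
    j <- j[!(i == 1 & j == n)]  # skip adjacent (wrap)
    if (!length(j)) next
    a <- seg[i, ]
    d1 <- cross2(a[1], a[2], a[3], a[4], seg[j, 1], seg[j, 2])
    d2 <- cross2(a[1], a[2], a[3], a[4], seg[j, 3], seg[j, 4])
    d3 <- cross2(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], a[1], a[2])
    d4 <- cross2(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], a[3], a[4])
    bad <- (d1 * d2 < -tol) & (d3 * d4 < -tol)
    if (any(bad)) return(FALSE)
  }
  TRUE
}

#' Point-in-polygon test (ray casting)
#'
#' @param x,y Numeric vectors of query coordinates.
#' @param poly Closed polygon matrix.
#' @return Logical vector, `TRUE` for points strictly inside.
#' @export
point_in_polygon <- function(x, y, poly) {
  px <- poly[-nrow(poly), 1]; py <- poly[-nrow(poly), 2]
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# minimum distance from points to polygon boundary (vectorized over segments)
dist_to_polygon <- function(x, y, poly) {
  ax <- poly[-nrow(poly), 1]; ay <- poly[-nrow(poly), 2]
  bx <- poly[-1, 1]; by <- poly[-1, 2]
  dx <- bx - ax; dy <- by - ay
  len2 <- pmax(dx^2 + dy^2, 1e-30)
  out <- numeric(length(x))
  for (k in seq_along(x)) {
    t <- pmin(1, pmax(0, ((x[k] - ax) * dx + (y[k] - ay) * dy) / len2))
    qx <- ax + t * dx; qy <- ay + t * dy
    out[k] <- sqrt(min((x[k] - qx)^2 + (y[k] - qy)^2))
  }
  out
}

# ---- placement ----------------------------------------------------------

#' Place a hydrofoil section in the channel
#'
#' Applies a rigid nose-down rotation by `attack_angle` about the leading
#' edge, then translates the leading edge to the anchor. A positive attack
#' angle rotates the trailing edge towards the reference wall (y = 0), which
#' is the orientation that deflects the large-particle stream towards that
#' wall.
#'
#' @param profile Closed polygon from [naca4_profile()] (leading edge at the
#'   origin, chord along +x).
#' @param spec A [hydrofoil_spec()].
#' @param channel_width Channel width (µm) used for the bounds check,
#'   default 300.
#' @return The transformed closed polygon (µm).
#' @export
place_hydrofoil <- function(profile, spec, channel_width = 300) {
  a <- -spec$attack_angle * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  out <- profile %*% t(R)
  out[, 1] <- out[, 1] + spec$anchor[1]
  out[, 2] <- out[, 2] + spec$anchor[2]
  colnames(out) <- c("x", "y")
  if (min(out[, 2]) < 0 || max(out[, 2]) > channel_width) {
    stop(sprintf(
      "placed hydrofoil exits channel bounds (y range %.1f..%.1f in 0..%g)",
      min(out[, 2]), max(out[, 2]), channel_width))
  }
  out
}

# separation wall polygon: half-ellipse nose + straight divider to x = length
wall_polygon <- function(wall, length, n_nose = 40) {
  b <- wall$minor_diameter / 2
  a <- wall$nose_aspect * b
  x0 <- wall$axial_position
  yc <- wall$center_offset
  if (x0 + a >= length) stop("wall nose extends beyond the domain outlet")
  th <- seq(pi, pi / 2, length.out = n_nose)      # tip -> top of ellipse
  nose_up <- cbind(x0 + a + a * cos(th), yc + b * sin(th))
  th2 <- seq(pi / 2, pi, length.out = n_nose)     # bottom of ellipse -> tip
  nose_dn <- cbind(x0 + a + a * cos(th2), yc - b * sin(th2))
  poly <- rbind(nose_up,                      # tip -> (x0+a, yc+b)
                c(length, yc + b),            # top edge to the outlet
                c(length, yc - b),            # down the outlet boundary
                nose_dn)                      # (x0+a, yc-b) -> tip (closes)
  colnames(poly) <- c("x", "y")
  poly
}

# ---- downstream domain --------------------------------------------------

#' Assemble the downstream simulation domain
#'
#' Builds the 2D separation region downstream of the spiral: a straight
#' channel segment carrying the focused streams, the placed hydrofoil (if
#' any), and the separation wall dividing the outlet section into a CTC
#' passage (reference-wall side) and a waste passage.
#'
#' @param spiral A [spiral_spec()] (provides channel width and depth).
#' @param foil A [hydrofoil_spec()] or `NULL` for the reference (no-foil)
#'   configuration.
#' @param wall A [separation_wall_spec()] or `NULL` for a single open outlet.
#' @param length Domain length along the flow (µm), default 800.
#' @param n_points Surface resolution for the hydrofoil polygon.
#' @return An object of class `downstream_domain`: a list with the channel
#'   size, solid polygons, outlet passage widths and boundary labels.
#' @export
build_downstream_domain <- function(spiral = spiral_spec(),
                                    foil = hydrofoil_spec(),
                                    wall = separation_wall_spec(),
                                    length = 800, n_points = 100) {
  w <- spiral$width
  foil_poly <- NULL
  if (!is.null(foil)) {
    foil_poly <- place_hydrofoil(naca4_profile(foil$naca, foil$chord,
                                               n_points),
                                 foil, channel_width = w)
    if (max(foil_poly[, 1]) >= length || min(foil_poly[, 1]) <= 0) {
      stop("hydrofoil extends beyond the domain in x")
    }
  }
  wall_poly <- NULL
  ctc_width <- w; waste_width <- 0
  if (!is.null(wall)) {
    if (wall$center_offset <= 0 || wall$center_offset >= w) {
      stop("wall center offset outside the channel")
    }
    ctc_width <- wall$center_offset - wall$minor_diameter / 2
    waste_width <- w - wall$center_offset - wall$minor_diameter / 2
    if (ctc_width <= 0 || waste_width <= 0) {
      stop("separation wall leaves no open outlet passage")
    }
    wall_poly <- wall_polygon(wall, length)
    if (!is.null(foil_poly)) {
      # solids must be pairwise disjoint
      if (any(point_in_polygon(foil_poly[, 1], foil_poly[, 2], wall_poly)) ||
          any(point_in_polygon(wall_poly[, 1], wall_poly[, 2], foil_poly))) {
        stop("hydrofoil and separation wall overlap")
      }
    }
  }
  structure(list(
    length = length, width = w, depth = spiral$depth,
    foil = foil_poly, wall = wall_poly,
    foil_spec = foil, wall_spec = wall, spiral = spiral,
    outlet_widths = c(ctc = ctc_width,
                      wall = if (is.null(wall)) 0 else wall$minor_diameter,
                      waste = waste_width),
    labels = list(inlet = "x = 0", ctc_outlet = sprintf(
      "x = %g, y in [0, %g]", length, ctc_width),
      waste_outlet = if (is.null(wall)) sprintf("x = %g, full width", length)
      else sprintf("x = %g, y in [%g, %g]", length,
                   wall$center_offset + wall$minor_diameter / 2, w))),
    class = "downstream_domain")
}

#' @export
print.downstream_domain <- function(x, ...) {
  cat("Downstream separation domain\n")
  cat(sprintf("  channel: %g x %g um (depth %g um)\n", x$length, x$width,
              x$depth))
  cat(sprintf("  hydrofoil: %s\n",
              if (is.null(x$foil)) "none" else
                sprintf("NACA%s chord %g um at %g deg, LE (%g, %g)",
                        x$foil_spec$naca, x$foil_spec$chord,
                        x$foil_spec$attack_angle, x$foil_spec$anchor[1],
                        x$foil_spec$anchor[2])))
  cat(sprintf("  outlet partition (ctc/wall/waste): %g / %g / %g um\n",
              x$outlet_widths[1], x$outlet_widths[2], x$outlet_widths[3]))
  invisible(x)
}

#' Spiral channel metrics
#'
#' Hydraulic diameter, loop pitch and centerline length of the Archimedean
#' spiral r = r0 + (pitch / 2 pi) theta, the length obtained by arc-length
#' quadrature over `loops` full turns.
#'
#' @param spec A [spiral_spec()].
#' @return List with `hydraulic_diameter` (µm), `centerline_length` (µm),
#'   `pitch` (µm) and `mean_radius` (µm).
#' @export
spiral_metrics <- function(spec) {
  w <- spec$width; h <- spec$depth
  dh <- 2 * w * h / (w + h)
  pitch <- w + spec$gap
  b <- pitch / (2 * pi)
  r0 <- spec$start_radius
  integrand <- function(theta) sqrt((r0 + b * theta)^2 + b^2)
  len <- stats::integrate(integrand, 0, spec$loops * 2 * pi,
                          rel.tol = 1e-10)$value
  list(hydraulic_diameter = dh, centerline_length = len, pitch = pitch,
       mean_radius = r0 + b * spec$loops * pi)
}

# ---- geometry export ----------------------------------------------------

#' Export domain geometry as CSV polygons and a JSON descriptor
#'
#' Writes one `<name>.csv` (columns `x_um`, `y_um`) per solid polygon plus a
#' `domain.json` descriptor with widths, labels and offsets.
#'
#' @param domain A `downstream_domain`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_domain_geometry <- function(domain, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (name in c("foil", "wall")) {
    poly <- domain[[name]]
    if (is.null(poly)) next
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(data.frame(x_um = poly[, 1], y_um = poly[, 2]), p,
                     row.names = FALSE)
    paths <- c(paths, p)
  }
  desc <- list(length_um = domain$length, width_um = domain$width,
               depth_um = domain$depth,
               outlet_widths_um = as.list(domain$outlet_widths),
               labels = domain$labels)
  jp <- file.path(dir, "domain.json")
  jsonlite::write_json(desc, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}
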