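# Passive finite-size particle transport: seed particles from discretized
# stream distributions, advect them through the solved flow field with a
# one-radius wall standoff, classify outlet arrivals and measure the
# downstream stream distributions.
#
# Particles are passive tracers: inertial lift and Dean drag act in the
# spiral upstream (where they set the focused inlet distributions), not in
# this short downstream segment. The only non-streamline ingredient is the
# finite-radius standoff from walls and solids.

# cell-centered bilinear interpolation of a (nx, ny) grid
interp_cc <- function(mat, x, y, h, nx, ny) {
  fx <- x / h + 0.5
  fy <- y / h + 0.5
  i0 <- pmin(pmax(floor(fx), 1), nx - 1); tx <- fx - i0
  j0 <- pmin(pmax(floor(fy), 1), ny - 1); ty <- fy - j0
  (1 - tx) * (1 - ty) * mat[cbind(i0, j0)] +
    tx * (1 - ty) * mat[cbind(i0 + 1, j0)] +
    (1 - tx) * ty * mat[cbind(i0, j0 + 1)] +
    tx * ty * mat[cbind(i0 + 1, j0 + 1)]
}

# distance (µm) from cell centers to the nearest solid polygon boundary,
# negative inside; Inf when the domain has no solids
solid_distance_grid <- function(field) {
  nx <- field$nx; ny <- field$ny; h <- field$h_um
  xs <- (seq_len(nx) - 0.5) * h
  ys <- (seq_len(ny) - 0.5) * h
  gx <- rep(xs, times = ny); gy <- rep(ys, each = nx)
  dmin <- rep(Inf, nx * ny)
  inside <- rep(FALSE, nx * ny)
  for (poly in list(field$domain$foil, field$domain$wall)) {
    if (is.null(poly)) next
    ax <- poly[-nrow(poly), 1]; ay <- poly[-nrow(poly), 2]
    bx <- poly[-1, 1]; by <- poly[-1, 2]
    dx <- bx - ax; dy <- by - ay
    len2 <- pmax(dx^2 + dy^2, 1e-30)
    dp <- rep(Inf, nx * ny)
    for (s in seq_along(ax)) {
      t <- pmin(1, pmax(0, ((gx - ax[s]) * dx[s] + (gy - ay[s]) * dy[s]) /
                          len2[s]))
      qx <- ax[s] + t * dx[s]; qy <- ay[s] + t * dy[s]
      dp <- pmin(dp, (gx - qx)^2 + (gy - qy)^2)
    }
    dp <- sqrt(dp)
    dmin <- pmin(dmin, dp)
    inside <- inside | point_in_polygon(gx, gy, poly)
  }
  d <- matrix(dmin, nx, ny)
  d[matrix(inside, nx, ny)] <- -d[matrix(inside, nx, ny)]
  d
}

# standoff geometry: distance and inward normal at points, combining the
# solid polygons (via the cached grid) and the channel walls (analytic)
standoff_eval <- function(env, x, y) {
  W <- env$W
  d_wall <- pmin(y, W - y)
  n_wall_y <- ifelse(y < W / 2, 1, -1)
  if (is.null(env$dgrid)) {
    return(list(d = d_wall, nx = rep(0, length(x)), ny = n_wall_y))
  }
  dp <- interp_cc(env$dgrid, x, y, env$h, env$nx, env$ny)
  # gradient of the polygon distance field
  eps <- env$h
  gxp <- (interp_cc(env$dgrid, pmin(x + eps, env$L - 1e-9), y, env$h,
                    env$nx, env$ny) -
          interp_cc(env$dgrid, pmax(x - eps, 1e-9), y, env$h,
                    env$nx, env$ny)) / (2 * eps)
  gyp <- (interp_cc(env$dgrid, x, pmin(y + eps, W - 1e-9), env$h,
                    env$nx, env$ny) -
          interp_cc(env$dgrid, x, pmax(y - eps, 1e-9), env$h,
                    env$nx, env$ny)) / (2 * eps)
  gn <- pmax(sqrt(gxp^2 + gyp^2), 1e-9)
  use_wall <- d_wall < dp
  list(d = pmin(d_wall, dp),
       nx = ifelse(use_wall, 0, gxp / gn),
       ny = ifelse(use_wall, n_wall_y, gyp / gn))
}

#' Seed particles from discretized stream distributions
#'
#' One particle per discretization bin per class, released at the inlet
#' station with the bin weight. Seeding positions are clamped to at least
#' one particle radius off the channel walls; bins falling inside a solid
#' are dropped with a warning and the class weights renormalized.
#'
#' @param dists List of discretized [stream_distribution()]s (one per
#'   class; run [discretize()] first).
#' @param domain A `downstream_domain`.
#' @param radii Particle radii (µm), one per class.
#' @param labels Class labels; defaults to the distribution labels or
#'   `class1`, `class2`, ...
#' @param x_seed Release station (µm), default 5.
#' @return `data.frame` with columns `x`, `y`, `radius`, `class`, `weight`.
#' @export
seed_particles <- function(dists, domain, radii, labels = NULL,
                           x_seed = 5) {
  stopifnot(length(dists) == length(radii))
  if (is.null(labels)) {
    labels <- vapply(seq_along(dists), function(k) {
      if (!is.null(dists[[k]]$label)) dists[[k]]$label else
        paste0("class", k)
    }, character(1))
  }
  out <- NULL
  for (k in seq_along(dists)) {
    b <- dists[[k]]$bins
    if (is.null(b)) stop("distribution ", k, " has no bins; discretize first")
    y <- pmin(pmax(b[, "position"], radii[k]),
              domain$width - radii[k])
    keep <- rep(TRUE, length(y))
    for (poly in list(domain$foil, domain$wall)) {
      if (!is.null(poly)) {
        keep <- keep & !point_in_polygon(rep(x_seed, length(y)), y, poly)
      }
    }
    w <- b[, "weight"]
    if (!all(keep)) {
      warning(sum(!keep), " seeding bins inside solids dropped; ",
              "weights renormalized")
      y <- y[keep]; w <- w[keep] / sum(w[keep])
    }
    out <- rbind(out, data.frame(x = x_seed, y = y, radius = radii[k],
                                 class = labels[k], weight = w))
  }
  out
}

# vectorized advection engine; returns terminal state and measurement
# crossings, optionally full trajectories
advect_engine <- function(field, particles, ds = 1, max_steps = NULL,
                          x_meas = NULL, record = FALSE) {
  n <- nrow(particles)
  env <- list(W = field$width_um, L = field$length_um, h = field$h_um,
              nx = field$nx, ny = field$ny,
              dgrid = if (is.null(field$domain$foil) &&
                          is.null(field$domain$wall)) NULL else
                solid_distance_grid(field))
  x <- particles$x; y <- particles$y; r <- particles$radius
  if (is.null(max_steps)) max_steps <- ceiling(5 * field$length_um / ds)
  x_end <- field$length_um - 1.5 * field$h_um
  active <- rep(TRUE, n)
  status <- rep("active", n)
  y_meas <- rep(NA_real_, n)
  y_exit <- rep(NA_real_, n)
  slow_count <- integer(n)
  traj <- if (record) lapply(seq_len(n), function(i) {
    list(x = x[i], y = y[i])
  }) else NULL
  u_ref <- field$u_avg
  vel <- function(px, py) {
    px <- pmin(pmax(px, 0), env$L); py <- pmin(pmax(py, 0), env$W)
    cbind(interp_u(field, px, py), interp_v(field, px, py))
  }
  for (step in seq_len(max_steps)) {
    idx <- which(active)
    if (!length(idx)) break
    px <- x[idx]; py <- y[idx]; pr <- r[idx]
    k1 <- vel(px, py)
    sp <- sqrt(k1[, 1]^2 + k1[, 2]^2)
    # stall detection: speed persistently far below the mean flow
    slow <- sp < 1e-4 * u_ref
    slow_count[idx] <- ifelse(slow, slow_count[idx] + 1L, 0L)
    stuck <- slow_count[idx] > 25L
    if (any(stuck)) {
      status[idx[stuck]] <- "stuck"
      active[idx[stuck]] <- FALSE
    }
    live <- !stuck
    if (!any(live)) next
    il <- idx[live]
    px <- px[live]; py <- py[live]; pr <- pr[live]
    k1 <- k1[live, , drop = FALSE]
    sp <- pmax(sp[live], 1e-6 * u_ref)
    dt <- ds / (sp * 1e6)   # s; field is m/s, coordinates µm
    s1 <- 1e6 * dt          # µm travelled per unit (m/s)
    k2 <- vel(px + 0.5 * s1 * k1[, 1], py + 0.5 * s1 * k1[, 2])
    k3 <- vel(px + 0.5 * s1 * k2[, 1], py + 0.5 * s1 * k2[, 2])
    k4 <- vel(px + s1 * k3[, 1], py + s1 * k3[, 2])
    vx <- (k1[, 1] + 2 * k2[, 1] + 2 * k3[, 1] + k4[, 1]) / 6
    vy <- (k1[, 2] + 2 * k2[, 2] + 2 * k3[, 2] + k4[, 2]) / 6
    # tangential projection within the standoff band (moving into surface)
    so <- standoff_eval(env, px, py)
    near <- so$d < pr + 0.5 & (vx * so$nx + vy * so$ny) < 0
    if (any(near)) {
      dot <- vx[near] * so$nx[near] + vy[near] * so$ny[near]
      vx[near] <- vx[near] - dot * so$nx[near]
      vy[near] <- vy[near] - dot * so$ny[near]
    }
    nx_ <- px + s1 * vx
    ny_ <- py + s1 * vy
    ny_ <- pmin(pmax(ny_, pr), env$W - pr)
    # positional standoff correction against solids
    so2 <- standoff_eval(env, nx_, ny_)
    pen <- so2$d < pr
    if (any(pen)) {
      corr <- (pr - so2$d)[pen]
      nx_[pen] <- nx_[pen] + corr * so2$nx[pen]
      ny_[pen] <- ny_[pen] + corr * so2$ny[pen]
      ny_[pen] <- pmin(pmax(ny_[pen], pr[pen]), env$W - pr[pen])
    }
    nx_ <- pmax(nx_, 0)
    # measurement-station crossing (linear interpolation in x)
    if (!is.null(x_meas)) {
      crossed <- is.na(y_meas[il]) & px < x_meas & nx_ >= x_meas
      if (any(crossed)) {
        f <- (x_meas - px[crossed]) / pmax(nx_[crossed] - px[crossed], 1e-12)
        y_meas[il[crossed]] <- py[crossed] +
          f * (ny_[crossed] - py[crossed])
      }
    }
    x[il] <- nx_; y[il] <- ny_
    if (record) {
      for (m in seq_along(il)) {
        traj[[il[m]]]$x <- c(traj[[il[m]]]$x, nx_[m])
        traj[[il[m]]]$y <- c(traj[[il[m]]]$y, ny_[m])
      }
    }
    done <- nx_ >= x_end
    if (any(done)) {
      status[il[done]] <- "exited"
      y_exit[il[done]] <- ny_[done]
      active[il[done]] <- FALSE
    }
  }
  status[active] <- "stuck"
  list(x = x, y = y, status = status, y_meas = y_meas, y_exit = y_exit,
       traj = traj)
}

#' Advect a single particle through the flow field
#'
#' 4th-order Runge-Kutta streamline integration with an adaptive time step
#' bounded by a 1 µm spatial step, a one-radius boundary standoff
#' (tangential velocity projection plus positional correction) and
#' termination on outlet crossing, stagnation or step-budget exhaustion.
#'
#' @param field A `flow_field`.
#' @param x,y Release position (µm).
#' @param radius Particle radius (µm).
#' @param ds Spatial step (µm), default 1.
#' @param max_steps Step budget, default 5 domain lengths.
#' @return An object of class `trajectory`: list with `x`, `y` polylines,
#'   terminal `status` (`exited`/`stuck`) and `outlet` label.
#' @export
advect <- function(field, x, y, radius = 0, ds = 1, max_steps = NULL) {
  p <- data.frame(x = x, y = y, radius = radius, class = "p", weight = 1)
  res <- advect_engine(field, p, ds = ds, max_steps = max_steps,
                       record = TRUE)
  structure(list(x = res$traj[[1]]$x, y = res$traj[[1]]$y,
                 status = res$status[1],
                 outlet = classify_outlet(field$domain, res$status[1],
                                          res$x[1], res$y[1])),
            class = "trajectory")
}

# outlet label for one terminal state
classify_outlet <- function(domain, status, x, y) {
  if (status != "exited") return("stuck")
  if (is.null(domain$wall)) return("outlet")
  if (y < domain$wall_spec$center_offset) "ctc" else "waste"
}

#' Simulate the downstream separation
#'
#' Seeds every discretized bin of every particle class, advects all
#' particles through the flow field, accumulates weighted outlet fractions
#' per class, and measures the downstream stream distributions at a station
#' one wall-minor-diameter upstream of the wall nose, from which the
#' downstream separation resolution is computed.
#'
#' Stuck particles stalled within one standoff of the wall nose are
#' assigned to the outlet matching their side of the wall centerline
#' (centerline hits go to waste, the conservative choice for recovery
#' claims); any other stuck weight above `stuck_tol` raises an error.
#'
#' @param domain A `downstream_domain`.
#' @param field The solved `flow_field` for that domain.
#' @param dists List of discretized [stream_distribution()]s per class.
#' @param radii Particle radii (µm) per class.
#' @param labels Optional class labels.
#' @param ds Advection spatial step (µm), default 1.
#' @param stuck_tol Tolerated stuck weight fraction per class, default 0.05.
#' @return An object of class `separation_outcome`: per-class fractions to
#'   each outlet, downstream distributions, upstream and downstream
#'   resolution, and the flow split.
#' @export
simulate_separation <- function(domain, field, dists, radii,
                                labels = NULL, ds = 1, stuck_tol = 0.05) {
  parts <- seed_particles(dists, domain, radii, labels)
  x_meas <- if (!is.null(domain$wall)) {
    domain$wall_spec$axial_position - domain$wall_spec$minor_diameter
  } else domain$length - 2 * field$h_um
  res <- advect_engine(field, parts, ds = ds, x_meas = x_meas)
  cls <- unique(parts$class)
  frac <- list()
  downstream <- list()
  for (cl in cls) {
    sel <- parts$class == cl
    w <- parts$weight[sel]
    st <- res$status[sel]
    lab <- vapply(which(sel), function(i) {
      s <- res$status[i]
      if (s == "stuck" && !is.null(domain$wall)) {
        ws <- domain$wall_spec
        near_nose <- abs(res$x[i] - ws$axial_position) <
          ws$minor_diameter + parts$radius[i] &&
          abs(res$y[i] - ws$center_offset) <= ws$minor_diameter
        if (near_nose) {
          return(if (res$y[i] < ws$center_offset) "ctc" else "waste")
        }
      }
      classify_outlet(domain, s, res$x[i], res$y[i])
    }, character(1))
    f_ctc <- sum(w[lab == "ctc"])
    f_waste <- sum(w[lab == "waste" | lab == "outlet"])
    f_stuck <- sum(w[lab == "stuck"])
    if (f_stuck > stuck_tol) {
      stop(sprintf("class %s: %.1f%% of weight stuck in the domain", cl,
                   100 * f_stuck))
    }
    frac[[cl]] <- c(ctc = f_ctc, waste = f_waste, stuck = f_stuck)
    ym <- res$y_meas[sel]
    okm <- !is.na(ym)
    if (sum(okm) >= 3) {
      downstream[[cl]] <- downstream_distribution(ym[okm], w[okm],
                                                  label = cl)
    }
  }
  r_up <- if (length(dists) == 2) resolution(dists[[1]], dists[[2]]) else NULL
  r_down <- if (length(downstream) == 2) {
    resolution(downstream[[1]], downstream[[2]])
  } else NULL
  structure(list(fractions = frac, downstream = downstream,
                 resolution_upstream = r_up, resolution_downstream = r_down,
                 flow_split = field$split_ctc, outlet_dp = field$outlet_dp,
                 x_meas = x_meas, particles = parts, status = res$status),
            class = "separation_outcome")
}

#' @export
print.separation_outcome <- function(x, ...) {
  cat("Separation outcome\n")
  for (cl in names(x$fractions)) {
    f <- x$fractions[[cl]]
    cat(sprintf("  %-10s ctc %5.1f%%  waste %5.1f%%  stuck %4.1f%%\n", cl,
                100 * f["ctc"], 100 * f["waste"], 100 * f["stuck"]))
  }
  if (!is.null(x$resolution_upstream)) {
    cat(sprintf("  R upstream   = %.2f\n", x$resolution_upstream$R))
  }
  if (!is.null(x$resolution_downstream)) {
    cat(sprintf("  R downstream = %.2f (station x = %g um)\n",
                x$resolution_downstream$R, x$x_meas))
  }
  if (!is.na(x$flow_split)) {
    cat(sprintf("  CTC flow split = %.1f%%\n", 100 * x$flow_split))
  }
  invisible(x)
}

#' Wall panning study
#'
#' Re-solves the flow and re-classifies the particles for a series of
#' lateral separation-wall offsets (positive values pan the wall towards
#' the waste side, widening the CTC passage), keeping the calibrated
#' outlet back-pressure of the base configuration.
#'
#' @param spiral,foil,wall,length Domain ingredients as in
#'   [build_downstream_domain()] (the wall spec provides the base offset).
#' @param config A [flow_config()].
#' @param dists,radii As in [simulate_separation()].
#' @param offsets Lateral offsets (µm) to add to the wall center, default
#'   `c(0, 12.5, 25)`.
#' @param outlet_dp Calibrated outlet back-pressure (Pa), default 0.
#' @param ds Advection step (µm).
#' @return `data.frame` with one row per offset: wall position, CTC passage
#'   width, per-class CTC fractions and the flow split.
#' @export
wall_panning_study <- function(spiral = spiral_spec(), foil = NULL,
                               wall = separation_wall_spec(),
                               length = 800, config = flow_config(),
                               dists, radii, offsets = c(0, 12.5, 25),
                               outlet_dp = 0, ds = 1) {
  rows <- NULL
  for (off in offsets) {
    w2 <- wall
    w2$center_offset <- wall$center_offset + off
    dom <- build_downstream_domain(spiral, foil, w2, length)
    fld <- solve_flow(dom, config, outlet_dp = outlet_dp)
    out <- simulate_separation(dom, fld, dists, radii, ds = ds)
    row <- data.frame(offset = off, wall_center = w2$center_offset,
                      ctc_width = dom$outlet_widths[["ctc"]],
                      flow_split = fld$split_ctc)
    for (cl in names(out$fractions)) {
      row[[paste0(cl, "_to_ctc")]] <- out$fractions[[cl]][["ctc"]]
    }
    rows <- rbind(rows, row)
  }
  rows
}

#' Export trajectories as CSV
#'
#' Columns `particle_id`, `class`, `step`, `x_um`, `y_um`.
#'
#' @param trajectories List of `trajectory` objects.
#' @param classes Class label per trajectory.
#' @param path Output path.
#' @export
write_trajectories <- function(trajectories, classes, path) {
  rows <- do.call(rbind, lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    data.frame(particle_id = i, class = classes[i],
               step = seq_along(tr$x) - 1L, x_um = tr$x, y_um = tr$y)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
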