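# Shared fixtures: expensive flow solves are computed once per test run and
# reused across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache)
}

# coarse, fast configuration for unit-level flow tests
test_flow_config <- function(resolution = 6, depth_friction = FALSE, ...) {
  flow_config(resolution = resolution, max_steps = 8000,
              steady_tol = 1e-4, depth_friction = depth_friction, ...)
}

# open straight channel, ideal plane-Poiseuille limit
empty_field <- function() {
  cached("empty_field", {
    dom <- build_downstream_domain(spiral_spec(), NULL, NULL, length = 300)
    solve_flow(dom, test_flow_config())
  })
}

# the full desk-scale separation study (reference + hydrofoil)
full_study <- function() {
  cached("full_study", {
    suppressWarnings(run_separation_study(
      config = flow_config(resolution = 4, max_steps = 30000)))
  })
}

# a hand-built uniform axial field with no solids (for transport kinematics)
uniform_field <- function(u0 = 0.5, length = 200, width = 300, h = 10) {
  nx <- length / h; ny <- width / h
  dom <- list(length = length, width = width, depth = 100, foil = NULL,
              wall = NULL, wall_spec = NULL,
              outlet_widths = c(ctc = width, wall = 0, waste = 0))
  class(dom) <- "downstream_domain"
  structure(list(
    u = matrix(u0, nx + 1, ny), v = matrix(0, nx, ny + 1),
    p = matrix(0, nx, ny), solid = matrix(FALSE, nx, ny),
    h_um = h, nx = nx, ny = ny, length_um = length, width_um = width,
    flux_in = u0 * width * 1e-6, u_avg = u0, domain = dom,
    config = NULL, outlet_dp = 0, steps = 0, resid = 0, converged = TRUE,
    split_ctc = NA), class = "flow_field")
}
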