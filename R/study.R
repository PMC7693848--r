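# High-level workflows binding the stages together: the simulation study
# (geometry -> flow -> transport -> resolutions) and the enrichment
# statistics study (count tables -> performance metrics), with JSON/CSV
# reporting. These functions are the package's entry points; each report
# carries a provenance block (package version, seeds, solver settings).

#' Canonical inlet stream distributions
#'
#' The package's default focused-stream model: the 17 µm (CTC-like) class
#' peaks 100 µm from the reference wall and the 10 µm (WBC-like) class at
#' 160 µm, both with a 15.8 µm half-height width — the widths that give the
#' upstream separation resolution of 2.24 for a 60 µm peak separation.
#'
#' @param n_bins Discretization bins per class, default 50.
#' @param span_sigmas Discretization half-span in sigmas, default 3.
#' @param channel_width Channel width (µm), default 300.
#' @return List of two discretized [stream_distribution()]s (17 µm class
#'   first).
#' @export
canonical_distributions <- function(n_bins = 50, span_sigmas = 3,
                                    channel_width = 300) {
  d17 <- discretize(stream_distribution(100, fwhm = 15.8,
                                        label = "CTC-17um"),
                    n_bins, span_sigmas, channel_width)
  d10 <- discretize(stream_distribution(160, fwhm = 15.8,
                                        label = "WBC-10um"),
                    n_bins, span_sigmas, channel_width)
  list(d17, d10)
}

#' Run the downstream separation study
#'
#' The full simulation workflow: build the domain, calibrate the outlet
#' network back-pressure on the reference (no-hydrofoil) geometry, solve
#' the flow with and without the hydrofoil, advect both particle classes,
#' and report recoveries, flow splits and upstream/downstream resolutions.
#'
#' @param spiral,foil,wall,length Domain ingredients as in
#'   [build_downstream_domain()].
#' @param config A [flow_config()]; for production use a resolution of
#'   5 µm or finer.
#' @param dists Discretized inlet distributions, default
#'   [canonical_distributions()].
#' @param radii Particle radii (µm), default `c(8.5, 5)`.
#' @param with_hydrofoil Also run the hydrofoil configuration, default TRUE.
#' @param ds Advection step (µm), default 1.
#' @param quiet Suppress solver progress, default TRUE.
#' @return An object of class `separation_study`: the calibration, the
#'   reference and (optionally) hydrofoil outcomes and fields.
#' @export
run_separation_study <- function(spiral = spiral_spec(),
                                 foil = hydrofoil_spec(),
                                 wall = separation_wall_spec(),
                                 length = 800,
                                 config = flow_config(resolution = 4),
                                 dists = canonical_distributions(),
                                 radii = c(8.5, 5),
                                 with_hydrofoil = TRUE, ds = 1,
                                 quiet = TRUE) {
  dom_ref <- build_downstream_domain(spiral, NULL, wall, length)
  cal <- calibrate_outlet_bc(dom_ref, config, quiet = quiet)
  out_ref <- simulate_separation(dom_ref, cal$field, dists, radii, ds = ds)
  out_foil <- NULL; fld_foil <- NULL; dom_foil <- NULL
  if (with_hydrofoil) {
    dom_foil <- build_downstream_domain(spiral, foil, wall, length)
    fld_foil <- solve_flow(dom_foil, config, quiet = quiet,
                           outlet_dp = cal$outlet_dp)
    out_foil <- simulate_separation(dom_foil, fld_foil, dists, radii,
                                    ds = ds)
  }
  structure(list(
    calibration = list(outlet_dp = cal$outlet_dp, split = cal$split),
    reference = out_ref, hydrofoil = out_foil,
    field_reference = cal$field, field_hydrofoil = fld_foil,
    domain_reference = dom_ref, domain_hydrofoil = dom_foil,
    config = config),
    class = "separation_study")
}

#' @export
print.separation_study <- function(x, ...) {
  cat("Hydrofoil separation study\n")
  cat(sprintf("  outlet back-pressure: %.1f Pa (reference split %.1f%%)\n",
              x$calibration$outlet_dp, 100 * x$calibration$split))
  cat("-- reference (no hydrofoil) --\n")
  print(x$reference)
  if (!is.null(x$hydrofoil)) {
    cat("-- with hydrofoil --\n")
    print(x$hydrofoil)
  }
  invisible(x)
}

#' Study report as a JSON-ready list (and optional file)
#'
#' @param study A `separation_study`.
#' @param path Optional JSON output path.
#' @return Invisibly, the report list.
#' @export
study_report <- function(study, path = NULL) {
  fr <- function(out) {
    if (is.null(out)) return(NULL)
    list(fractions = lapply(out$fractions, as.list),
         R_upstream = if (!is.null(out$resolution_upstream))
           out$resolution_upstream$R else NA,
         R_downstream = if (!is.null(out$resolution_downstream))
           out$resolution_downstream$R else NA,
         flow_split_ctc = out$flow_split)
  }
  rep <- list(
    provenance = list(
      package = "spiralfoil",
      version = as.character(utils::packageVersion("spiralfoil")),
      resolution_um = study$config$resolution,
      outlet_dp_pa = study$calibration$outlet_dp),
    reference = fr(study$reference),
    hydrofoil = fr(study$hydrofoil))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(rep)
}

#' Enrichment statistics report
#'
#' Computes the full performance panel from count objects: bead metrics
#' when bead counts are given, two-cycle depletion/recovery, enrichment
#' factor, viability losses, the linear-fit spiking recovery and the cycle
#' volume bookkeeping.
#'
#' @param cycle A [cycle_counts()] or NULL.
#' @param beads A [bead_counts()] or NULL.
#' @param viability A [viability_counts()] or NULL.
#' @param spiking A [spiking_series()] (or list of them) or NULL.
#' @param volumes Optional list with `input_volume_ml`, `split_ratio`,
#'   `flow_rate_ml_min` for [cycle_bookkeeping()].
#' @param path Optional JSON output path.
#' @return List of metric blocks (equation-keyed where applicable).
#' @export
enrichment_report <- function(cycle = NULL, beads = NULL, viability = NULL,
                              spiking = NULL, volumes = NULL, path = NULL) {
  rep <- list(provenance = list(
    package = "spiralfoil",
    version = as.character(utils::packageVersion("spiralfoil"))))
  if (!is.null(beads)) {
    rep$beads <- list(eq4_recovery_pct = bead_recovery(beads),
                      eq5_purity_pct = bead_purity(beads))
  }
  if (!is.null(cycle)) {
    dep1 <- wbc_depletion(cycle, 1)
    res <- list(eq6_depletion_c1_pct = dep1)
    if (!is.na(cycle$wbc_ctc_c2)) {
      dep2 <- wbc_depletion(cycle, 2)
      res$eq7_depletion_c2_pct <- dep2
      res$enrichment_factor <- as.numeric(enrichment_factor(dep2))
    } else {
      res$enrichment_factor <- as.numeric(enrichment_factor(dep1))
    }
    if (!is.na(cycle$mcf7_inlet)) {
      if (!is.na(cycle$mcf7_waste_c1)) {
        res$eq8_recovery_c1_pct <- ctc_recovery(cycle, 1)
      }
      if (!is.na(cycle$mcf7_waste_c2)) {
        res$eq9_recovery_c2_pct <- ctc_recovery(cycle, 2)
      }
    }
    rep$cycles <- res
  }
  if (!is.null(viability)) {
    cl <- cell_loss(viability)
    rep$viability <- list(eq10_viable_loss_pct = cl$viable_loss,
                          eq11_total_loss_pct = cl$total_loss,
                          viability_in_pct = cl$viability_in,
                          viability_out_pct = cl$viability_out)
  }
  if (!is.null(spiking)) {
    if (inherits(spiking, "spiking_series")) spiking <- list(spiking)
    rep$spiking <- lapply(spiking, function(s) {
      fit <- linear_fit_recovery(s)
      list(recovery_pct = fit$rate, r_squared = fit$r_squared)
    })
  }
  if (!is.null(volumes)) {
    rep$bookkeeping <- do.call(cycle_bookkeeping, volumes)
  }
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  rep
}

#' Analyze a cross-channel intensity profile
#'
#' The profile workflow: two-Gaussian fit, discretization into seeding
#' weights and the separation resolution of the fitted streams.
#'
#' @param profile An [intensity_profile()] or a path to a profile CSV.
#' @param n_bins,span_sigmas Discretization parameters.
#' @param channel_width Channel width (µm), default 300.
#' @param path Optional JSON output path.
#' @return List with the fitted distributions, the resolution and fit
#'   diagnostics.
#' @export
analyze_profile <- function(profile, n_bins = 50, span_sigmas = 3,
                            channel_width = 300, path = NULL) {
  if (is.character(profile)) profile <- read_intensity_profile(profile)
  fit <- fit_two_gaussians(profile)
  degen <- isTRUE(attr(fit, "degenerate"))
  out <- list(degenerate = degen,
              residual_norm = attr(fit, "residual_norm"))
  if (!degen) {
    d1 <- discretize(fit[[1]], n_bins, span_sigmas, channel_width)
    d2 <- discretize(fit[[2]], n_bins, span_sigmas, channel_width)
    r <- resolution(d1, d2)
    out$distributions <- list(d1, d2)
    out$peaks_um <- c(d1$peak, d2$peak)
    out$fwhms_um <- c(d1$fwhm, d2$fwhm)
    out$resolution <- r$R
  } else {
    out$distributions <- fit
    out$peaks_um <- fit[[1]]$peak
  }
  if (!is.null(path)) {
    keep <- out[setdiff(names(out), "distributions")]
    jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  out
}
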