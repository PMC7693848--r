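# Seeded synthetic-data generators. These emulate the inputs the analysis
# consumes: the two-peak bead intensity profile across the channel, spiking
# dilution series with per-cell binomial capture, two-cycle WBC carryover
# counts, and Trypan-blue viability counts.

#' Synthetic-data configuration
#'
#' Defaults encode the study conditions the pipeline is designed around:
#' bead focal peaks at 100 and 160 µm with 15.8 µm half-height widths
#' (upstream resolution 2.24), cycle-1 CTC capture probability 0.771 with a
#' conditional cycle-2 capture of 0.655/0.771 = 0.849 (two-cycle recovery
#' 65.5%), WBC carryover 0.369 in cycle 1 and conditional 0.317 in cycle 2
#' (cumulative depletion 88.3%), 15 spiking levels between 50 and 3500 cells
#' (serial dilution, geometric spacing), and 81.6% inlet viability.
#'
#' @param seed Integer seed recorded in all outputs.
#' @param peaks Peak positions (µm), default `c(100, 160)` (17 µm then
#'   10 µm class).
#' @param fwhms Half-height widths (µm), default `c(15.8, 15.8)`.
#' @param amplitudes Peak amplitudes, default `c(1, 1)`.
#' @param baseline Constant intensity baseline, default 0.05.
#' @param noise_sd Additive zero-mean Gaussian intensity noise, default 0.02.
#' @param capture_probs Per-cycle CTC capture `c(p1, p2_conditional)`,
#'   default `c(0.771, 0.655/0.771)`.
#' @param wbc_carryover Per-cycle WBC carryover to the CTC outlet
#'   `c(c1, c2_conditional)`, default `c(0.369, (1-0.883)/(1-0.631))`.
#' @param spiking_levels Spiked-cell counts, default 15 geometrically spaced
#'   levels from 50 to 3500.
#' @param inlet_viability Viable fraction at the inlet, default 0.816.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         peaks = c(100, 160),
                         fwhms = c(15.8, 15.8),
                         amplitudes = c(1, 1),
                         baseline = 0.05,
                         noise_sd = 0.02,
                         capture_probs = c(0.771, 0.655 / 0.771),
                         wbc_carryover = c(0.369, (1 - 0.883) / (1 - 0.631)),
                         spiking_levels = round(exp(seq(log(50), log(3500),
                                                        length.out = 15))),
                         inlet_viability = 0.816) {
  stopifnot(length(peaks) == 2, length(fwhms) == 2, all(fwhms > 0),
            all(capture_probs >= 0 & capture_probs <= 1),
            all(wbc_carryover >= 0 & wbc_carryover <= 1),
            inlet_viability >= 0, inlet_viability <= 1,
            length(spiking_levels) >= 3, noise_sd >= 0)
  structure(list(seed = as.integer(seed), peaks = peaks, fwhms = fwhms,
                 amplitudes = amplitudes, baseline = baseline,
                 noise_sd = noise_sd, capture_probs = capture_probs,
                 wbc_carryover = wbc_carryover,
                 spiking_levels = spiking_levels,
                 inlet_viability = inlet_viability),
            class = "synth_config")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a two-peak cross-channel intensity profile
#'
#' Sum of two Gaussians at the configured peaks/widths plus a constant
#' baseline and additive zero-mean Gaussian noise; deterministic for a fixed
#' seed.
#'
#' @param cfg A [synth_config()].
#' @param n_samples Number of positions across the channel (>= 32).
#' @param channel_width Channel width (µm), default 300.
#' @return An [intensity_profile()] with attribute `seed`.
#' @export
gen_intensity_profile <- function(cfg = synth_config(), n_samples = 256,
                                  channel_width = 300) {
  stopifnot(n_samples >= 32)
  x <- seq(channel_width / (2 * n_samples),
           channel_width - channel_width / (2 * n_samples),
           length.out = n_samples)
  s <- cfg$fwhms / (2 * sqrt(2 * log(2)))
  y <- cfg$baseline +
    cfg$amplitudes[1] * exp(-(x - cfg$peaks[1])^2 / (2 * s[1]^2)) +
    cfg$amplitudes[2] * exp(-(x - cfg$peaks[2])^2 / (2 * s[2]^2))
  if (cfg$noise_sd > 0) {
    y <- y + with_seed(cfg$seed, rnorm(n_samples, 0, cfg$noise_sd))
  }
  out <- intensity_profile(x, y)
  attr(out, "seed") <- cfg$seed
  out
}

#' Generate a binomial spiking series
#'
#' For each spiking level n the number of recovered cells is drawn as
#' Binomial(n, p) with p the capture probability of the requested cycle
#' (cycle 2 uses the cumulative two-cycle probability p1 * p2_conditional).
#'
#' @param cfg A [synth_config()].
#' @param cycle 1 or 2.
#' @return A [spiking_series()] with attribute `seed` and `capture_prob`.
#' @export
gen_spiking_series <- function(cfg = synth_config(), cycle = 1) {
  stopifnot(cycle %in% c(1, 2))
  p <- if (cycle == 1) cfg$capture_probs[1] else prod(cfg$capture_probs)
  rec <- with_seed(cfg$seed,
                   rbinom(length(cfg$spiking_levels), cfg$spiking_levels, p))
  out <- spiking_series(cfg$spiking_levels, rec)
  attr(out, "seed") <- cfg$seed
  attr(out, "capture_prob") <- p
  out
}

#' Generate two-cycle WBC/MCF7 count tables
#'
#' WBC counts at the CTC outlet follow Binomial(inlet, carryover_1) in
#' cycle 1 and a further Binomial(cycle-1 count, conditional carryover_2) in
#' cycle 2; MCF7 waste counts follow the complementary capture
#' probabilities. Realistic use has WBC inlet counts 4-6 orders of magnitude
#' above MCF7 counts.
#'
#' @param cfg A [synth_config()].
#' @param wbc_inlet Inlet WBC count, default 1e6.
#' @param mcf7_inlet Inlet MCF7 count, default 100.
#' @return A [cycle_counts()] with attribute `seed`.
#' @export
gen_cycle_counts <- function(cfg = synth_config(), wbc_inlet = 1e6,
                             mcf7_inlet = 100) {
  if (wbc_inlet < 1e4 * mcf7_inlet) {
    warning("WBC inlet count is less than 1e4 times the MCF7 count; ",
            "real samples exceed it by 4-6 orders of magnitude")
  }
  out <- with_seed(cfg$seed, {
    wbc1 <- rbinom(1, wbc_inlet, cfg$wbc_carryover[1])
    wbc2 <- rbinom(1, wbc1, cfg$wbc_carryover[2])
    waste1 <- rbinom(1, mcf7_inlet, 1 - cfg$capture_probs[1])
    kept1 <- mcf7_inlet - waste1
    waste2 <- rbinom(1, kept1, 1 - cfg$capture_probs[2])
    cycle_counts(wbc_inlet, wbc1, wbc2, mcf7_inlet, waste1, waste2)
  })
  attr(out, "seed") <- cfg$seed
  out
}

#' Generate Trypan-blue viability counts
#'
#' The viable inlet count is Binomial(n_cells, inlet viability); the loss of
#' a cycle is applied as independent binomial thinning of the viable and
#' total pools, so viable <= total is preserved on every draw.
#'
#' @param cfg A [synth_config()].
#' @param n_cells Total cells at the inlet, default 1000.
#' @param loss_prob Probability that a cell is lost across the chip,
#'   default 0.157 (cycle-1 conditions).
#' @return A [viability_counts()] with attribute `seed`.
#' @export
gen_viability_counts <- function(cfg = synth_config(), n_cells = 1000,
                                 loss_prob = 0.157) {
  stopifnot(loss_prob >= 0, loss_prob <= 1, n_cells > 0)
  out <- with_seed(cfg$seed, {
    viable_in <- rbinom(1, n_cells, cfg$inlet_viability)
    dead_in <- n_cells - viable_in
    viable_out <- rbinom(1, viable_in, 1 - loss_prob)
    dead_out <- rbinom(1, dead_in, 1 - loss_prob)
    viability_counts(viable_in, n_cells, viable_out,
                     viable_out + dead_out)
  })
  attr(out, "seed") <- cfg$seed
  out
}

#' Write a full set of synthetic fixtures with a manifest
#'
#' Emits the CSV schemas consumed by the profile-analysis and
#' enrichment-statistics stages, plus `manifest.json` recording the seed and
#' all generator parameters. Identical seeds give byte-identical files.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_synthetic_fixtures <- function(cfg = synth_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prof <- gen_intensity_profile(cfg)
  p1 <- write_intensity_profile(prof, file.path(dir, "intensity_profile.csv"))
  s1 <- gen_spiking_series(cfg, 1)
  s2 <- gen_spiking_series(cfg, 2)
  p2 <- file.path(dir, "spiking_series.csv")
  utils::write.csv(data.frame(
    cycle = rep(c(1L, 2L), each = length(cfg$spiking_levels)),
    n_spiked = c(s1$n_spiked, s2$n_spiked),
    n_recovered = c(s1$n_recovered, s2$n_recovered)), p2, row.names = FALSE)
  cc <- gen_cycle_counts(cfg)
  p3 <- file.path(dir, "cycle_counts.csv")
  utils::write.csv(data.frame(
    sample_id = "synth-1",
    cycle = c(0L, 1L, 2L, 1L, 2L),
    location = c("inlet", "ctc", "ctc", "waste", "waste"),
    wbc_count = c(cc$wbc_inlet, cc$wbc_ctc_c1, cc$wbc_ctc_c2, NA, NA),
    mcf7_count = c(cc$mcf7_inlet, NA, NA, cc$mcf7_waste_c1,
                   cc$mcf7_waste_c2)), p3, row.names = FALSE)
  vc <- gen_viability_counts(cfg)
  p4 <- file.path(dir, "viability_counts.csv")
  utils::write.csv(data.frame(
    location = c("inlet", "outlets"),
    viable_count = c(vc$viable_inlet, vc$viable_outlets),
    total_count = c(vc$total_inlet, vc$total_outlets)), p4,
    row.names = FALSE)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(unclass(cfg), mp, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3, p4, mp))
}
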