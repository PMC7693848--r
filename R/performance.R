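# Enrichment performance statistics: bead recovery/purity, two-cycle WBC
# depletion and CTC recovery, viability losses, through-origin linear-fit
# recovery estimation, enrichment factor and cycle volume/time bookkeeping.

#' Bead count table
#'
#' Counts of 17 µm and 10 µm calibration beads at the two outlets.
#'
#' @param n17_ctc,n17_waste 17 µm bead counts at CTC and waste outlets.
#' @param n10_ctc,n10_waste 10 µm bead counts at CTC and waste outlets.
#' @return An object of class `bead_counts`.
#' @export
bead_counts <- function(n17_ctc, n17_waste, n10_ctc = 0, n10_waste = 0) {
  v <- c(n17_ctc, n17_waste, n10_ctc, n10_waste)
  stopifnot(all(v >= 0))
  structure(list(n17_ctc = n17_ctc, n17_waste = n17_waste,
                 n10_ctc = n10_ctc, n10_waste = n10_waste),
            class = "bead_counts")
}

#' Bead recovery rate
#'
#' 100 * n17_ctc / (n17_ctc + n17_waste): the percentage of large beads
#' collected at the CTC outlet.
#'
#' @param counts A [bead_counts()].
#' @return Percent.
#' @export
bead_recovery <- function(counts) {
  den <- counts$n17_ctc + counts$n17_waste
  if (den <= 0) stop("bead recovery undefined: no 17 um beads counted")
  100 * counts$n17_ctc / den
}

#' Bead purity at the CTC outlet
#'
#' 100 * n17_ctc / (n17_ctc + n10_ctc).
#'
#' @param counts A [bead_counts()].
#' @return Percent.
#' @export
bead_purity <- function(counts) {
  den <- counts$n17_ctc + counts$n10_ctc
  if (den <= 0) stop("bead purity undefined: no beads at the CTC outlet")
  100 * counts$n17_ctc / den
}

#' Two-cycle cell count table
#'
#' WBC counts at the inlet and at the CTC outlet after each cycle, and MCF7
#' (CTC-model) counts at the inlet and at the waste outlet after each cycle.
#' Cycle-2 metrics are referenced to the original inlet counts.
#'
#' @param wbc_inlet,wbc_ctc_c1,wbc_ctc_c2 WBC counts.
#' @param mcf7_inlet,mcf7_waste_c1,mcf7_waste_c2 MCF7 counts.
#' @return An object of class `cycle_counts`.
#' @export
cycle_counts <- function(wbc_inlet, wbc_ctc_c1, wbc_ctc_c2 = NA,
                         mcf7_inlet = NA, mcf7_waste_c1 = NA,
                         mcf7_waste_c2 = NA) {
  v <- c(wbc_inlet, wbc_ctc_c1, wbc_ctc_c2, mcf7_inlet, mcf7_waste_c1,
         mcf7_waste_c2)
  stopifnot(all(v[!is.na(v)] >= 0))
  if (!is.na(wbc_ctc_c2) && (wbc_ctc_c2 > wbc_ctc_c1 ||
                             wbc_ctc_c1 > wbc_inlet)) {
    warning("unexpected count ordering (outlet exceeds inlet)")
  }
  structure(list(wbc_inlet = wbc_inlet, wbc_ctc_c1 = wbc_ctc_c1,
                 wbc_ctc_c2 = wbc_ctc_c2, mcf7_inlet = mcf7_inlet,
                 mcf7_waste_c1 = mcf7_waste_c1,
                 mcf7_waste_c2 = mcf7_waste_c2),
            class = "cycle_counts")
}

#' WBC depletion after a processing cycle
#'
#' 100 * (1 - WBC at the CTC outlet of the cycle / WBC at the inlet). Both
#' cycles are referenced to the same original inlet count, so the cycle-2
#' value is cumulative depletion.
#'
#' @param counts A [cycle_counts()].
#' @param cycle 1 or 2.
#' @return Percent.
#' @export
wbc_depletion <- function(counts, cycle = 1) {
  stopifnot(cycle %in% c(1, 2))
  if (counts$wbc_inlet <= 0) stop("depletion undefined: zero inlet count")
  out <- if (cycle == 1) counts$wbc_ctc_c1 else counts$wbc_ctc_c2
  100 * (1 - out / counts$wbc_inlet)
}

#' CTC recovery after a processing cycle
#'
#' 100 * (1 - MCF7 at the waste outlet of the cycle / MCF7 at the inlet),
#' both cycles referenced to the original inlet count.
#'
#' @inheritParams wbc_depletion
#' @return Percent.
#' @export
ctc_recovery <- function(counts, cycle = 1) {
  stopifnot(cycle %in% c(1, 2))
  if (is.na(counts$mcf7_inlet) || counts$mcf7_inlet <= 0) {
    stop("recovery undefined: zero inlet count")
  }
  out <- if (cycle == 1) counts$mcf7_waste_c1 else counts$mcf7_waste_c2
  100 * (1 - out / counts$mcf7_inlet)
}

#' Viability count table (Trypan blue exclusion)
#'
#' @param viable_inlet,total_inlet Viable and total cell counts at the inlet.
#' @param viable_outlets,total_outlets Pooled counts over both outlets.
#' @return An object of class `viability_counts`.
#' @export
viability_counts <- function(viable_inlet, total_inlet, viable_outlets,
                             total_outlets) {
  stopifnot(viable_inlet <= total_inlet, viable_outlets <= total_outlets,
            all(c(viable_inlet, total_inlet, viable_outlets,
                  total_outlets) >= 0))
  structure(list(viable_inlet = viable_inlet, total_inlet = total_inlet,
                 viable_outlets = viable_outlets,
                 total_outlets = total_outlets),
            class = "viability_counts")
}

#' Viable and total cell loss across the chip
#'
#' Viable loss = 100 (viable_in - viable_out) / viable_in, total loss
#' likewise on total counts; also reports percent viability at inlet and
#' outlets.
#'
#' @param v A [viability_counts()].
#' @return List with `viable_loss`, `total_loss`, `viability_in`,
#'   `viability_out` (all percent).
#' @export
cell_loss <- function(v) {
  if (v$total_inlet <= 0 || v$viable_inlet <= 0) {
    stop("cell loss undefined: zero inlet counts")
  }
  list(viable_loss = 100 * (v$viable_inlet - v$viable_outlets) /
         v$viable_inlet,
       total_loss = 100 * (v$total_inlet - v$total_outlets) / v$total_inlet,
       viability_in = 100 * v$viable_inlet / v$total_inlet,
       viability_out = if (v$total_outlets > 0) {
         100 * v$viable_outlets / v$total_outlets
       } else NA_real_)
}

#' Spiking series
#'
#' Paired (spiked, recovered) cell counts over a dilution series of spiking
#' experiments.
#'
#' @param n_spiked Numbers of cells spiked (>= 3 levels with spread).
#' @param n_recovered Numbers recovered at the CTC outlet.
#' @return An object of class `spiking_series`.
#' @export
spiking_series <- function(n_spiked, n_recovered) {
  stopifnot(length(n_spiked) == length(n_recovered), length(n_spiked) >= 3,
            all(n_spiked >= 0), all(n_recovered >= 0))
  if (any(n_recovered > n_spiked)) {
    warning("recovered exceeds spiked at some levels")
  }
  structure(list(n_spiked = as.numeric(n_spiked),
                 n_recovered = as.numeric(n_recovered)),
            class = "spiking_series")
}

#' Recovery rate from the linear fit of a spiking series
#'
#' Least-squares regression of recovered on spiked cells through the origin
#' (a zero-spike sample recovers zero cells); the recovery rate is 100 times
#' the slope, with R-squared reported on the through-origin model.
#'
#' @param series A [spiking_series()].
#' @return List with `rate` (percent), `slope` and `r_squared`.
#' @export
linear_fit_recovery <- function(series) {
  x <- series$n_spiked; y <- series$n_recovered
  sxx <- sum(x^2)
  if (sxx <= 0 || stats::sd(x) == 0) {
    stop("degenerate spiking series: no spread in spiked numbers")
  }
  slope <- sum(x * y) / sxx
  ss_res <- sum((y - slope * x)^2)
  ss_tot <- sum(y^2)
  list(rate = 100 * slope, slope = slope,
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}

#' Enrichment factor implied by a WBC depletion
#'
#' 100 / (100 - depletion): an 88.3% depletion concentrates CTCs roughly
#' 8.5-fold relative to WBCs (order ~10X).
#'
#' @param depletion Depletion percent in `[0, 100)`; exactly 100 returns
#'   `Inf`.
#' @return Fold enrichment (numeric) with a formatted `label` attribute.
#' @export
enrichment_factor <- function(depletion) {
  stopifnot(depletion >= 0, depletion <= 100)
  if (depletion == 100) {
    out <- Inf
  } else {
    out <- 100 / (100 - depletion)
  }
  attr(out, "label") <- if (is.finite(out)) {
    sprintf("~%.1fX", out)
  } else "complete depletion"
  out
}

#' Cycle volume and time bookkeeping
#'
#' Splits the processed volume between the CTC and waste outlets by the
#' outlet volume ratio and computes the processing time at the given flow
#' rate. Volume is conserved exactly.
#'
#' @param input_volume_ml Volume entering the cycle (mL).
#' @param split_ratio Numeric pair `c(ctc, waste)`, default `c(2, 3)`.
#' @param flow_rate_ml_min Flow rate (mL/min), default 1.2.
#' @return List with `ctc_volume_ml`, `waste_volume_ml`, `process_time_min`.
#' @export
cycle_bookkeeping <- function(input_volume_ml, split_ratio = c(2, 3),
                              flow_rate_ml_min = 1.2) {
  stopifnot(input_volume_ml > 0, all(split_ratio > 0),
            flow_rate_ml_min > 0, length(split_ratio) == 2)
  f <- split_ratio[1] / sum(split_ratio)
  list(ctc_volume_ml = input_volume_ml * f,
       waste_volume_ml = input_volume_ml * (1 - f),
       process_time_min = input_volume_ml / flow_rate_ml_min)
}
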