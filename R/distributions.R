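# Cross-channel stream distributions: two-Gaussian decomposition of bead
# intensity profiles, discretization into seeding weights, and the
# chromatography-style separation resolution.

FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2))  # 2.3548...

#' Stream distribution of one particle class
#'
#' The lateral distribution of one particle class across the channel,
#' Gaussian-parameterized: peak position (µm from the reference wall),
#' standard deviation sigma (µm) and amplitude. The half-height width is the
#' FWHM, 2 sqrt(2 ln 2) sigma. `bins` (filled by [discretize()]) holds the
#' discrete seeding positions and normalized weights used to release
#' particles into the flow simulation.
#'
#' @param peak Peak position (µm).
#' @param sigma Gaussian standard deviation (µm); alternatively give `fwhm`.
#' @param amplitude Peak amplitude (arbitrary units), default 1.
#' @param fwhm Half-height width (µm); exactly one of `sigma`/`fwhm`.
#' @param label Optional class label (e.g. "CTC-17um").
#' @return An object of class `stream_distribution`.
#' @export
stream_distribution <- function(peak, sigma = NULL, amplitude = 1,
                                fwhm = NULL, label = NULL) {
  if (is.null(sigma) == is.null(fwhm)) {
    stop("give exactly one of sigma or fwhm")
  }
  if (is.null(sigma)) sigma <- fwhm / FWHM_PER_SIGMA
  stopifnot(sigma > 0, amplitude > 0)
  structure(list(peak = peak, sigma = sigma, amplitude = amplitude,
                 fwhm = FWHM_PER_SIGMA * sigma, label = label,
                 bins = NULL),
            class = "stream_distribution")
}

#' @export
print.stream_distribution <- function(x, ...) {
  cat(sprintf("Stream distribution%s: peak %.2f um, FWHM %.2f um%s\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$peak, x$fwhm,
              if (is.null(x$bins)) "" else
                sprintf(", %d seeding bins", nrow(x$bins))))
  invisible(x)
}

#' Read / write intensity-profile CSV
#'
#' Two-column schema with a header row: `position_um`, `intensity`.
#'
#' @param path File path.
#' @return `read_intensity_profile`: an `intensity_profile` (list with
#'   `position`, `intensity`).
#' @export
read_intensity_profile <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("position_um", "intensity") %in% names(d))) {
    stop("intensity profile CSV must have columns position_um, intensity")
  }
  intensity_profile(d$position_um, d$intensity)
}

#' @rdname read_intensity_profile
#' @param profile An `intensity_profile`.
#' @export
write_intensity_profile <- function(profile, path) {
  utils::write.csv(data.frame(position_um = profile$position,
                              intensity = profile$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Construct an intensity profile
#'
#' @param position Strictly increasing positions (µm from reference wall).
#' @param intensity Grayscale intensities (arbitrary units).
#' @return An object of class `intensity_profile`.
#' @export
intensity_profile <- function(position, intensity) {
  stopifnot(length(position) == length(intensity), length(position) >= 16,
            all(diff(position) > 0))
  structure(list(position = as.numeric(position),
                 intensity = as.numeric(intensity)),
            class = "intensity_profile")
}

# local maxima of a 5-point-smoothed profile, strongest first; maxima with
# less than 5% of the profile range above the baseline are discarded
profile_peaks <- function(profile) {
  y <- stats::filter(profile$intensity, rep(1 / 5, 5), sides = 2)
  y[is.na(y)] <- profile$intensity[is.na(y)]
  y <- as.numeric(y)
  n <- length(y)
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  i <- i[y[i] >= min(y) + 0.05 * (max(y) - min(y))]
  i[order(y[i], decreasing = TRUE)]
}

#' Fit two Gaussians (plus constant baseline) to an intensity profile
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `b + A1 exp(-(x-m1)^2 / 2 s1^2) + A2 exp(-(x-m2)^2 / 2 s2^2)`.
#' Initialized from the two strongest local maxima of the 5-point-smoothed
#' profile with the baseline at the profile minimum. If the profile exhibits
#' a single peak, one distribution is returned with a degeneracy warning.
#'
#' @param profile An [intensity_profile()].
#' @return List of two `stream_distribution`s ordered by peak position, with
#'   attributes `residual_norm` and `fit`. For a single-peak profile, a list
#'   of one with attribute `degenerate = TRUE`.
#' @export
fit_two_gaussians <- function(profile) {
  x <- profile$position; y <- profile$intensity
  pk <- profile_peaks(profile)
  if (length(pk) == 0) stop("profile exhibits no local maximum")
  base0 <- min(y)
  span <- diff(range(x))
  if (length(pk) == 1) {
    f1 <- minpack.lm::nlsLM(
      y ~ b + A1 * exp(-(x - m1)^2 / (2 * s1^2)),
      start = list(b = base0, A1 = y[pk[1]] - base0, m1 = x[pk[1]],
                   s1 = span / 10),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(f1)
    d <- stream_distribution(cf[["m1"]], sigma = abs(cf[["s1"]]),
                             amplitude = cf[["A1"]])
    warning("single-peak profile: returning one distribution")
    out <- list(d)
    attr(out, "degenerate") <- TRUE
    attr(out, "residual_norm") <- sqrt(sum(stats::resid(f1)^2))
    return(out)
  }
  p1 <- pk[1]; p2 <- pk[2]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + A1 * exp(-(x - m1)^2 / (2 * s1^2)) +
        A2 * exp(-(x - m2)^2 / (2 * s2^2)),
      start = list(b = base0,
                   A1 = y[p1] - base0, m1 = x[p1], s1 = span / 15,
                   A2 = y[p2] - base0, m2 = x[p2], s2 = span / 15),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stop("two-Gaussian fit failed (initial peaks at ",
           paste(signif(x[c(p1, p2)], 4), collapse = ", "), "): ",
           conditionMessage(e))
    })
  cf <- coef(fit)
  d1 <- stream_distribution(cf[["m1"]], sigma = abs(cf[["s1"]]),
                            amplitude = cf[["A1"]])
  d2 <- stream_distribution(cf[["m2"]], sigma = abs(cf[["s2"]]),
                            amplitude = cf[["A2"]])
  out <- if (d1$peak <= d2$peak) list(d1, d2) else list(d2, d1)
  attr(out, "degenerate") <- FALSE
  attr(out, "residual_norm") <- sqrt(sum(stats::resid(fit)^2))
  attr(out, "baseline") <- cf[["b"]]
  out
}

#' Discretize a stream distribution into seeding bins
#'
#' Equally spaced bins over `mean +/- span_sigmas * sigma`, weights
#' proportional to the Gaussian density and normalized to 1. Bins falling
#' outside `[0, channel_width]` are clipped (dropped) with renormalization
#' and a warning.
#'
#' @param dist A [stream_distribution()].
#' @param n_bins Number of bins (>= 1; the single-bin case collapses to the
#'   mean), default 50.
#' @param span_sigmas Half-span in sigmas, default 3.
#' @param channel_width Channel width (µm) for clipping, default `Inf`.
#' @return The distribution with `bins`: a matrix with columns `position`,
#'   `weight` (weights sum to 1).
#' @export
discretize <- function(dist, n_bins = 50, span_sigmas = 3,
                       channel_width = Inf) {
  stopifnot(inherits(dist, "stream_distribution"), n_bins >= 1,
            span_sigmas > 0)
  if (n_bins == 1) {
    dist$bins <- cbind(position = dist$peak, weight = 1)
    return(dist)
  }
  pos <- seq(dist$peak - span_sigmas * dist$sigma,
             dist$peak + span_sigmas * dist$sigma, length.out = n_bins)
  w <- dnorm(pos, dist$peak, dist$sigma)
  keep <- pos >= 0 & pos <= channel_width
  if (!all(keep)) {
    warning("discretization span clipped to the channel; renormalized")
    pos <- pos[keep]; w <- w[keep]
    if (!length(pos)) stop("distribution lies entirely outside the channel")
  }
  dist$bins <- cbind(position = pos, weight = w / sum(w))
  dist
}

#' Separation resolution between two stream distributions
#'
#' R = 1.18 |peak1 - peak2| / (w1 + w2) with w the half-height (FWHM)
#' widths, the chromatographic resolution statistic. R > 1 indicates
#' non-overlapping streams; larger is better separated.
#'
#' @param d1,d2 [stream_distribution()]s (or any list with `peak` and
#'   `fwhm`).
#' @return An object of class `resolution_result`: list with `R`, `s_p`
#'   (peak separation, µm) and `w_sum` (summed widths, µm).
#' @export
resolution <- function(d1, d2) {
  w_sum <- d1$fwhm + d2$fwhm
  if (w_sum <= 0) stop("resolution undefined for zero combined width")
  s_p <- abs(d1$peak - d2$peak)
  structure(list(R = 1.18 * s_p / w_sum, s_p = s_p, w_sum = w_sum),
            class = "resolution_result")
}

#' @export
print.resolution_result <- function(x, ...) {
  cat(sprintf("Separation resolution R = %.3f (s_p = %.2f um, w1+w2 = %.2f um)\n",
              x$R, x$s_p, x$w_sum))
  invisible(x)
}

#' Downstream distribution from particle crossing positions
#'
#' Builds a weighted histogram of outlet-section crossing positions, takes
#' the peak as the weighted mode with parabolic refinement, and measures the
#' half-height width directly on the histogram (with a floor of one bin
#' width when all particles land in a single bin).
#'
#' @param position Crossing positions (µm).
#' @param weight Particle weights (default equal).
#' @param bin_width Histogram bin width (µm), default 2.
#' @param label Optional class label.
#' @return A `stream_distribution` whose `fwhm` is the measured histogram
#'   half-height width (sigma stored as fwhm / 2.3548 for consistency).
#' @export
downstream_distribution <- function(position, weight = NULL, bin_width = 2,
                                    label = NULL) {
  stopifnot(length(position) >= 3)
  if (is.null(weight)) weight <- rep(1 / length(position), length(position))
  stopifnot(length(weight) == length(position), all(weight >= 0))
  lo <- floor(min(position) / bin_width) * bin_width - bin_width
  hi <- ceiling(max(position) / bin_width) * bin_width + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  idx <- findInterval(position, breaks, rightmost.closed = TRUE)
  counts <- numeric(length(breaks) - 1)
  for (k in seq_along(idx)) counts[idx[k]] <- counts[idx[k]] + weight[k]
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  i <- which.max(counts)
  # parabolic refinement of the mode
  peak <- centers[i]
  if (i > 1 && i < length(counts)) {
    y0 <- counts[i - 1]; y1 <- counts[i]; y2 <- counts[i + 1]
    den <- y0 - 2 * y1 + y2
    if (abs(den) > 1e-12) {
      peak <- centers[i] + 0.5 * (y0 - y2) / den * bin_width
    }
  }
  half <- counts[i] / 2
  above <- which(counts >= half)
  if (length(above) <= 1) {
    warning("all particle weight in one histogram bin; width floored")
    fwhm <- bin_width
  } else {
    # linear interpolation of the half-height crossings around the modal run
    li <- min(above); ri <- max(above)
    left <- centers[li]
    if (li > 1) {
      left <- centers[li - 1] + (half - counts[li - 1]) /
        (counts[li] - counts[li - 1]) * bin_width
    }
    right <- centers[ri]
    if (ri < length(counts)) {
      right <- centers[ri] + (half - counts[ri]) /
        (counts[ri + 1] - counts[ri]) * bin_width
    }
    fwhm <- max(right - left, bin_width)
  }
  d <- stream_distribution(peak, fwhm = fwhm, label = label)
  d$histogram <- list(centers = centers, weights = counts)
  d
}
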