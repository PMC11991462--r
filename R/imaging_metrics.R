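# Image-quality and energy-resolution statistics from tallies and
# projection maps: SNR, per-event deposit statistics, fluctuation metric,
# deposit histograms.

#' Signal-to-noise ratio of a projection map
#'
#' Mean pixel intensity divided by the sample (n-1) standard deviation over
#' the masked pixels. A constant map has zero variance; the SNR is then
#' reported as `Inf` with `infinite = TRUE`.
#'
#' @param map A [project()] map, or a bare numeric matrix of pixel values.
#' @param mask Optional logical matrix selecting pixels (>= 2 pixels);
#'   default uses every pixel.
#' @return List with `mean`, `sd`, `snr`, `n_pixels`, `infinite`.
#' @export
#' @examples
#' snr(matrix(c(2, 4), 1))  # mean 3, sd sqrt(2)
snr <- function(map, mask = NULL) {
  px <- if (inherits(map, "projection_map")) map$pixels else map
  if (is.null(mask)) mask <- array(TRUE, dim = dim(px))
  vals <- px[mask]
  if (length(vals) < 2L)
    stop("mask must select at least 2 pixels", call. = FALSE)
  m <- mean(vals)
  s <- stats::sd(vals)
  list(mean = m, sd = s, snr = if (s > 0) m / s else Inf,
       n_pixels = length(vals), infinite = s == 0)
}

#' Per-volume SNR report from a simulation tally
#'
#' For each volume and projection plane, the voxel subgrid overlapping the
#' volume is projected onto the plane and the SNR computed over the
#' resulting footprint pixels (the paper-style per-material SNR from shared
#' images). Whole-image SNR rows are appended for comparison.
#'
#' @param tally A [run_simulation()] tally.
#' @param planes Projection planes (default all three).
#' @return data.frame with `volume`, `plane`, `mean`, `sd`, `snr`,
#'   `n_pixels`.
#' @export
snr_report <- function(tally, planes = c("XY", "XZ", "YZ")) {
  stopifnot(inherits(tally, "simulation_tally"))
  rows <- list()
  for (plane in planes) {
    keep <- switch(plane, XY = c(1L, 2L), XZ = c(1L, 3L), YZ = c(2L, 3L))
    for (v in seq_along(tally$volumes)) {
      rng <- .voxel_ranges(tally, v)
      sub <- tally$grid[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
      px <- apply(sub, keep, sum)
      s <- snr(px)
      rows[[length(rows) + 1L]] <- data.frame(
        volume = tally$volumes[[v]]$name, plane = plane,
        mean = s$mean, sd = s$sd, snr = s$snr, n_pixels = s$n_pixels)
    }
    s <- snr(project(tally, plane))
    rows[[length(rows) + 1L]] <- data.frame(
      volume = "(whole image)", plane = plane,
      mean = s$mean, sd = s$sd, snr = s$snr, n_pixels = s$n_pixels)
  }
  do.call(rbind, rows)
}

#' Mean and RMS of per-event energy deposits
#'
#' Mean over all source events (zero-deposit events included) and the RMS
#' spread, the root of the mean squared deviation from the mean.
#'
#' @param deposits Numeric vector of per-event deposits (keV).
#' @return List with `n`, `mean`, `rms`.
#' @export
#' @examples
#' edep_stats(c(0, 0, 0, 4))  # mean 1, rms sqrt(3)
edep_stats <- function(deposits) {
  if (!length(deposits)) stop("need at least one event", call. = FALSE)
  m <- mean(deposits)
  list(n = length(deposits), mean = m,
       rms = sqrt(mean((deposits - m)^2)))
}

#' Pool deposit statistics of two event sets
#'
#' Closed-form combination of `(n, mean, rms)` summaries, equal to
#' [edep_stats()] on the concatenated samples.
#'
#' @param a,b Lists as returned by [edep_stats()].
#' @return Pooled list with `n`, `mean`, `rms`.
#' @export
pool_edep_stats <- function(a, b) {
  n <- a$n + b$n
  m <- (a$n * a$mean + b$n * b$mean) / n
  msq <- (a$n * (a$rms^2 + a$mean^2) + b$n * (b$rms^2 + b$mean^2)) / n
  list(n = n, mean = m, rms = sqrt(msq - m^2))
}

#' Energy-deposition fluctuation metric
#'
#' Relative spread of the per-event deposit, `F = 100 * RMS / mean` (in
#' percent), and the same scaled by the square root of the mean initial
#' photon energy, `F_scaled = F * sqrt(E0)`, indicating how the material
#' responds across initial energies. Undefined (flagged `NA`) when the mean
#' deposit is zero.
#'
#' @param mean_edep Mean per-event deposit (keV).
#' @param rms_edep RMS per-event deposit (keV).
#' @param e0_keV Mean initial photon energy of the run (keV).
#' @return List with `percent`, `scaled`, `defined`.
#' @export
fluctuation_metric <- function(mean_edep, rms_edep, e0_keV) {
  if (mean_edep == 0)
    return(list(percent = NA_real_, scaled = NA_real_, defined = FALSE))
  f <- 100 * rms_edep / mean_edep
  list(percent = f, scaled = f * sqrt(e0_keV), defined = TRUE)
}

#' Histogram of per-event energy deposits
#'
#' @param deposits Numeric vector of per-event deposits (keV).
#' @param breaks Bin edges (keV), strictly increasing and covering the
#'   deposit range; values at an edge go to the upper bin (left-closed).
#' @return data.frame with `lower_keV`, `upper_keV`, `count`; counts sum to
#'   the number of events.
#' @export
export_histograms <- function(deposits, breaks) {
  if (any(diff(breaks) <= 0))
    stop("breaks must be strictly increasing", call. = FALSE)
  if (min(deposits) < breaks[1] || max(deposits) >= breaks[length(breaks)])
    stop("breaks must cover the deposit range", call. = FALSE)
  idx <- findInterval(deposits, breaks)
  nb <- length(breaks) - 1L
  data.frame(lower_keV = breaks[-length(breaks)], upper_keV = breaks[-1L],
             count = tabulate(idx, nbins = nb))
}
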