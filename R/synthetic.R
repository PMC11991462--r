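# Synthetic test surfaces: deterministic test images with known moments
# and Beer-Lambert parameter-recovery experiments closing the loop between
# the transport and attenuation halves of the package.

#' Seeded synthetic test image with known moments
#'
#' Pixel values drawn i.i.d. with the requested mean and standard
#' deviation, then truncated at zero (the truncation rate is reported as an
#' attribute). The truncated-normal mode gives a closed-form SNR
#' expectation of `mean/std` when truncation is negligible; a Poisson mode
#' (variance = mean) is also available.
#'
#' @param n_pixels Total pixel count, or a length-2 vector of matrix
#'   dimensions.
#' @param mean Target pixel mean (ignored `std` in `"poisson"` mode).
#' @param std Target pixel standard deviation (>= 0).
#' @param seed Integer seed.
#' @param mode `"truncnorm"` (default) or `"poisson"`.
#' @return A `"projection_map"` whose `pixels` matrix carries attribute
#'   `truncation_rate`.
#' @export
#' @examples
#' img <- make_test_image(1e4, mean = 10, std = 2, seed = 42)
#' snr(img)$snr  # close to 5
make_test_image <- function(n_pixels, mean, std, seed,
                            mode = c("truncnorm", "poisson")) {
  mode <- match.arg(mode)
  if (std < 0) stop("std must be >= 0", call. = FALSE)
  dims <- if (length(n_pixels) == 2L) as.integer(n_pixels)
          else c(as.integer(n_pixels), 1L)
  n <- prod(dims)
  set.seed(seed)
  vals <- switch(mode,
    truncnorm = stats::rnorm(n, mean, std),
    poisson = stats::rpois(n, mean))
  trunc_rate <- mean(vals < 0)
  vals[vals < 0] <- 0
  px <- matrix(vals, nrow = dims[1], ncol = dims[2])
  attr(px, "truncation_rate") <- trunc_rate
  structure(list(plane = "synthetic", pixels = px, pixel_size = NULL,
                 masks = NULL),
            class = "projection_map")
}

#' Recover a linear attenuation coefficient from transmission counts
#'
#' Least-squares fit of `ln(I/I0)` against thickness; the slope estimates
#' `-mu`. Thickness points with zero transmitted counts are dropped with a
#' warning. The confidence interval comes from the linear fit.
#'
#' @param thickness_cm Slab thicknesses (cm), at least 3 usable points.
#' @param transmitted Transmitted (uncollided) counts per thickness.
#' @param emitted Emitted counts per thickness (I0).
#' @param level Confidence level for the interval (default 0.99).
#' @return List with `mu` (1/cm), `ci` (length-2), `level`, `fit`.
#' @export
#' @examples
#' x <- 1:5
#' I0 <- 1e5
#' mu_recovery(x, round(I0 * exp(-0.25 * x)), rep(I0, 5))$mu
mu_recovery <- function(thickness_cm, transmitted, emitted, level = 0.99) {
  keep <- transmitted > 0
  if (any(!keep))
    warning(sum(!keep), " thickness point(s) with zero transmitted counts ",
            "dropped", call. = FALSE)
  x <- thickness_cm[keep]
  y <- log(transmitted[keep] / emitted[keep])
  if (length(x) < 3L)
    stop("need at least 3 usable thickness points", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ci <- -rev(stats::confint(fit, "x", level = level)[1, ])
  list(mu = -unname(stats::coef(fit)["x"]),
       ci = unname(ci), level = level, fit = fit)
}

#' End-to-end attenuation-coefficient recovery experiment
#'
#' Generates transmission counts with the Monte Carlo transport sampler
#' ([transmission_experiment()]) and recovers the linear attenuation
#' coefficient by [mu_recovery()], comparing against the analytic value
#' from the same photoatomic library. Recovery succeeds when the true mu
#' lies inside the confidence interval.
#'
#' @param material A [material()].
#' @param energy_keV Beam energy (keV).
#' @param thickness_cm Slab thicknesses (default 1--5 cm).
#' @param n_photons Photons per thickness (default 1e5).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.99).
#' @return List with `mu_true`, `mu_hat`, `ci`, `recovered`, `counts`.
#' @export
run_recovery_experiment <- function(material, energy_keV,
                                    thickness_cm = 1:5, n_photons = 1e5,
                                    seed = 42, level = 0.99) {
  counts <- transmission_experiment(material, energy_keV, thickness_cm,
                                    n_photons, seed = seed)
  rec <- mu_recovery(counts$thickness_cm, counts$transmitted,
                     counts$n_photons, level = level)
  mu_true <- linear_mu(material, energy_keV)
  list(mu_true = mu_true, mu_hat = rec$mu, ci = rec$ci,
       recovered = mu_true >= rec$ci[1] && mu_true <= rec$ci[2],
       counts = counts)
}
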