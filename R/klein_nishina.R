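#' Klein--Nishina total cross-section
#'
#' Total free-electron Compton cross-section at photon energy E, in
#' cm^2/electron (1 barn = 1e-24 cm^2). Reduces to the Thomson value
#' 0.6652 barn as E -> 0 and decreases monotonically with energy.
#'
#' @param energy_keV Photon energy in keV (> 0); vectorized.
#' @return Cross-section in cm^2 per electron.
#' @export
#' @examples
#' kn_total_cross_section(60) / 1e-24   # barns at 60 keV
kn_total_cross_section <- function(energy_keV) {
  if (any(energy_keV <= 0)) stop("energy must be positive", call. = FALSE)
  k <- energy_keV / .MEC2_KEV
  pre <- 2 * pi * .R_ELECTRON_CM^2
  term1 <- (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log1p(2 * k) / k)
  term2 <- log1p(2 * k) / (2 * k)
  term3 <- (1 + 3 * k) / (1 + 2 * k)^2
  pre * (term1 + term2 - term3)
}

#' Compton-scattered photon energy
#'
#' \eqn{E' = E / (1 + k(1 - \cos\theta))} with \eqn{k = E/m_ec^2}.
#'
#' @param energy_keV Incident photon energy (keV).
#' @param theta Scattering angle in radians.
#' @return Scattered photon energy in keV.
#' @export
compton_scattered_energy <- function(energy_keV, theta) {
  k <- energy_keV / .MEC2_KEV
  energy_keV / (1 + k * (1 - cos(theta)))
}

#' Klein--Nishina differential cross-section
#'
#' \eqn{d\sigma/d\Omega = (r_e^2/2)(E'/E)^2 (E/E' + E'/E - \sin^2\theta)}
#' in cm^2/sr/electron, with the Compton-shifted scattered energy E'(theta).
#' At theta = 0 this equals the forward Thomson value \eqn{r_e^2}.
#'
#' @param energy_keV Photon energy in keV (> 0).
#' @param theta Scattering angle in radians, in [0, pi].
#' @return Differential cross-section in cm^2/sr per electron.
#' @export
kn_differential <- function(energy_keV, theta) {
  if (any(energy_keV <= 0)) stop("energy must be positive", call. = FALSE)
  if (any(theta < 0 | theta > pi))
    stop("theta must lie in [0, pi]", call. = FALSE)
  ratio <- compton_scattered_energy(energy_keV, theta) / energy_keV
  0.5 * .R_ELECTRON_CM^2 * ratio^2 * (1 / ratio + ratio - sin(theta)^2)
}

#' Sample Compton scattering angles from the Klein--Nishina density
#'
#' Rejection sampling of \eqn{\theta} with density proportional to
#' \eqn{(d\sigma/d\Omega)\sin\theta}, using a uniform envelope in
#' \eqn{\cos\theta}. Draws from the current R random stream.
#'
#' @param energy_keV Incident photon energy (keV); scalar or vector of
#'   length `n`.
#' @param n Number of samples.
#' @return Numeric vector of scattering angles in radians.
#' @export
sample_compton_angle <- function(energy_keV, n = length(energy_keV)) {
  E <- rep_len(energy_keV, n)
  out <- numeric(n)
  todo <- seq_len(n)
  # envelope: dsigma/dOmega is maximal at theta = 0 (value r_e^2)
  fmax <- .R_ELECTRON_CM^2
  while (length(todo) > 0L) {
    m <- length(todo)
    cost <- stats::runif(m, -1, 1)
    theta <- acos(cost)
    f <- kn_differential(E[todo], theta)
    ok <- stats::runif(m) * fmax < f
    out[todo[ok]] <- theta[ok]
    todo <- todo[!ok]
  }
  out
}

#' One Compton interaction
#'
#' Samples a scattering angle from the Klein--Nishina density, applies
#' Compton kinematics, and splits the incident energy between the scattered
#' photon and the recoil electron (deposited locally by the transport
#' module). Azimuth is uniform on [0, 2*pi).
#'
#' @param energy_keV Incident photon energy (keV); vectorized.
#' @return List with `theta`, `phi`, `scattered_keV`, `electron_keV`.
#' @export
do_compton <- function(energy_keV) {
  theta <- sample_compton_angle(energy_keV, length(energy_keV))
  ep <- compton_scattered_energy(energy_keV, theta)
  list(theta = theta,
       phi = stats::runif(length(energy_keV), 0, 2 * pi),
       scattered_keV = ep,
       electron_keV = energy_keV - ep)
}

#' One photoelectric absorption
#'
#' The full photon energy is transferred to a secondary electron and
#' deposited locally (no fluorescence or Auger relaxation is modelled);
#' the photon is terminated.
#'
#' @param energy_keV Photon energy (keV); vectorized.
#' @return List with `deposit_keV` and `terminated`.
#' @export
do_photoelectric <- function(energy_keV) {
  list(deposit_keV = energy_keV, terminated = rep(TRUE, length(energy_keV)))
}
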