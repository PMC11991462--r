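# Material-level photon interaction parameters over the diagnostic range:
# mass/linear attenuation, transmission, HVL, atomic/electronic
# cross-sections, Z_eff, N_eff, percent increase and K-edge localization.

#' Mass attenuation coefficient of a material
#'
#' Weight-fraction mixture rule over the elemental coefficients:
#' \eqn{\mu/\rho = \sum_i w_i (\mu/\rho)_i}.
#'
#' @param material A [material()].
#' @param energy_keV Photon energies in keV (10--150); vectorized.
#' @param include_coherent Include the Rayleigh term (default `TRUE`).
#' @return Mass attenuation coefficient(s) in cm^2/g.
#' @export
#' @examples
#' peek <- study_materials()$PEEK
#' mixture_mu_m(peek, c(30, 50, 80, 100))
mixture_mu_m <- function(material, energy_keV, include_coherent = TRUE) {
  stopifnot(inherits(material, "material"))
  w <- material$composition
  out <- 0
  for (sym in names(w))
    out <- out + w[[sym]] *
      element_mass_attenuation(sym, energy_keV, include_coherent)
  out
}

#' Linear attenuation coefficient
#'
#' \eqn{\mu = (\mu/\rho)\,\rho} in 1/cm.
#'
#' @inheritParams mixture_mu_m
#' @return Linear attenuation coefficient(s) in 1/cm.
#' @export
linear_mu <- function(material, energy_keV, include_coherent = TRUE) {
  mixture_mu_m(material, energy_keV, include_coherent) * material$density_g_cm3
}

#' Beam transmission through a thickness
#'
#' Beer--Lambert fraction \eqn{I/I_0 = e^{-\mu x}}.
#'
#' @param mu Linear attenuation coefficient(s), 1/cm.
#' @param x_cm Thickness in cm (>= 0).
#' @return Transmitted fraction(s).
#' @export
transmission <- function(mu, x_cm) {
  if (any(x_cm < 0)) stop("thickness must be non-negative", call. = FALSE)
  exp(-mu * x_cm)
}

#' Half value layer
#'
#' Thickness halving the beam intensity: \eqn{HVL = \ln 2 / \mu}.
#'
#' @param mu Linear attenuation coefficient(s), 1/cm (> 0).
#' @return HVL in cm.
#' @export
hvl <- function(mu) {
  if (any(mu <= 0)) stop("mu must be positive", call. = FALSE)
  log(2) / mu
}

#' Total atomic cross-section of a material
#'
#' \eqn{\sigma_{t,a} = (\mu/\rho) / (N_A \sum_i w_i/A_i)}: the mass
#' attenuation coefficient divided by the number of atoms per gram.
#'
#' @inheritParams mixture_mu_m
#' @return Cross-section(s) in cm^2/atom.
#' @export
total_atomic_cross_section <- function(material, energy_keV,
                                       include_coherent = TRUE) {
  w <- material$composition
  a <- .element_row(names(w))$a_weight
  atoms_per_g <- .N_AVOGADRO * sum(w / a)
  mixture_mu_m(material, energy_keV, include_coherent) / atoms_per_g
}

#' Total electronic cross-section of a material
#'
#' \eqn{\sigma_{t,el} = (1/N_A) \sum_i f_i (A_i/Z_i) (\mu/\rho)_i} with
#' atom fractions \eqn{f_i} and elemental mass attenuation coefficients
#' \eqn{(\mu/\rho)_i}. For a pure element this collapses to
#' \eqn{\sigma_{t,a}/Z}.
#'
#' @inheritParams mixture_mu_m
#' @return Cross-section(s) in cm^2/electron.
#' @export
total_electronic_cross_section <- function(material, energy_keV,
                                           include_coherent = TRUE) {
  w <- material$composition
  el <- .element_row(names(w))
  f <- atom_fractions(w)
  out <- 0
  for (i in seq_along(w)) {
    sym <- names(w)[i]
    out <- out + f[[sym]] * (el$a_weight[i] / el$z[i]) *
      element_mass_attenuation(sym, energy_keV, include_coherent)
  }
  out / .N_AVOGADRO
}

#' Effective atomic number
#'
#' \eqn{Z_{eff} = \sigma_{t,a} / \sigma_{t,el}}; equals Z exactly for a
#' pure element and lies between the constituent Z values for a compound.
#'
#' @inheritParams mixture_mu_m
#' @return Dimensionless Z_eff value(s).
#' @export
z_eff <- function(material, energy_keV, include_coherent = TRUE) {
  total_atomic_cross_section(material, energy_keV, include_coherent) /
    total_electronic_cross_section(material, energy_keV, include_coherent)
}

#' Effective electron density
#'
#' \eqn{N_{eff} = (\mu/\rho) / \sigma_{t,el}} in electrons/g; equals
#' \eqn{N_A Z / A} for a pure element.
#'
#' @inheritParams mixture_mu_m
#' @return N_eff value(s) in electrons/g.
#' @export
n_eff <- function(material, energy_keV, include_coherent = TRUE) {
  mixture_mu_m(material, energy_keV, include_coherent) /
    total_electronic_cross_section(material, energy_keV, include_coherent)
}

#' Percent increase of an attenuation coefficient over a baseline
#'
#' \eqn{100\,(\mu_{composite} - \mu_{baseline}) / \mu_{baseline}}.
#'
#' @param mu_composite Coefficient(s) of the composite.
#' @param mu_baseline Coefficient(s) of the baseline material (> 0).
#' @return Percent increase (negative if the composite attenuates less).
#' @export
percent_increase <- function(mu_composite, mu_baseline) {
  if (any(mu_baseline <= 0))
    stop("baseline coefficient must be positive", call. = FALSE)
  100 * (mu_composite - mu_baseline) / mu_baseline
}

#' Attenuation curve of a material
#'
#' Evaluates mass and linear attenuation, HVL, Z_eff and N_eff on an
#' energy grid with duplicated nodes at the in-range K-edges of the
#' material's constituent elements.
#'
#' @inheritParams mixture_mu_m
#' @inheritParams energy_grid
#' @return A data.frame of class `"attenuation_curve"` with columns
#'   `material`, `energy_keV`, `mu_m_cm2_g`, `mu_1_cm`, `hvl_cm`, `z_eff`,
#'   `n_eff`.
#' @export
#' @examples
#' crv <- attenuation_curve(study_materials()$PEEK, step = 5)
#' head(crv)
attenuation_curve <- function(material, emin = 20, emax = 120, step = 0.1,
                              include_coherent = TRUE) {
  grid <- energy_grid(emin, emax, step, elements = names(material$composition))
  # evaluate the below-edge branch on the first node of each duplicated pair
  mu_m <- mixture_mu_m(material, grid, include_coherent)
  dup <- which(duplicated(grid))  # second of each duplicated pair
  for (i2 in dup) {
    i1 <- i2 - 1L
    eps_e <- grid[i1] * (1 - 1e-12)
    mu_m[i1] <- mixture_mu_m(material, eps_e, include_coherent)
  }
  mu <- mu_m * material$density_g_cm3
  out <- data.frame(material = material$name, energy_keV = grid,
                    mu_m_cm2_g = mu_m, mu_1_cm = mu, hvl_cm = hvl(mu),
                    z_eff = z_eff(material, grid, include_coherent),
                    n_eff = n_eff(material, grid, include_coherent))
  class(out) <- c("attenuation_curve", "data.frame")
  out
}

#' Locate a K-edge discontinuity on an attenuation curve
#'
#' Finds the largest upward jump between adjacent grid points of the
#' mass attenuation curve. Returns `NA` when no jump exceeds the relative
#' threshold (i.e. the material has no K-edge in the grid span).
#'
#' @param curve An [attenuation_curve()] (grid step must be <= 0.1 keV).
#' @param threshold Minimum relative upward jump to count as an edge
#'   (default 0.05, i.e. 5\%).
#' @return Edge energy in keV, or `NA_real_` if none found.
#' @export
#' @examples
#' crv <- attenuation_curve(study_materials()$`PEEK-BaSO4`)
#' locate_k_edge(crv)  # Ba K-edge
locate_k_edge <- function(curve, threshold = 0.05) {
  e <- curve$energy_keV
  v <- curve$mu_m_cm2_g
  steps <- diff(unique(e))
  if (length(steps) && max(steps) > 0.1 + 1e-9)
    stop("grid too coarse for K-edge localization (step must be <= 0.1 keV)",
         call. = FALSE)
  jump <- v[-1L] / v[-length(v)] - 1
  if (!length(jump) || max(jump) < threshold) return(NA_real_)
  i <- which.max(jump)
  e[i + 1L]
}
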