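#' Construct a material
#'
#' A material is a named elemental composition (weight fractions) plus a bulk
#' density; the subject of every attenuation and transport calculation. The
#' composition can be given either as a chemical formula or as explicit
#' weight fractions (e.g. for tissue mixtures such as cortical bone).
#'
#' @param name Material name.
#' @param density_g_cm3 Bulk density in g/cm^3 (> 0).
#' @param formula Chemical formula, e.g. `"C19H12O3"` for the PEEK repeat
#'   unit. Exactly one of `formula` / `weight_fractions` must be given.
#' @param weight_fractions Named numeric vector of weight fractions.
#' @param elastic_modulus_GPa Optional elastic modulus, carried as metadata
#'   only (no mechanical modelling is done).
#' @return An object of class `"material"`.
#' @export
#' @examples
#' material("PEEK", 1.32, formula = "C19H12O3", elastic_modulus_GPa = 4)
material <- function(name, density_g_cm3, formula = NULL,
                     weight_fractions = NULL, elastic_modulus_GPa = NA_real_) {
  if (!is.numeric(density_g_cm3) || length(density_g_cm3) != 1L ||
      density_g_cm3 <= 0)
    stop("density must be a single positive number", call. = FALSE)
  if (is.null(formula) == is.null(weight_fractions))
    stop("give exactly one of 'formula' or 'weight_fractions'", call. = FALSE)
  comp <- if (!is.null(formula)) {
    weight_fractions(parse_formula(formula))
  } else {
    w <- weight_fractions / sum(weight_fractions)  # tolerate rounded inputs
    validate_composition(w)
    w
  }
  structure(
    list(name = name, composition = comp, density_g_cm3 = density_g_cm3,
         formula = formula, elastic_modulus_GPa = elastic_modulus_GPa),
    class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s  (rho = %g g/cm3)\n", x$name, x$density_g_cm3))
  comp <- sort(x$composition, decreasing = TRUE)
  cat("  composition (wt): ",
      paste(sprintf("%s %.4f", names(comp), comp), collapse = ", "), "\n")
  invisible(x)
}

#' Matrix--filler mixture specification
#'
#' @param matrix_material Matrix [material()] (e.g. PEEK).
#' @param filler Filler [material()] (e.g. BaSO4).
#' @param filler_weight_fraction Filler weight fraction f in [0, 1].
#' @return An object of class `"mixture_spec"`.
#' @export
mixture_spec <- function(matrix_material, filler, filler_weight_fraction) {
  f <- filler_weight_fraction
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1)
    stop("filler weight fraction must lie in [0, 1]", call. = FALSE)
  stopifnot(inherits(matrix_material, "material"), inherits(filler, "material"))
  structure(list(matrix = matrix_material, filler = filler, f = f),
            class = "mixture_spec")
}

#' Rule-of-mixtures density
#'
#' Linear weight-fraction combination of the component densities,
#' \eqn{\rho = f\,\rho_{filler} + (1-f)\,\rho_{matrix}}. Exposed as a
#' utility; the shipped study materials use their tabulated bulk densities
#' directly, which do not all satisfy this rule (see the methods vignette).
#'
#' @param spec A [mixture_spec()].
#' @return Mixture density in g/cm^3.
#' @export
mixture_density <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  spec$f * spec$filler$density_g_cm3 + (1 - spec$f) * spec$matrix$density_g_cm3
}

#' Mixture elemental composition
#'
#' Weight fractions of the composite:
#' \eqn{w_e = f\,w_e^{filler} + (1-f)\,w_e^{matrix}}.
#'
#' @param spec A [mixture_spec()].
#' @return Named numeric vector of weight fractions summing to 1.
#' @export
mix_compositions <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  els <- union(names(spec$matrix$composition), names(spec$filler$composition))
  wm <- stats::setNames(numeric(length(els)), els)
  wf <- wm
  wm[names(spec$matrix$composition)] <- spec$matrix$composition
  wf[names(spec$filler$composition)] <- spec$filler$composition
  w <- spec$f * wf + (1 - spec$f) * wm
  w <- w[w > 0]
  validate_composition(w)
  w
}

#' Build a composite material from a mixture specification
#'
#' @param name Composite name.
#' @param spec A [mixture_spec()].
#' @param density_g_cm3 Bulk density of the composite. If `NULL`, the
#'   rule-of-mixtures value from [mixture_density()] is used; the study
#'   composites override it with their tabulated densities.
#' @param elastic_modulus_GPa Optional metadata.
#' @return A [material()].
#' @export
mix_materials <- function(name, spec, density_g_cm3 = NULL,
                          elastic_modulus_GPa = NA_real_) {
  if (is.null(density_g_cm3)) density_g_cm3 <- mixture_density(spec)
  material(name, density_g_cm3, weight_fractions = mix_compositions(spec),
           elastic_modulus_GPa = elastic_modulus_GPa)
}

#' The six study materials
#'
#' Cortical bone, pure PEEK, and PEEK with a 20 wt% filler loading of
#' hydroxyapatite, barium sulfate, bismuth oxide, or tantalum. PEEK is
#' modelled from its repeat unit C19H12O3 (three phenylene rings, two ether
#' oxygens, one carbonyl); bone uses the ICRP cortical-bone elemental
#' composition. Composite bulk densities are the tabulated study values
#' (1.52, 3.84, 1.68, 4.65 g/cm^3), carried as authoritative inputs.
#'
#' @return Named list of six [material()] objects, in the order
#'   `bone`, `PEEK`, `PEEK-HA`, `PEEK-BaSO4`, `PEEK-Bi2O3`, `PEEK-Ta`.
#' @export
#' @examples
#' names(study_materials())
study_materials <- function() {
  peek <- material("PEEK", 1.32, formula = "C19H12O3",
                   elastic_modulus_GPa = 4)
  fillers <- list(
    "PEEK-HA"    = list(material("HA", 3.16, formula = "Ca10(PO4)6(OH)2"),
                        rho = 1.68, em = 5.2),
    "PEEK-BaSO4" = list(material("BaSO4", 4.5, formula = "BaSO4"),
                        rho = 1.52, em = 5),
    "PEEK-Bi2O3" = list(material("Bi2O3", 8.9, formula = "Bi2O3"),
                        rho = 3.84, em = 10.5),
    "PEEK-Ta"    = list(material("Ta", 16.65, formula = "Ta"),
                        rho = 4.65, em = 11))
  bone <- material(
    "bone", 1.92,
    weight_fractions = c(H = 0.034, C = 0.155, N = 0.042, O = 0.435,
                         Na = 0.001, Mg = 0.002, P = 0.103, S = 0.003,
                         Ca = 0.225))
  out <- list(bone = bone, PEEK = peek)
  for (nm in names(fillers)) {
    fl <- fillers[[nm]]
    out[[nm]] <- mix_materials(nm, mixture_spec(peek, fl[[1]], 0.2),
                               density_g_cm3 = fl$rho,
                               elastic_modulus_GPa = fl$em)
  }
  out
}

#' Read / write materials as YAML
#'
#' Small schema: a list of entries with `name`, `density_g_cm3`, one of
#' `formula` or `weight_fractions`, and optional `elastic_modulus_GPa`.
#' The six study materials ship as `extdata/materials.yaml`.
#'
#' @param path File path.
#' @return `read_materials()`: named list of [material()] objects.
#' @export
read_materials <- function(path) {
  raw <- yaml::read_yaml(path)
  mats <- lapply(raw, function(m) {
    wf <- if (!is.null(m$weight_fractions)) unlist(m$weight_fractions)
    material(m$name, m$density_g_cm3, formula = m$formula,
             weight_fractions = wf,
             elastic_modulus_GPa = m$elastic_modulus_GPa %||% NA_real_)
  })
  stats::setNames(mats, vapply(mats, `[[`, "", "name"))
}

#' @param materials Named list of [material()] objects.
#' @rdname read_materials
#' @export
write_materials <- function(materials, path) {
  entries <- lapply(materials, function(m) {
    e <- list(name = m$name, density_g_cm3 = m$density_g_cm3)
    if (!is.null(m$formula)) e$formula <- m$formula
    else e$weight_fractions <- as.list(m$composition)
    if (!is.na(m$elastic_modulus_GPa))
      e$elastic_modulus_GPa <- m$elastic_modulus_GPa
    e
  })
  yaml::write_yaml(unname(entries), path, precision = 12)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
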