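# Per-element photoatomic model. The photoelectric term is a two-branch
# power law a*E^-p per element with an upward jump at the K-edge; branch
# coefficients are derived from anchor constants embedded in the packaged
# fixture (extdata/photoatomic_anchors.csv). The incoherent term is the
# analytic free-electron Klein-Nishina cross-section; the coherent term is
# a per-element power law from the same fixture. Coefficients are cm^2/g,
# energies keV, valid on 10-150 keV.

.LIB_EMIN <- 10
.LIB_EMAX <- 150

.photoatomic_anchors <- function() {
  an <- .radiopeek_env$anchors
  if (is.null(an)) {
    path <- system.file("extdata", "photoatomic_anchors.csv",
                        package = "radiopeek", mustWork = TRUE)
    an <- utils::read.csv(path, stringsAsFactors = FALSE)
    # derive (a, p) of v(E) = a * E^-p from the two anchor points per branch
    an$p <- log(an$v1_cm2_g / an$v2_cm2_g) / log(an$e2_keV / an$e1_keV)
    an$a <- an$v1_cm2_g * an$e1_keV^an$p
    .radiopeek_env$anchors <- an
  }
  an
}

.branch_params <- function(symbol, process, branch) {
  an <- .photoatomic_anchors()
  row <- an[an$symbol == symbol & an$process == process & an$branch == branch, ]
  if (nrow(row) != 1L)
    stop("photoatomic fixture incomplete for element '", symbol, "' (",
         process, "/", branch, ")", call. = FALSE)
  row
}

.check_energy_range <- function(energy_keV) {
  if (any(energy_keV < .LIB_EMIN | energy_keV > .LIB_EMAX))
    stop(sprintf("energy outside library validity range [%g, %g] keV",
                 .LIB_EMIN, .LIB_EMAX), call. = FALSE)
  invisible(energy_keV)
}

#' Photoelectric mass attenuation coefficient of an element
#'
#' Piecewise power law \eqn{a\,E^{-p}} with distinct coefficients below and
#' above the K-edge and a discontinuous upward jump at the edge. By
#' convention an energy exactly at the K-edge returns the above-edge branch.
#'
#' @param symbol Element symbol (must be in [element_table()]).
#' @param energy_keV Photon energies in keV, within the library validity
#'   range 10--150 keV; vectorized.
#' @return Photoelectric mass coefficient(s) in cm^2/g.
#' @export
#' @examples
#' photoelectric_mass_coeff("Ba", c(37.3, 37.4, 37.5))
photoelectric_mass_coeff <- function(symbol, energy_keV) {
  .check_energy_range(energy_keV)
  el <- .element_row(symbol)
  hi <- .branch_params(symbol, "pe", "hi")
  out <- hi$a * energy_keV^(-hi$p)
  if (el$k_edge_keV > 0) {
    below <- energy_keV < el$k_edge_keV
    if (any(below)) {
      lo <- .branch_params(symbol, "pe", "lo")
      out[below] <- lo$a * energy_keV[below]^(-lo$p)
    }
  }
  out
}

#' Incoherent (Compton) mass attenuation coefficient of an element
#'
#' Free-electron Klein--Nishina approximation:
#' \eqn{(Z/A) N_A \sigma_{KN}(E)}. This neglects the incoherent scattering
#' function, the main physics simplification of the library.
#'
#' @inheritParams photoelectric_mass_coeff
#' @return Incoherent mass coefficient(s) in cm^2/g.
#' @export
incoherent_mass_coeff <- function(symbol, energy_keV) {
  .check_energy_range(energy_keV)
  el <- .element_row(symbol)
  (el$z / el$a_weight) * .N_AVOGADRO * kn_total_cross_section(energy_keV)
}

#' Coherent (Rayleigh) mass attenuation coefficient of an element
#'
#' Simple per-element power-law parameterization from the packaged fixture.
#'
#' @inheritParams photoelectric_mass_coeff
#' @return Coherent mass coefficient(s) in cm^2/g.
#' @export
coherent_mass_coeff <- function(symbol, energy_keV) {
  .check_energy_range(energy_keV)
  co <- .branch_params(symbol, "coh", "hi")
  co$a * energy_keV^(-co$p)
}

#' Total mass attenuation coefficient of an element
#'
#' Sum of the photoelectric, incoherent and (optionally) coherent terms.
#'
#' @inheritParams photoelectric_mass_coeff
#' @param include_coherent Include the Rayleigh term (default `TRUE`).
#' @return Total mass attenuation coefficient(s) in cm^2/g.
#' @export
element_mass_attenuation <- function(symbol, energy_keV,
                                     include_coherent = TRUE) {
  out <- photoelectric_mass_coeff(symbol, energy_keV) +
    incoherent_mass_coeff(symbol, energy_keV)
  if (include_coherent) out <- out + coherent_mass_coeff(symbol, energy_keV)
  out
}

#' Energy grid with duplicated K-edge nodes
#'
#' Regular grid from `emin` to `emax` with in-range K-edges of the given
#' elements inserted as duplicated nodes so that tables carry a below-edge
#' and an above-edge value at the same energy.
#'
#' @param emin,emax Grid span in keV (default 20--120, the diagnostic
#'   X-ray imaging range).
#' @param step Grid step in keV (default 0.1).
#' @param elements Character vector of element symbols whose K-edges are
#'   inserted; default all library elements.
#' @return Numeric vector of energies (non-strictly increasing at edges).
#' @export
energy_grid <- function(emin = 20, emax = 120, step = 0.1, elements = NULL) {
  if (emin >= emax || step <= 0) stop("invalid grid", call. = FALSE)
  if (emin < 1) stop("grid minimum must be >= 1 keV", call. = FALSE)
  e <- seq(emin, emax, by = step)
  if (e[length(e)] < emax) e <- c(e, emax)
  el <- element_table()
  if (!is.null(elements)) el <- el[el$symbol %in% elements, ]
  edges <- el$k_edge_keV[el$k_edge_keV > emin & el$k_edge_keV < emax]
  sort(c(e[!e %in% edges], rep(edges, each = 2L)))
}

#' Build the packaged photon-data library
#'
#' Generates per-element tables of photoelectric, incoherent and coherent
#' mass coefficients on an energy grid from the parameterization constants
#' embedded in the packaged fixture. Regeneration is deterministic: the
#' same constants always give the same tables.
#'
#' @inheritParams energy_grid
#' @return An object of class `"photon_library"`: list with `version`,
#'   `elements` (the element table) and `tables`, a named list of
#'   data.frames with columns `energy_keV`, `pe`, `incoh`, `coh`.
#' @export
#' @examples
#' lib <- build_default_library(emin = 20, emax = 40, step = 1)
#' head(lib$tables$Ba)
build_default_library <- function(emin = 20, emax = 120, step = 0.1,
                                  elements = NULL) {
  el <- element_table()
  if (!is.null(elements)) {
    missing <- setdiff(elements, el$symbol)
    if (length(missing))
      stop("library build error: unparameterized element(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    el <- el[el$symbol %in% elements, ]
  }
  tables <- lapply(seq_len(nrow(el)), function(i) {
    sym <- el$symbol[i]
    grid <- energy_grid(emin, emax, step, elements = sym)
    pe <- photoelectric_mass_coeff(sym, grid)
    # duplicated edge node: first row takes the below-edge branch value
    if (el$k_edge_keV[i] > emin && el$k_edge_keV[i] < emax) {
      at_edge <- which(grid == el$k_edge_keV[i])
      lo <- .branch_params(sym, "pe", "lo")
      pe[at_edge[1L]] <- lo$a * grid[at_edge[1L]]^(-lo$p)
    }
    data.frame(energy_keV = grid, pe = pe,
               incoh = incoherent_mass_coeff(sym, grid),
               coh = coherent_mass_coeff(sym, grid))
  })
  structure(list(version = "1.0", elements = el,
                 tables = stats::setNames(tables, el$symbol)),
            class = "photon_library")
}

#' Log--log interpolation on an element photon table
#'
#' Linear interpolation in (ln E, ln coefficient). Duplicated K-edge nodes
#' carry the below/above branch values; a query exactly at the edge energy
#' returns the above-edge value by convention. Queries outside the table
#' span are an error (no extrapolation).
#'
#' @param table A per-element table from [build_default_library()] (columns
#'   `energy_keV`, `pe`, `incoh`, `coh`).
#' @param energy_keV Query energies in keV.
#' @param what Column to interpolate: `"pe"`, `"incoh"`, `"coh"` or
#'   `"total"` (sum of all three).
#' @return Interpolated coefficient(s) in cm^2/g.
#' @export
interpolate_log_log <- function(table, energy_keV,
                                what = c("pe", "incoh", "coh", "total")) {
  what <- match.arg(what)
  e <- table$energy_keV
  v <- if (what == "total") table$pe + table$incoh + table$coh
       else table[[what]]
  if (any(energy_keV < e[1L] | energy_keV > e[length(e)]))
    stop("extrapolation outside the table span is not allowed",
         call. = FALSE)
  # rightmost index with e[i] <= E: at a duplicated edge node this selects
  # the above-edge row, realizing the stated convention
  i <- findInterval(energy_keV, e, rightmost.closed = TRUE)
  exact <- e[i] == energy_keV
  out <- numeric(length(energy_keV))
  out[exact] <- v[i[exact]]
  if (any(!exact)) {
    j <- i[!exact]
    x <- energy_keV[!exact]
    t <- (log(x) - log(e[j])) / (log(e[j + 1L]) - log(e[j]))
    out[!exact] <- exp((1 - t) * log(v[j]) + t * log(v[j + 1L]))
  }
  out
}

#' Write / read a photon library as CSV
#'
#' Serializes the library to `photon_library.csv` (columns `element`,
#' `energy_keV`, `pe`, `incoh`, `coh`), `elements.csv` and a small JSON
#' metadata file in `dir`.
#'
#' @param library A [build_default_library()] object.
#' @param dir Output directory (created if needed).
#' @return `write_photon_library()`: the directory, invisibly;
#'   `read_photon_library()`: a `"photon_library"` object.
#' @export
write_photon_library <- function(library, dir) {
  stopifnot(inherits(library, "photon_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- do.call(rbind, lapply(names(library$tables), function(sym) {
    cbind(element = sym, library$tables[[sym]])
  }))
  utils::write.csv(long, file.path(dir, "photon_library.csv"),
                   row.names = FALSE)
  utils::write.csv(library$elements, file.path(dir, "elements.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(version = library$version),
                       file.path(dir, "photon_library_meta.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_photon_library
#' @export
read_photon_library <- function(dir) {
  long <- utils::read.csv(file.path(dir, "photon_library.csv"),
                          stringsAsFactors = FALSE)
  el <- utils::read.csv(file.path(dir, "elements.csv"),
                        stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "photon_library_meta.json"))
  tables <- lapply(split(long[, -1L], long$element), function(d) {
    rownames(d) <- NULL
    d[order(d$energy_keV), ]
  })
  structure(list(version = meta$version, elements = el,
                 tables = tables[el$symbol]),
            class = "photon_library")
}
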