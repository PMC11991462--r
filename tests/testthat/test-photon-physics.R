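BARN <- 1e-24

test_that("Klein-Nishina total cross-section has the right limits", {
  # Thomson limit as E -> 0
  expect_equal(kn_total_cross_section(0.01) / BARN, 0.6652,
               tolerance = 1e-3)
  # monotone decrease over the diagnostic range
  e <- seq(20, 120, 5)
  expect_true(all(diff(kn_total_cross_section(e)) < 0))
  expect_lt(kn_total_cross_section(120), kn_total_cross_section(20))
  expect_error(kn_total_cross_section(-5), "positive")
})

test_that("KN closed form equals quadrature of the differential", {
  for (E in c(20, 60, 100, 120)) {
    q <- integrate(function(th) 2 * pi * sin(th) * kn_differential(E, th),
                   0, pi, rel.tol = 1e-10)
    expect_equal(kn_total_cross_section(E), q$value, tolerance = 1e-6)
  }
})

test_that("KN differential obeys forward-Thomson and Compton kinematics", {
  r_e2 <- 2.8179403262e-13^2
  expect_equal(kn_differential(60, 0), r_e2, tolerance = 1e-12)
  # backscatter of a 511 keV photon carries a third of the energy
  expect_equal(compton_scattered_energy(511, pi), 511 / 3,
               tolerance = 1e-5)
  expect_error(kn_differential(60, -0.1), "\\[0, pi\\]")
})

test_that("photoelectric term is a two-branch power law with a K-edge jump", {
  eps <- 1e-6
  expect_gt(photoelectric_mass_coeff("Ba", 37.4 + eps),
            photoelectric_mass_coeff("Ba", 37.4 - eps))
  # at the edge the above-branch applies by convention
  expect_equal(photoelectric_mass_coeff("Ba", 37.4),
               photoelectric_mass_coeff("Ba", 37.4 + eps),
               tolerance = 1e-4)
  # log-log slope between 80 and 120 keV equals the branch exponent
  an <- read.csv(system.file("extdata", "photoatomic_anchors.csv",
                             package = "radiopeek"))
  for (sym in c("C", "O", "Ca", "Bi")) {
    row <- an[an$symbol == sym & an$process == "pe" & an$branch == "hi", ]
    p_anchor <- log(row$v1_cm2_g / row$v2_cm2_g) / log(row$e2_keV / row$e1_keV)
    # stay on one branch: Bi's K-edge (90.5 keV) sits inside 80-120
    lohi <- if (sym == "Bi") c(95, 120) else c(80, 120)
    slope <- log(photoelectric_mass_coeff(sym, lohi[1]) /
                   photoelectric_mass_coeff(sym, lohi[2])) /
      log(lohi[2] / lohi[1])
    expect_equal(slope, p_anchor, tolerance = 1e-6)
  }
  # the parameterization reproduces its stored anchor constants
  for (i in seq_len(nrow(an))) {
    if (an$process[i] != "pe") next
    expect_equal(photoelectric_mass_coeff(an$symbol[i], an$e1_keV[i]),
                 an$v1_cm2_g[i], tolerance = 5e-3)
  }
  expect_error(photoelectric_mass_coeff("C", 5), "validity range")
})

test_that("element totals sum their parts and order physically", {
  e <- c(20, 50, 100, 150)
  for (sym in c("H", "C", "Ba", "Bi")) {
    expect_equal(element_mass_attenuation(sym, e),
                 photoelectric_mass_coeff(sym, e) +
                   incoherent_mass_coeff(sym, e) +
                   coherent_mass_coeff(sym, e), tolerance = 1e-14)
    expect_lt(max(element_mass_attenuation(sym, e, include_coherent = FALSE) -
                    element_mass_attenuation(sym, e)), 0)
  }
  # for hydrogen at 100 keV incoherent scattering dominates strongly
  expect_gt(incoherent_mass_coeff("H", 100) /
              photoelectric_mass_coeff("H", 100), 10)
})

test_that("library tables satisfy their invariants", {
  lib <- build_default_library()
  expect_setequal(names(lib$tables),
                  c("H", "C", "N", "O", "Na", "Mg", "P", "S", "Ca",
                    "Ba", "Ta", "Bi"))
  for (sym in names(lib$tables)) {
    tb <- lib$tables[[sym]]
    expect_true(all(tb$pe > 0 & tb$incoh > 0 & tb$coh > 0))
    kk <- lib$elements$k_edge_keV[lib$elements$symbol == sym]
    dup <- which(duplicated(tb$energy_keV))
    if (kk > 20 && kk < 120) {
      # exactly one upward jump, between the duplicated edge nodes
      expect_length(dup, 1L)
      expect_equal(tb$energy_keV[dup], kk)
      expect_gt(tb$pe[dup], tb$pe[dup - 1L])
      # pe non-increasing away from the edge
      expect_true(all(diff(tb$pe[seq_len(dup - 1L)]) <= 0))
      expect_true(all(diff(tb$pe[dup:nrow(tb)]) <= 0))
    } else {
      expect_length(dup, 0L)
      expect_true(all(diff(tb$pe) <= 0))
      # total strictly decreasing off-edge
      tot <- tb$pe + tb$incoh + tb$coh
      expect_true(all(diff(tot) < 0))
    }
  }
  # deterministic regeneration
  expect_identical(lib$tables, build_default_library()$tables)
  expect_error(build_default_library(elements = c("C", "Xx")),
               "Xx")
})

test_that("log-log interpolation is exact on power laws and at nodes", {
  lib <- build_default_library(emin = 20, emax = 60, step = 0.5)
  tb <- lib$tables$C
  # node identity
  expect_equal(interpolate_log_log(tb, tb$energy_keV, "pe"), tb$pe,
               tolerance = 1e-14)
  # a pure power law interpolates exactly anywhere
  set.seed(1)
  q <- runif(50, 20, 60)
  expect_equal(interpolate_log_log(tb, q, "pe"),
               photoelectric_mass_coeff("C", q), tolerance = 1e-12)
  # edge convention: query at the K-edge returns the above-edge branch
  tba <- build_default_library(emin = 20, emax = 60, step = 0.5)$tables$Ba
  dup <- which(duplicated(tba$energy_keV))
  expect_equal(interpolate_log_log(tba, 37.4, "pe"), tba$pe[dup])
  expect_error(interpolate_log_log(tb, 10, "pe"), "extrapolation")
})

test_that("library CSV serialization round-trips", {
  lib <- build_default_library(emin = 20, emax = 40, step = 1)
  dir <- tempfile()
  write_photon_library(lib, dir)
  back <- read_photon_library(dir)
  expect_equal(back$version, lib$version)
  expect_named(back$tables, names(lib$tables))
  expect_equal(back$tables$Ba$pe, lib$tables$Ba$pe, tolerance = 1e-12)
})
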