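test_that("mixture rule is exactly linear in weight fractions", {
  e <- c(25, 60, 110)
  carbon <- material("graphite", 2.2, weight_fractions = c(C = 1))
  expect_equal(mixture_mu_m(carbon, e), element_mass_attenuation("C", e),
               tolerance = 1e-14)
  blend <- material("CO-blend", 1.5, weight_fractions = c(C = 0.5, O = 0.5))
  expect_equal(mixture_mu_m(blend, e),
               (element_mass_attenuation("C", e) +
                  element_mass_attenuation("O", e)) / 2, tolerance = 1e-14)
})

test_that("transmission and HVL satisfy their defining identities", {
  expect_identical(transmission(0.5, 0), 1)
  expect_equal(transmission(log(2), 1), 0.5, tolerance = 1e-12)
  mu <- 0.37
  expect_equal(transmission(mu, 2), transmission(mu, 1)^2,
               tolerance = 1e-12)
  expect_error(transmission(0.5, -1), "non-negative")
  expect_equal(hvl(log(2)), 1, tolerance = 1e-12)
  expect_equal(hvl(2 * mu), hvl(mu) / 2, tolerance = 1e-12)
  expect_equal(transmission(mu, hvl(mu)), 0.5, tolerance = 1e-12)
  expect_error(hvl(0), "positive")
})

test_that("cross-sections reduce correctly for pure elements", {
  e <- c(30, 60, 100)
  carbon <- material("graphite", 2.2, weight_fractions = c(C = 1))
  mu_m <- mixture_mu_m(carbon, e)
  expect_equal(total_atomic_cross_section(carbon, e),
               mu_m * 12.011 / AVOGADRO, tolerance = 1e-12)
  expect_equal(total_electronic_cross_section(carbon, e),
               total_atomic_cross_section(carbon, e) / 6, tolerance = 1e-12)
})

test_that("water cross-sections match molecule-level brute-force oracles", {
  water <- material("water", 1.0, formula = "H2O")
  for (E in c(30, 60, 100)) {
    mu_h <- element_mass_attenuation("H", E)
    mu_o <- element_mass_attenuation("O", E)
    # per-molecule sum of atomic cross-sections over atoms per molecule
    sig_h <- mu_h * 1.008 / AVOGADRO
    sig_o <- mu_o * 15.999 / AVOGADRO
    expect_equal(total_atomic_cross_section(water, E),
                 (2 * sig_h + sig_o) / 3, tolerance = 1e-9)
    # electron-weighted oracle: sigma_a_i / Z_i weighted by atom fraction
    expect_equal(total_electronic_cross_section(water, E),
                 (2 * sig_h / 1 + sig_o / 8) / 3, tolerance = 1e-9)
  }
  # splitting a weight fraction into identical entries changes nothing
  blend1 <- material("c1", 2, weight_fractions = c(C = 0.6, O = 0.4))
  sig1 <- total_atomic_cross_section(blend1, 60)
  w2 <- c(0.3, 0.3, 0.4)
  a2 <- c(12.011, 12.011, 15.999)
  mu2 <- 0.3 * element_mass_attenuation("C", 60) * 2 +
    0.4 * element_mass_attenuation("O", 60)
  expect_equal(sig1, mu2 / (AVOGADRO * sum(w2 / a2)), tolerance = 1e-12)
})

test_that("Z_eff and N_eff collapse to Z and N_A Z/A for pure elements", {
  el <- element_table()
  grid <- c(20, 37.4, 60, 90, 120)
  for (i in seq_len(nrow(el))) {
    m <- material(el$symbol[i], 1.0,
                  weight_fractions = setNames(1.0, el$symbol[i]))
    expect_equal(z_eff(m, grid), rep(el$z[i], length(grid)),
                 tolerance = 1e-9)
    expect_equal(n_eff(m, grid),
                 rep(AVOGADRO * el$z[i] / el$a_weight[i], length(grid)),
                 tolerance = 1e-9)
  }
  # carbon N_eff ~ 3.008e23 electrons/g
  carbon <- material("graphite", 2.2, weight_fractions = c(C = 1))
  expect_equal(n_eff(carbon, 60), 3.008e23, tolerance = 1e-3)
})

test_that("Z_eff is bounded by constituent Z and rises with heavy fillers", {
  for (m in mats) {
    z <- element_table()$z[match(names(m$composition),
                                 element_table()$symbol)]
    ze <- z_eff(m, c(20, 30, 60, 120))
    expect_true(all(ze >= min(z) - 1e-9 & ze <= max(z) + 1e-9))
  }
  expect_gt(z_eff(mats$`PEEK-Bi2O3`, 30), z_eff(mats$PEEK, 30))
  expect_gt(n_eff(mats$`PEEK-Ta`, 30), n_eff(mats$PEEK, 30))
})

test_that("N_eff times the electronic cross-section recovers mu_m", {
  for (m in mats[c("PEEK", "PEEK-Bi2O3", "bone")]) {
    e <- seq(20, 120, 2.5)
    expect_equal(n_eff(m, e) * total_electronic_cross_section(m, e),
                 mixture_mu_m(m, e), tolerance = 1e-12)
  }
})

test_that("percent increase is a relative difference with sign", {
  expect_equal(percent_increase(0.5, 0.5), 0)
  expect_equal(percent_increase(1, 0.5), 100)
  expect_lt(percent_increase(0.4, 0.5), 0)
  expect_error(percent_increase(1, 0), "positive")
})

test_that("attenuation curves are internally consistent", {
  crv <- attenuation_curve(mats$`PEEK-BaSO4`, step = 0.1)
  expect_s3_class(crv, "attenuation_curve")
  expect_equal(crv$hvl_cm * crv$mu_1_cm, rep(log(2), nrow(crv)),
               tolerance = 1e-12)
  expect_equal(crv$mu_1_cm, crv$mu_m_cm2_g * 1.52, tolerance = 1e-12)
})

test_that("mass attenuation decreases with energy away from K-edges", {
  for (m in mats) {
    crv <- attenuation_curve(m, step = 0.5)
    edge_rows <- which(duplicated(crv$energy_keV))
    keep <- setdiff(seq_len(nrow(crv) - 1L),
                    c(edge_rows - 1L, edge_rows))
    expect_true(all(diff(crv$mu_m_cm2_g)[keep] < 0))
  }
})

test_that("pure PEEK has the lowest mass attenuation among the six", {
  e <- energy_grid(20, 120, 0.1)
  mu <- sapply(mats, function(m) mixture_mu_m(m, e))
  others <- mu[, colnames(mu) != "PEEK"]
  expect_true(all(mu[, "PEEK"] < others))
  # the bismuth-oxide composite always beats PEEK
  expect_true(all(mu[, "PEEK-Bi2O3"] > mu[, "PEEK"]))
})

test_that("K-edge localization finds edges and ignores smooth curves", {
  expect_true(is.na(locate_k_edge(attenuation_curve(mats$PEEK))))
  expect_true(is.na(locate_k_edge(attenuation_curve(mats$bone))))
  expect_true(is.na(locate_k_edge(attenuation_curve(mats$`PEEK-HA`))))
  # synthetic curve with an injected 20% jump at 50.0 keV
  e <- seq(20, 120, 0.1)
  v <- 2 * (e / 20)^-3
  v[e >= 50] <- v[e >= 50] * 1.2
  fake <- data.frame(energy_keV = e, mu_m_cm2_g = v)
  expect_equal(locate_k_edge(fake), 50.0)
  # composite curves locate the filler K-edge stored in the element table
  el <- element_table()
  expect_equal(locate_k_edge(attenuation_curve(mats$`PEEK-BaSO4`)),
               el$k_edge_keV[el$symbol == "Ba"])
  expect_equal(locate_k_edge(attenuation_curve(mats$`PEEK-Ta`)),
               el$k_edge_keV[el$symbol == "Ta"])
  expect_equal(locate_k_edge(attenuation_curve(mats$`PEEK-Bi2O3`)),
               el$k_edge_keV[el$symbol == "Bi"])
  coarse <- attenuation_curve(mats$`PEEK-BaSO4`, step = 1)
  expect_error(locate_k_edge(coarse), "grid too coarse")
})
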