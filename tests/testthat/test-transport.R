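test_that("planar source samples uniform positions and energies along +Z", {
  src <- planar_source(width = 40, height = 30, n_events = 1e5)
  set.seed(42)
  ph <- sample_source(src)
  expect_true(all(ph$dx == 0 & ph$dy == 0 & ph$dz == 1))
  expect_true(all(abs(ph$x) <= 20 & abs(ph$y) <= 15))
  # mean x within 3 sigma of 0; mean E within 3 sigma of 70 keV
  expect_lt(abs(mean(ph$x)), 3 * (40 / sqrt(12)) / sqrt(1e5))
  expect_lt(abs(mean(ph$energy_keV) - 70), 3 * (100 / sqrt(12)) / sqrt(1e5))
  mono <- planar_source(e_min = 60, e_max = 60, n_events = 10)
  expect_true(all(sample_source(mono)$energy_keV == 60))
  expect_error(planar_source(e_min = 100, e_max = 50), "e_min")
})

test_that("free-path sampling reproduces the exponential law", {
  mu <- 0.8
  set.seed(42)
  d <- distance_to_interaction(rep(mu, 1e5))
  expect_lt(abs(mean(d) - 1 / mu), 3 * (1 / mu) / sqrt(1e5))
  # half the draws exceed the HVL (median = ln2 / mu)
  p_hvl <- mean(d > hvl(mu))
  expect_lt(abs(p_hvl - 0.5), 3 * 0.5 / sqrt(1e5))
  set.seed(7); a <- distance_to_interaction(rep(mu, 100))
  set.seed(7); b <- distance_to_interaction(rep(mu, 100))
  expect_identical(a, b)
})

test_that("interaction selection follows the partial coefficients", {
  set.seed(42)
  # Rayleigh disabled -> never selected
  procs <- select_interaction(mats$PEEK, rep(60, 1000),
                              include_coherent = FALSE)
  expect_false(any(procs == "rayleigh"))
  # hydrogen at 120 keV is essentially pure Compton
  h <- material("H", 0.07, weight_fractions = c(H = 1))
  expect_gt(mean(select_interaction(h, rep(120, 1e4)) == "compton"), 0.99)
  # Bi2O3 at 25 keV: photoelectric fraction matches pe / total within 3 sigma
  bi <- material("Bi2O3", 8.9, formula = "Bi2O3")
  n <- 1e5
  got <- mean(select_interaction(bi, rep(25, n)) == "photoelectric")
  w <- bi$composition
  pe <- sum(sapply(names(w), function(s)
    w[[s]] * photoelectric_mass_coeff(s, 25)))
  tot <- sum(sapply(names(w), function(s)
    w[[s]] * element_mass_attenuation(s, 25)))
  p <- pe / tot
  expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("Compton sampling conserves energy and matches the KN density", {
  set.seed(42)
  E <- 60
  cs <- do_compton(rep(E, 1e5))
  expect_equal(cs$scattered_keV + cs$electron_keV, rep(E, 1e5),
               tolerance = 1e-14)
  # kinematic backscatter bound
  k <- E / 510.99895
  expect_true(all(cs$scattered_keV >= E / (1 + 2 * k) - 1e-12))
  # goodness of fit of sampled angles against the analytic density
  edges <- seq(0, pi, length.out = 21)
  dens <- function(th) 2 * pi * sin(th) * kn_differential(E, th)
  probs <- vapply(seq_len(20), function(i)
    integrate(dens, edges[i], edges[i + 1])$value, numeric(1))
  probs <- probs / sum(probs)
  counts <- tabulate(findInterval(cs$theta, edges,
                                  rightmost.closed = TRUE), nbins = 20)
  gof <- suppressWarnings(chisq.test(counts, p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("photoelectric absorption deposits the full energy", {
  pe <- do_photoelectric(c(30, 80))
  expect_equal(pe$deposit_keV, c(30, 80))
  expect_true(all(pe$terminated))
})

test_that("electron range proxy is monotone and density-scaled", {
  expect_equal(electron_range(0, mats$PEEK), 0)
  expect_gt(electron_range(100, mats$PEEK), electron_range(50, mats$PEEK))
  expect_gt(electron_range(80, mats$PEEK), electron_range(80, mats$`PEEK-Ta`))
  expect_equal(electron_range(80, mats$PEEK) /
                 electron_range(80, mats$`PEEK-Ta`), 4.65 / 1.32,
               tolerance = 1e-12)
})

test_that("empty geometry yields zero deposits and full escape", {
  src <- planar_source(n_events = 100)
  tl <- run_simulation(src, list(), seed = 3)
  expect_equal(sum(tl$grid), 0)
  expect_equal(tl$escaped_keV, tl$emitted_keV)
})

test_that("overlapping volumes are rejected before the run", {
  b1 <- box_volume(mats$PEEK, c(0, 0, 2.5), c(2.5, 2.5, 2.5))
  b2 <- box_volume(mats$bone, c(1, 0, 2.5), c(2.5, 2.5, 2.5))
  expect_error(run_simulation(planar_source(n_events = 10), list(b1, b2)),
               "overlap")
})

test_that("uncollided slab transmission matches Beer-Lambert within 3 sigma", {
  n <- 2e4
  te <- transmission_experiment(mats$bone, 60, c(1, 3, 5), n_photons = n,
                                seed = 42)
  for (i in seq_len(nrow(te))) {
    p <- te$analytic_transmission[i]
    expect_lt(abs(te$mc_transmission[i] - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("simulation conserves energy and is seed-reproducible", {
  src <- planar_source(width = 20, height = 20, n_events = 5000)
  vols <- list(box_volume(mats$PEEK, c(-4, 0, 2.5), c(2.5, 2.5, 2.5)),
               box_volume(mats$`PEEK-Bi2O3`, c(4, 0, 2.5), c(2.5, 2.5, 2.5)))
  tl1 <- run_simulation(src, vols, grid_n = c(30, 15, 15), seed = 42)
  expect_equal(sum(tl1$per_event) + tl1$escaped_keV, tl1$emitted_keV,
               tolerance = 1e-6)
  expect_equal(sum(tl1$grid), sum(tl1$per_event), tolerance = 1e-9)
  # per-volume grid sums match per-volume deposit totals
  for (v in seq_along(vols)) {
    rng <- radiopeek:::.voxel_ranges(tl1, v)
    expect_equal(sum(tl1$grid[rng[[1]], rng[[2]], rng[[3]]]),
                 tl1$per_volume$total_edep_keV[v], tolerance = 1e-9)
  }
  tl2 <- run_simulation(src, vols, grid_n = c(30, 15, 15), seed = 42)
  expect_identical(tl1$per_event, tl2$per_event)
  expect_identical(tl1$grid, tl2$grid)
})

test_that("projections conserve the deposited energy", {
  arr <- array(0, dim = c(4, 5, 6))
  expect_equal(sum(project(arr, "XY")$pixels), 0)
  arr[2, 3, 4] <- 7
  for (pl in c("XY", "XZ", "YZ")) {
    pm <- project(arr, pl)
    expect_equal(sum(pm$pixels), 7)
    expect_equal(sum(pm$pixels > 0), 1)
  }
  expect_error(project(arr, "QQ"))
})

test_that("mean deposit tracks the linear attenuation ordering (thin slabs)", {
  # thin boxes avoid saturation so deposits order like mu at the mean energy
  src <- planar_source(width = 12, height = 12, e_min = 70, e_max = 70,
                       n_events = 5e4)
  sel <- mats[c("PEEK", "PEEK-HA", "PEEK-BaSO4", "PEEK-Ta")]
  pitch <- 3
  vols <- lapply(seq_along(sel), function(i)
    box_volume(sel[[i]], c(-4.5 + (i - 1) * pitch, 0, 0.1),
               c(1, 1, 0.1), name = names(sel)[i]))
  tl <- run_simulation(src, vols, grid_n = c(40, 10, 2), seed = 42)
  mu <- vapply(sel, function(m) linear_mu(m, 70), numeric(1))
  expect_equal(order(tl$per_volume$mean_edep_keV), order(mu))
})
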