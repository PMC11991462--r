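# Monte Carlo photon transport: planar source, box phantoms in vacuum,
# photoelectric / Compton / Rayleigh interactions, energy-deposition and
# track-length tallies on a voxel grid. Analog transport (no variance
# reduction); charged-particle energy deposits at the interaction point.

#' Planar X-ray source
#'
#' A rectangular plate source emitting photons along +Z with positions
#' uniform over the plate and energies uniform on `[e_min, e_max]` keV
#' (`e_min == e_max` gives a monoenergetic beam).
#'
#' @param width,height Plate dimensions in cm (default 100 x 100).
#' @param z_position Plate Z coordinate in cm (default -50, in front of
#'   volumes placed at Z = 0).
#' @param e_min,e_max Energy range in keV (default 20--120).
#' @param n_events Number of source photons.
#' @return An object of class `"planar_source"`.
#' @export
planar_source <- function(width = 100, height = 100, z_position = -50,
                          e_min = 20, e_max = 120, n_events = 1e5) {
  if (width <= 0 || height <= 0) stop("plate dimensions must be positive",
                                      call. = FALSE)
  if (e_min > e_max) stop("e_min must be <= e_max", call. = FALSE)
  if (n_events < 1) stop("n_events must be >= 1", call. = FALSE)
  structure(list(width = width, height = height, z_position = z_position,
                 e_min = e_min, e_max = e_max,
                 n_events = as.integer(n_events)),
            class = "planar_source")
}

#' Sample photons from a planar source
#'
#' X and Y are uniform over the plate, Z is the plate position, the
#' direction is exactly +Z, and the energy is uniform on the source range.
#' Draws from the current R random stream.
#'
#' @param source A [planar_source()].
#' @param n Number of photons (default `source$n_events`).
#' @return data.frame with `x`, `y`, `z` (cm), `dx`, `dy`, `dz`,
#'   `energy_keV`.
#' @export
sample_source <- function(source, n = source$n_events) {
  stopifnot(inherits(source, "planar_source"))
  data.frame(
    x = stats::runif(n, -source$width / 2, source$width / 2),
    y = stats::runif(n, -source$height / 2, source$height / 2),
    z = rep(source$z_position, n),
    dx = 0, dy = 0, dz = 1,
    energy_keV = if (source$e_min == source$e_max) rep(source$e_min, n)
                 else stats::runif(n, source$e_min, source$e_max))
}

#' Box phantom volume
#'
#' Axis-aligned box of a single material, placed in vacuum.
#'
#' @param material A [material()].
#' @param center Numeric length-3 center (cm).
#' @param half_widths Numeric length-3 half-widths (cm, > 0).
#' @param name Volume label (defaults to the material name).
#' @return An object of class `"box_volume"`.
#' @export
box_volume <- function(material, center, half_widths,
                       name = material$name) {
  stopifnot(inherits(material, "material"),
            length(center) == 3L, length(half_widths) == 3L)
  if (any(half_widths <= 0)) stop("half-widths must be positive",
                                  call. = FALSE)
  structure(list(material = material, center = as.numeric(center),
                 half = as.numeric(half_widths), name = name),
            class = "box_volume")
}

#' Exponential free-path sampling
#'
#' Distance to the next interaction, \eqn{-\ln(u)/\mu}, drawn from the
#' current R random stream.
#'
#' @param mu Total linear attenuation coefficient(s), 1/cm (> 0).
#' @param n Number of draws (default `length(mu)`).
#' @return Distances in cm.
#' @export
distance_to_interaction <- function(mu, n = length(mu)) {
  if (any(mu <= 0)) stop("mu must be positive", call. = FALSE)
  -log(stats::runif(n)) / mu
}

# per-process mass coefficients of a material (cm^2/g), vectorized over E
.material_mu_parts <- function(material, energy_keV, include_coherent = TRUE) {
  w <- material$composition
  pe <- incoh <- coh <- 0
  for (sym in names(w)) {
    pe <- pe + w[[sym]] * photoelectric_mass_coeff(sym, energy_keV)
    incoh <- incoh + w[[sym]] * incoherent_mass_coeff(sym, energy_keV)
    if (include_coherent)
      coh <- coh + w[[sym]] * coherent_mass_coeff(sym, energy_keV)
  }
  if (!include_coherent) coh <- rep(0, length(energy_keV))
  list(pe = pe, incoh = incoh, coh = coh, total = pe + incoh + coh)
}

#' Sample the interaction process
#'
#' Chooses photoelectric, Compton or Rayleigh with probability proportional
#' to the partial linear attenuation coefficients of the material at each
#' photon energy (same photoatomic library as the attenuation module).
#'
#' @param material A [material()].
#' @param energy_keV Photon energies in keV; vectorized.
#' @param include_coherent If `FALSE`, Rayleigh scattering is disabled.
#' @return Character vector in `c("photoelectric", "compton", "rayleigh")`.
#' @export
select_interaction <- function(material, energy_keV,
                               include_coherent = TRUE) {
  parts <- .material_mu_parts(material, energy_keV, include_coherent)
  u <- stats::runif(length(energy_keV)) * parts$total
  ifelse(u < parts$pe, "photoelectric",
         ifelse(u < parts$pe + parts$incoh, "compton", "rayleigh"))
}

#' Secondary-electron range proxy
#'
#' Continuous-slowing-down-style power-law range estimate,
#' \eqn{R = 0.0143\,(E/100)^{1.7} / \rho} cm (returned in mm): monotone in
#' energy, zero at zero, and scaling with inverse density. A proxy for the
#' track length of locally deposited secondary electrons; no electron
#' transport is performed.
#'
#' @param energy_keV Electron energy in keV (>= 0); vectorized.
#' @param material A [material()].
#' @return Range(s) in mm.
#' @export
electron_range <- function(energy_keV, material) {
  if (any(energy_keV < 0)) stop("energy must be >= 0", call. = FALSE)
  10 * 0.0143 * (energy_keV / 100)^1.7 / material$density_g_cm3
}

# slab-method ray/box intersection, vectorized over photon rows
.ray_box <- function(pos, dir, lo, hi) {
  d <- dir
  d[abs(d) < 1e-12] <- 1e-12
  t1 <- sweep(-pos, 2, lo, `+`) / d   # (lo - pos) / d
  t2 <- sweep(-pos, 2, hi, `+`) / d
  tmin <- pmax(pmin(t1[, 1], t2[, 1]),
               pmin(t1[, 2], t2[, 2]),
               pmin(t1[, 3], t2[, 3]))
  tmax <- pmin(pmax(t1[, 1], t2[, 1]),
               pmax(t1[, 2], t2[, 2]),
               pmax(t1[, 3], t2[, 3]))
  list(tmin = tmin, tmax = tmax)
}

# rotate unit directions by polar angle theta about themselves, azimuth phi
.rotate_direction <- function(dir, theta, phi) {
  dz_dom <- abs(dir[, 3]) > 0.99
  a <- cbind(ifelse(dz_dom, 1, 0), 0, ifelse(dz_dom, 0, 1))
  u <- cbind(a[, 2] * dir[, 3] - a[, 3] * dir[, 2],
             a[, 3] * dir[, 1] - a[, 1] * dir[, 3],
             a[, 1] * dir[, 2] - a[, 2] * dir[, 1])
  u <- u / sqrt(rowSums(u^2))
  v <- cbind(dir[, 2] * u[, 3] - dir[, 3] * u[, 2],
             dir[, 3] * u[, 1] - dir[, 1] * u[, 3],
             dir[, 1] * u[, 2] - dir[, 2] * u[, 1])
  nd <- cos(theta) * dir +
    sin(theta) * (cos(phi) * u + sin(phi) * v)
  nd / sqrt(rowSums(nd^2))
}

# Thomson-shaped angular sampling for Rayleigh: density prop. to 1+cos^2
.sample_rayleigh_angle <- function(n) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    m <- length(todo)
    ct <- stats::runif(m, -1, 1)
    ok <- stats::runif(m) * 2 < (1 + ct^2)
    out[todo[ok]] <- acos(ct[ok])
    todo <- todo[!ok]
  }
  out
}

#' Run the X-ray imaging Monte Carlo experiment
#'
#' Tracks photons from a planar source through axis-aligned box volumes in
#' vacuum. Interactions are photoelectric absorption (full local deposit),
#' Compton scattering (Klein--Nishina angle sampling, recoil-electron
#' energy deposited locally) and optional Rayleigh scattering (Thomson
#' angular law, no energy loss). Photons leaving the world are dropped;
#' photons falling below `e_cutoff_keV` inside a volume are terminated with
#' a local deposit. Deposited energy is accumulated per event, per volume
#' and on a 3D voxel grid spanning the tight bounding box of all volumes.
#'
#' @param source A [planar_source()].
#' @param volumes List of pairwise non-overlapping [box_volume()]s.
#' @param grid_n Integer length-3 voxel counts (default `c(100, 100, 100)`).
#' @param seed Optional integer seed (`set.seed`) for reproducible runs.
#' @param include_coherent Model Rayleigh scattering (default `TRUE`).
#' @param e_cutoff_keV Photon termination threshold inside a volume
#'   (default 10 keV, the library validity floor; mean free paths there are
#'   well below a millimetre in all study materials).
#' @param batch_size Internal vectorization batch (does not affect physics;
#'   results are reproducible for a fixed seed, config and batch size).
#' @return An object of class `"simulation_tally"`: list with
#'   `per_volume` (data.frame of per-volume statistics), `per_event`
#'   (n_events x n_volumes deposit matrix, keV), `grid` (3D array of
#'   deposited energy, keV), `grid_origin`, `voxel_size`, `emitted_keV`,
#'   `escaped_keV`, `volumes`, `source`, `seed`.
#' @export
run_simulation <- function(source, volumes, grid_n = c(100, 100, 100),
                           seed = NULL, include_coherent = TRUE,
                           e_cutoff_keV = 10, batch_size = 100000L) {
  stopifnot(inherits(source, "planar_source"))
  if (inherits(volumes, "box_volume")) volumes <- list(volumes)
  m <- length(volumes)
  if (m == 0L) {
    if (!is.null(seed)) set.seed(seed)
    emitted <- sum(sample_source(source)$energy_keV)
    return(structure(
      list(per_volume = data.frame(), per_event = matrix(0, source$n_events, 0),
           grid = array(0, dim = as.integer(grid_n)),
           grid_origin = c(0, 0, 0), voxel_size = c(1, 1, 1),
           emitted_keV = emitted, escaped_keV = emitted, volumes = list(),
           source = source, seed = seed),
      class = "simulation_tally"))
  }
  lo <- t(vapply(volumes, function(v) v$center - v$half, numeric(3)))
  hi <- t(vapply(volumes, function(v) v$center + v$half, numeric(3)))
  if (m > 1L) {
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      if (all(lo[i, ] < hi[j, ] & lo[j, ] < hi[i, ]))
        stop("geometry error: volumes ", i, " and ", j, " overlap",
             call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)

  bb_lo <- apply(lo, 2, min)
  bb_hi <- apply(hi, 2, max)
  grid_n <- as.integer(grid_n)
  vox <- (bb_hi - bb_lo) / grid_n
  grid_acc <- numeric(prod(grid_n))

  n_events <- source$n_events
  edep <- matrix(0, nrow = n_events, ncol = m)
  track_mm <- numeric(m)
  n_proc <- matrix(0L, nrow = m, ncol = 3,
                   dimnames = list(NULL, c("photoelectric", "compton",
                                           "rayleigh")))
  emitted <- 0
  escaped <- 0
  eps <- 1e-9

  record_deposit <- function(ev, vol, pos, dep) {
    edep[cbind(ev, vol)] <<- edep[cbind(ev, vol)] + dep
    ix <- pmin(pmax(floor((pos[, 1] - bb_lo[1]) / vox[1]) + 1, 1), grid_n[1])
    iy <- pmin(pmax(floor((pos[, 2] - bb_lo[2]) / vox[2]) + 1, 1), grid_n[2])
    iz <- pmin(pmax(floor((pos[, 3] - bb_lo[3]) / vox[3]) + 1, 1), grid_n[3])
    flat <- ix + grid_n[1] * (iy - 1) + grid_n[1] * grid_n[2] * (iz - 1)
    agg <- rowsum(dep, flat)
    fi <- as.integer(rownames(agg))
    grid_acc[fi] <<- grid_acc[fi] + agg[, 1]
  }

  batches <- split(seq_len(n_events),
                   ceiling(seq_len(n_events) / batch_size))
  for (batch in batches) {
    nb <- length(batch)
    ph <- sample_source(source, nb)
    pos <- cbind(ph$x, ph$y, ph$z)
    dir <- cbind(ph$dx, ph$dy, ph$dz)
    E <- ph$energy_keV
    emitted <- emitted + sum(E)
    alive <- rep(TRUE, nb)
    iter <- 0L

    while (any(alive)) {
      iter <- iter + 1L
      if (iter > 10000L) stop("transport did not terminate", call. = FALSE)
      idx <- which(alive)
      p <- pos[idx, , drop = FALSE]
      d <- dir[idx, , drop = FALSE]
      # containing volume (0 = vacuum); boxes are non-overlapping
      vol <- integer(length(idx))
      for (v in seq_len(m)) {
        ins <- p[, 1] > lo[v, 1] & p[, 1] < hi[v, 1] &
               p[, 2] > lo[v, 2] & p[, 2] < hi[v, 2] &
               p[, 3] > lo[v, 3] & p[, 3] < hi[v, 3]
        vol[ins] <- v
      }

      # --- photons in vacuum: fly to the nearest box or escape
      vac <- vol == 0L
      if (any(vac)) {
        pv <- p[vac, , drop = FALSE]
        dv <- d[vac, , drop = FALSE]
        t_entry <- rep(Inf, sum(vac))
        for (v in seq_len(m)) {
          ib <- .ray_box(pv, dv, lo[v, ], hi[v, ])
          valid <- ib$tmax > pmax(ib$tmin, 0) & ib$tmin > eps
          t_entry[valid] <- pmin(t_entry[valid], ib$tmin[valid])
        }
        esc <- !is.finite(t_entry)
        gi <- idx[vac]
        if (any(esc)) {
          escaped <- escaped + sum(E[gi[esc]])
          alive[gi[esc]] <- FALSE
        }
        adv <- !esc
        if (any(adv)) {
          pos[gi[adv], ] <- pv[adv, , drop = FALSE] +
            dv[adv, , drop = FALSE] * (t_entry[adv] + eps)
        }
      }

      # --- photons inside a volume, grouped by volume
      for (v in unique(vol[vol > 0L])) {
        sel <- vol == v
        gi <- idx[sel]
        pv <- p[sel, , drop = FALSE]
        dv <- d[sel, , drop = FALSE]
        Ev <- E[gi]
        mat <- volumes[[v]]$material
        parts <- .material_mu_parts(mat, Ev, include_coherent)
        mu_tot <- parts$total * mat$density_g_cm3
        s <- distance_to_interaction(mu_tot)
        t_exit <- .ray_box(pv, dv, lo[v, ], hi[v, ])$tmax
        leave <- s >= t_exit
        if (any(leave)) {
          pos[gi[leave], ] <- pv[leave, , drop = FALSE] +
            dv[leave, , drop = FALSE] * (t_exit[leave] + eps)
        }
        act <- which(!leave)
        if (!length(act)) next
        ga <- gi[act]
        pa <- pv[act, , drop = FALSE] + dv[act, , drop = FALSE] * s[act]
        pos[ga, ] <- pa
        Ea <- Ev[act]
        u <- stats::runif(length(act)) * (parts$total[act])
        is_pe <- u < parts$pe[act]
        is_co <- !is_pe & u < parts$pe[act] + parts$incoh[act]
        is_ra <- !is_pe & !is_co

        if (any(is_pe)) {
          n_proc[v, "photoelectric"] <- n_proc[v, "photoelectric"] +
            sum(is_pe)
          record_deposit(ga[is_pe], v, pa[is_pe, , drop = FALSE], Ea[is_pe])
          track_mm[v] <- track_mm[v] + sum(electron_range(Ea[is_pe], mat))
          alive[ga[is_pe]] <- FALSE
        }
        if (any(is_co)) {
          n_proc[v, "compton"] <- n_proc[v, "compton"] + sum(is_co)
          cs <- do_compton(Ea[is_co])
          dep <- cs$electron_keV
          record_deposit(ga[is_co], v, pa[is_co, , drop = FALSE], dep)
          track_mm[v] <- track_mm[v] + sum(electron_range(dep, mat))
          dir[ga[is_co], ] <- .rotate_direction(d[sel, , drop = FALSE][
            act[is_co], , drop = FALSE], cs$theta, cs$phi)
          E[ga[is_co]] <- cs$scattered_keV
          # terminate photons below the tracking cutoff with a local deposit
          low <- cs$scattered_keV < e_cutoff_keV
          if (any(low)) {
            gl <- ga[is_co][low]
            record_deposit(gl, v,
                           pa[is_co, , drop = FALSE][low, , drop = FALSE],
                           cs$scattered_keV[low])
            track_mm[v] <- track_mm[v] +
              sum(electron_range(cs$scattered_keV[low], mat))
            alive[gl] <- FALSE
          }
        }
        if (any(is_ra)) {
          n_proc[v, "rayleigh"] <- n_proc[v, "rayleigh"] + sum(is_ra)
          th <- .sample_rayleigh_angle(sum(is_ra))
          phi <- stats::runif(sum(is_ra), 0, 2 * pi)
          dir[ga[is_ra], ] <- .rotate_direction(d[sel, , drop = FALSE][
            act[is_ra], , drop = FALSE], th, phi)
        }
      }
    }
  }

  totals <- colSums(edep)
  means <- totals / n_events
  rms <- sqrt(colMeans(sweep(edep, 2, means)^2))
  per_volume <- data.frame(
    volume = vapply(volumes, `[[`, "", "name"),
    material = vapply(volumes, function(v) v$material$name, ""),
    n_events = n_events,
    total_edep_keV = totals,
    mean_edep_keV = means,
    mean_edep_eV = means * 1000,
    rms_edep_keV = rms,
    track_length_mm = track_mm,
    n_photoelectric = n_proc[, "photoelectric"],
    n_compton = n_proc[, "compton"],
    n_rayleigh = n_proc[, "rayleigh"])
  structure(list(per_volume = per_volume, per_event = edep,
                 grid = array(grid_acc, dim = grid_n),
                 grid_origin = bb_lo, voxel_size = vox,
                 emitted_keV = emitted, escaped_keV = escaped,
                 volumes = volumes, source = source, seed = seed),
            class = "simulation_tally")
}

#' @export
print.simulation_tally <- function(x, ...) {
  cat(sprintf("<simulation_tally> %d events, %d volume(s)\n",
              x$per_volume$n_events[1], nrow(x$per_volume)))
  print(x$per_volume[, c("volume", "mean_edep_eV", "rms_edep_keV",
                         "track_length_mm")], row.names = FALSE)
  invisible(x)
}

# voxel index ranges overlapping volume v, per axis
.voxel_ranges <- function(tally, v) {
  vol <- tally$volumes[[v]]
  lo <- vol$center - vol$half
  hi <- vol$center + vol$half
  n <- dim(tally$grid)
  lapply(1:3, function(ax) {
    i1 <- max(1L, floor((lo[ax] - tally$grid_origin[ax]) /
                          tally$voxel_size[ax]) + 1L)
    i2 <- min(n[ax], ceiling((hi[ax] - tally$grid_origin[ax]) /
                               tally$voxel_size[ax]))
    i1:i2
  })
}

#' Project the deposition grid onto an image plane
#'
#' Sums the 3D deposited-energy grid along the axis orthogonal to the
#' requested plane. The map total equals the grid total.
#'
#' @param tally A [run_simulation()] tally (or a bare 3D array).
#' @param plane `"XY"`, `"XZ"` or `"YZ"`.
#' @return An object of class `"projection_map"`: list with `plane`,
#'   `pixels` (matrix of deposited energy, keV), `pixel_size` (cm) and,
#'   when projected from a tally, per-volume footprint `masks`.
#' @export
project <- function(tally, plane = c("XY", "XZ", "YZ")) {
  plane <- match.arg(plane)
  grid <- if (inherits(tally, "simulation_tally")) tally$grid else tally
  stopifnot(length(dim(grid)) == 3L)
  keep <- switch(plane, XY = c(1L, 2L), XZ = c(1L, 3L), YZ = c(2L, 3L))
  px <- apply(grid, keep, sum)
  out <- list(plane = plane, pixels = px, pixel_size = NULL, masks = NULL)
  if (inherits(tally, "simulation_tally")) {
    out$pixel_size <- tally$voxel_size[keep]
    out$masks <- lapply(seq_along(tally$volumes), function(v) {
      rng <- .voxel_ranges(tally, v)
      msk <- matrix(FALSE, nrow = dim(grid)[keep[1]],
                    ncol = dim(grid)[keep[2]])
      msk[rng[[keep[1]]], rng[[keep[2]]]] <- TRUE
      msk
    })
    names(out$masks) <- vapply(tally$volumes, `[[`, "", "name")
  }
  structure(out, class = "projection_map")
}

#' Monte Carlo slab transmission experiment
#'
#' Counts photons of a monoenergetic pencil beam that cross a slab of the
#' given thickness without interacting, using the simulator's exponential
#' free-path sampling and the same photoatomic library as the analytic
#' attenuation module. The uncollided fraction estimates the Beer--Lambert
#' transmission \eqn{e^{-\mu x}}.
#'
#' @param material A [material()].
#' @param energy_keV Beam energy (keV).
#' @param thickness_cm Vector of slab thicknesses (cm).
#' @param n_photons Photons per thickness.
#' @param seed Optional integer seed.
#' @param include_coherent Passed to the attenuation library.
#' @return data.frame with `thickness_cm`, `n_photons`, `transmitted`,
#'   `mc_transmission`, `analytic_transmission`.
#' @export
transmission_experiment <- function(material, energy_keV, thickness_cm,
                                    n_photons = 1e5, seed = NULL,
                                    include_coherent = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  mu <- linear_mu(material, energy_keV, include_coherent)
  transmitted <- vapply(thickness_cm, function(x) {
    sum(distance_to_interaction(rep(mu, n_photons)) > x)
  }, numeric(1))
  data.frame(thickness_cm = thickness_cm, n_photons = n_photons,
             transmitted = transmitted,
             mc_transmission = transmitted / n_photons,
             analytic_transmission = transmission(mu, thickness_cm))
}
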