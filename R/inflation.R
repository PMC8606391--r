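# Quasi-static inflation of a sleeve geometry over a pressure schedule.
# Every axial station is an independent incompressible plane-strain ring;
# end fixity at the two junctions is imposed as a smooth attenuation of the
# stretch profile whose characteristic length is the deformed radius at the
# clamped end. Volumes follow the insufflated-volume convention (deformed lumen
# minus reference lumen) unless "total" is requested.

#' Pressure schedule
#'
#' Ordered target intragastric pressures in mmHg. Must be strictly
#' increasing and non-negative; schedules beyond `max_mmhg` (default 75,
#' the upper bound of the simulated loading) are rejected.
#'
#' @param pressures_mmhg Numeric vector of pressures in mmHg.
#' @param max_mmhg Upper admissible pressure.
#' @return The validated numeric vector with class `pressure_schedule`.
#' @export
pressure_schedule <- function(pressures_mmhg = c(7.5, 15, 22.5, 37.5, 75),
                              max_mmhg = 75) {
  p <- as.numeric(pressures_mmhg)
  if (length(p) == 0 || any(!is.finite(p)) || any(p < 0)) {
    stop("pressures must be finite and non-negative (mmHg)")
  }
  if (length(p) > 1 && any(diff(p) <= 0)) {
    stop("pressure schedule must be strictly increasing")
  }
  if (max(p) > max_mmhg) {
    stop(sprintf("pressure schedule exceeds %g mmHg", max_mmhg))
  }
  structure(p, class = "pressure_schedule")
}

# Safeguarded Newton with bisection fallback, vectorised across rings.
# Solves P(lam) = p_kpa per ring to |residual| <= 1e-10 kPa (or a 1e-12
# stretch step). lam is bracketed in [1, lam_max].
.solve_rings_vec <- function(Ri, Rm, Ro, stack, p_kpa, lam0 = NULL,
                             n_gauss = 16, lam_max = 5) {
  n <- length(Ri)
  p_kpa <- rep_len(p_kpa, n)
  lam <- rep(1, n)
  active <- p_kpa > 0
  if (!any(active)) return(lam)

  idx <- which(active)
  quad <- .ring_quad(Ri[idx], Rm[idx], Ro[idx], n_gauss)
  p_hi <- .ring_eval(quad, stack, rep(lam_max, length(idx)))$p
  if (any(p_hi < p_kpa[idx])) {
    bad <- idx[which(p_hi < p_kpa[idx])[1]]
    stop(sprintf(
      "material too soft: pressure %.4g kPa not reached at stretch %g (ring %d)",
      p_kpa[bad], lam_max, bad
    ))
  }

  lo <- rep(1, length(idx))
  hi <- rep(lam_max, length(idx))
  x <- if (is.null(lam0)) {
    pmin(pmax(rep(1.1, length(idx)), lo + 1e-9), hi - 1e-9)
  } else {
    pmin(pmax(rep_len(lam0, n)[idx], lo + 1e-9), hi - 1e-9)
  }
  eps <- .Machine$double.eps
  for (it in 1:200) {
    ev <- .ring_eval(quad, stack, x, deriv = TRUE)
    f <- ev$p - p_kpa[idx]
    lo[f < 0] <- x[f < 0]
    hi[f >= 0] <- x[f >= 0]
    conv <- abs(f) <= 1e-10
    if (all(conv)) break
    x_new <- x - f / ev$dp
    out <- !is.finite(x_new) | x_new < lo | x_new > hi
    x_new[out] <- (lo[out] + hi[out]) / 2
    # a step below floating-point resolution cannot improve further
    stalled <- abs(x_new - x) <= 4 * eps * pmax(x, 1)
    x <- x_new
    if (all(conv | stalled)) break
  }
  lam[idx] <- x
  lam
}

#' Solve one ring for its equilibrium luminal stretch
#'
#' Inverts [ring_pressure()]: finds the luminal stretch at which the ring
#' carries the requested pressure, by safeguarded Newton iteration bracketed
#' in stretch `[1, 5]`, to a pressure residual of 1e-8 kPa or better.
#'
#' @param ring A [ring_spec()] radii vector.
#' @param stack A [material_stack()].
#' @param pressure_kpa Target pressure in kPa (>= 0).
#' @param n_gauss Quadrature order per layer.
#' @return Luminal stretch (exactly 1 at zero pressure).
#' @export
solve_ring <- function(ring, stack, pressure_kpa, n_gauss = 16) {
  stopifnot(length(ring) == 3, inherits(stack, "material_stack"))
  if (pressure_kpa < 0) stop("pressure must be non-negative")
  .solve_rings_vec(ring[[1]], ring[[2]], ring[[3]], stack, pressure_kpa,
                   n_gauss = n_gauss)
}

#' Attenuate a stretch profile for junction end fixity
#'
#' The sleeve is clamped at the gastroesophageal and gastroduodenal
#' junctions, so the circumferential stretch must return to 1 at the two
#' terminal stations. The excess stretch is damped by a squared-exponential
#' factor of the axial distance to each end, with characteristic length
#' equal to the deformed luminal radius at that end: the clamp sets the
#' size of its own boundary layer, and stations further than a few
#' characteristic lengths from both ends are left numerically unchanged.
#'
#' @param lam Per-station luminal stretch profile.
#' @param geometry The [build_sleeve()] geometry the profile belongs to.
#' @return The attenuated stretch profile (<= `lam` when `lam >= 1`).
#' @export
apply_end_fixity <- function(lam, geometry) {
  stopifnot(inherits(geometry, "sleeve_geometry"))
  z <- geometry$z_mm
  n <- length(z)
  if (length(lam) != n) {
    stop("stretch profile length must match station count")
  }
  ell1 <- max(lam[1] * geometry$r_inner_mm[1], 1e-9)
  ell2 <- max(lam[n] * geometry$r_inner_mm[n], 1e-9)
  d1 <- z - z[1]
  d2 <- z[n] - z
  f <- (1 - exp(-(d1 / ell1)^2)) * (1 - exp(-(d2 / ell2)^2))
  1 + (lam - 1) * f
}

# Trapezoid station weights for axial integration (mm).
.station_dz <- function(z) {
  n <- length(z)
  dz <- numeric(n)
  dz[1] <- (z[2] - z[1]) / 2
  dz[n] <- (z[n] - z[n - 1]) / 2
  if (n > 2) dz[2:(n - 1)] <- (z[3:n] - z[1:(n - 2)]) / 2
  dz
}

# Solve all stations of a geometry at one pressure (kPa), exploiting
# duplicate ring cross-sections; returns the raw (unattenuated) profile.
.solve_stations <- function(geometry, stack, p_kpa, lam0 = NULL,
                            n_gauss = 16) {
  key <- round(geometry$r_inner_mm, 12)
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  lam_u <- .solve_rings_vec(
    geometry$r_inner_mm[uk], geometry$r_mucosa_outer_mm[uk],
    geometry$r_outer_mm[uk], stack, p_kpa,
    lam0 = if (is.null(lam0)) NULL else lam0[uk], n_gauss = n_gauss
  )
  lam_u[map]
}

#' Inflate a sleeve geometry over a pressure schedule
#'
#' For each pressure: solves every station's ring equilibrium (with
#' quasi-static continuation from the previous pressure), applies the
#' junction end-fixity attenuation, maps the wall through the
#' incompressible plane-strain kinematics, and records the lumen volume and
#' the elongation strain `(lambda_theta - 1) * 100` at Gauss sampling points
#' through each layer's thickness.
#'
#' @param geometry A [build_sleeve()] geometry.
#' @param stack A [material_stack()].
#' @param schedule A [pressure_schedule()] or numeric pressures in mmHg.
#' @param volume_convention `"delta"` (insufflated volume relative to the
#'   unloaded lumen; the packaged pressure-volume table is read under this
#'   convention) or `"total"` (deformed lumen volume).
#' @param end_fixity Apply the junction attenuation (default TRUE).
#' @param n_through Through-thickness Gauss sampling points per layer.
#' @param n_gauss Quadrature order for the pressure integral.
#' @return An object of class `inflation_result` with elements
#'   `pressures_mmhg`, `volumes_ml`, `lambda_inner` (stations x pressures),
#'   `samples` (long data.frame of strain samples with reference-volume
#'   weights), `geometry`, `stack`, `volume_convention`.
#' @export
inflate <- function(geometry, stack, schedule = pressure_schedule(),
                    volume_convention = c("delta", "total"),
                    end_fixity = TRUE, n_through = 4, n_gauss = 16) {
  stopifnot(inherits(geometry, "sleeve_geometry"),
            inherits(stack, "material_stack"))
  volume_convention <- match.arg(volume_convention)
  if (!inherits(schedule, "pressure_schedule")) {
    schedule <- pressure_schedule(schedule)
  }
  p_mmhg <- as.numeric(schedule)
  p_kpa <- mmhg_to_kpa(p_mmhg)

  z <- geometry$z_mm
  n_st <- length(z)
  dz <- .station_dz(z)
  v_ref <- reference_lumen_volume(geometry)
  gl <- .gauss_nodes(n_through)

  lam_mat <- matrix(NA_real_, n_st, length(p_kpa))
  volumes <- numeric(length(p_kpa))
  samples <- vector("list", length(p_kpa))
  lam_prev <- NULL

  for (j in seq_along(p_kpa)) {
    lam_raw <- tryCatch(
      .solve_stations(geometry, stack, p_kpa[j], lam0 = lam_prev,
                      n_gauss = n_gauss),
      error = function(e) {
        stop(sprintf("inflation failed at %g mmHg: %s",
                     p_mmhg[j], conditionMessage(e)), call. = FALSE)
      }
    )
    lam_prev <- lam_raw
    lam <- if (end_fixity) apply_end_fixity(lam_raw, geometry) else lam_raw
    lam_mat[, j] <- lam

    r_def <- lam * geometry$r_inner_mm
    v_def <- pi * pracma::trapz(z, r_def^2) / 1000
    volumes[j] <- if (volume_convention == "delta") v_def - v_ref else v_def

    # through-thickness strain samples, weighted by reference ring volume
    Ri <- geometry$r_inner_mm
    delta <- (lam^2 - 1) * Ri^2
    layer_bounds <- list(
      mucosa = cbind(Ri, geometry$r_mucosa_outer_mm),
      muscularis = cbind(geometry$r_mucosa_outer_mm, geometry$r_outer_mm)
    )
    per_layer <- lapply(names(layer_bounds), function(nm) {
      ab <- layer_bounds[[nm]]
      half <- (ab[, 2] - ab[, 1]) / 2
      R <- outer(half, gl$x) + (ab[, 1] + ab[, 2]) / 2
      W <- outer(half, gl$w)
      lamR <- sqrt(R^2 + delta) / R
      data.frame(
        pressure_mmhg = p_mmhg[j],
        z_mm = rep(z, n_through),
        region = rep(geometry$region, n_through),
        layer = nm,
        R_mm = as.vector(R),
        lambda_theta = as.vector(lamR),
        strain_percent = (as.vector(lamR) - 1) * 100,
        weight = as.vector(W * R * dz), # ref volume / (2 pi)
        stringsAsFactors = FALSE
      )
    })
    samples[[j]] <- do.call(rbind, per_layer)
  }

  structure(
    list(
      pressures_mmhg = p_mmhg,
      volumes_ml = volumes,
      lambda_inner = lam_mat,
      samples = do.call(rbind, samples),
      geometry = geometry,
      stack = stack,
      volume_convention = volume_convention
    ),
    class = "inflation_result"
  )
}

#' @export
print.inflation_result <- function(x, ...) {
  cat(sprintf(
    "Inflation of %g Fr sleeve (%s volume convention)\n",
    x$geometry$bougie$size_fr, x$volume_convention
  ))
  print(data.frame(
    pressure_mmhg = x$pressures_mmhg,
    volume_ml = round(x$volumes_ml, 2)
  ), row.names = FALSE)
  invisible(x)
}

#' Summarise elongation strain for one grouping at one pressure
#'
#' Mean and standard deviation of the elongation strain over the grouping's
#' samples, weighted by reference sample volume. Groupings: the whole model,
#' one region (`antrum`, `corpus`, by station), or one layer (`mucosa`,
#' `muscularis`, by through-thickness position).
#'
#' @param result An [inflate()] result.
#' @param pressure_mmhg One pressure present in the result's schedule.
#' @param grouping One of `"whole"`, `"antrum"`, `"corpus"`, `"mucosa"`,
#'   `"muscularis"`.
#' @return A one-row data.frame with `grouping`, `pressure_mmhg`,
#'   `mean_percent`, `sd_percent`.
#' @export
strain_summary <- function(result, pressure_mmhg,
                           grouping = c("whole", "antrum", "corpus",
                                        "mucosa", "muscularis")) {
  stopifnot(inherits(result, "inflation_result"))
  grouping <- match.arg(grouping)
  if (!pressure_mmhg %in% result$pressures_mmhg) {
    stop("pressure not present in the inflation result")
  }
  s <- result$samples[result$samples$pressure_mmhg == pressure_mmhg, ]
  s <- switch(grouping,
    whole = s,
    antrum = s[s$region == "antrum", ],
    corpus = s[s$region == "corpus", ],
    mucosa = s[s$layer == "mucosa", ],
    muscularis = s[s$layer == "muscularis", ]
  )
  w <- s$weight / sum(s$weight)
  m <- sum(w * s$strain_percent)
  sd <- sqrt(sum(w * (s$strain_percent - m)^2))
  data.frame(
    grouping = grouping, pressure_mmhg = pressure_mmhg,
    mean_percent = m, sd_percent = sd, stringsAsFactors = FALSE
  )
}

#' Full strain-summary table of an inflation result
#'
#' @param result An [inflate()] result.
#' @param pressures Pressures to summarise (default all in the result).
#' @return Long data.frame over pressures x groupings.
#' @export
strain_summary_table <- function(result, pressures = result$pressures_mmhg) {
  groups <- c("whole", "antrum", "corpus", "mucosa", "muscularis")
  out <- lapply(pressures, function(p) {
    do.call(rbind, lapply(groups, function(g) strain_summary(result, p, g)))
  })
  do.call(rbind, out)
}

#' Pressure-volume curve of a sleeve without strain bookkeeping
#'
#' Fast path used by calibration and the synthetic-data generators: solves
#' the same per-station equilibria as [inflate()] (with quasi-static
#' continuation and end fixity) but records only the lumen volumes.
#'
#' @inheritParams inflate
#' @param pressures_mmhg Pressures in mmHg (need not be a full schedule;
#'   must be non-negative and strictly increasing).
#' @return data.frame `pressure_mmhg`, `volume_ml`.
#' @export
pv_curve <- function(geometry, stack, pressures_mmhg,
                     volume_convention = c("delta", "total"),
                     end_fixity = TRUE, n_gauss = 16) {
  stopifnot(inherits(geometry, "sleeve_geometry"),
            inherits(stack, "material_stack"))
  volume_convention <- match.arg(volume_convention)
  p_mmhg <- as.numeric(pressures_mmhg)
  if (any(p_mmhg < 0) || (length(p_mmhg) > 1 && any(diff(p_mmhg) <= 0))) {
    stop("pressures must be non-negative and strictly increasing")
  }
  v_ref <- reference_lumen_volume(geometry)
  z <- geometry$z_mm
  volumes <- numeric(length(p_mmhg))
  lam_prev <- NULL
  for (j in seq_along(p_mmhg)) {
    lam_raw <- .solve_stations(geometry, stack, mmhg_to_kpa(p_mmhg[j]),
                               lam0 = lam_prev, n_gauss = n_gauss)
    lam_prev <- lam_raw
    lam <- if (end_fixity) apply_end_fixity(lam_raw, geometry) else lam_raw
    v_def <- pi * pracma::trapz(z, (lam * geometry$r_inner_mm)^2) / 1000
    volumes[j] <- if (volume_convention == "delta") v_def - v_ref else v_def
  }
  data.frame(pressure_mmhg = p_mmhg, volume_ml = volumes)
}

# Volumes for a family of geometries at shared pressures, solving all
# distinct ring cross-sections of the whole family jointly per pressure
# (with continuation across pressures). Returns a length(geoms) x
# length(pressures) matrix of delta volumes (ml). Calibration hot path.
.family_pv <- function(geoms, stack, pressures_mmhg, end_fixity = TRUE,
                       n_gauss = 16) {
  Ri <- unlist(lapply(geoms, `[[`, "r_inner_mm"))
  Rm <- unlist(lapply(geoms, `[[`, "r_mucosa_outer_mm"))
  Ro <- unlist(lapply(geoms, `[[`, "r_outer_mm"))
  gidx <- rep(seq_along(geoms), vapply(geoms, function(g) length(g$z_mm),
                                       integer(1)))
  key <- round(Ri, 12)
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  v_ref <- vapply(geoms, reference_lumen_volume, numeric(1))

  out <- matrix(NA_real_, length(geoms), length(pressures_mmhg))
  lam_prev <- NULL
  for (j in seq_along(pressures_mmhg)) {
    lam_u <- .solve_rings_vec(Ri[uk], Rm[uk], Ro[uk], stack,
                              mmhg_to_kpa(pressures_mmhg[j]),
                              lam0 = lam_prev, n_gauss = n_gauss)
    lam_prev <- lam_u
    lam <- lam_u[map]
    for (g in seq_along(geoms)) {
      li <- lam[gidx == g]
      if (end_fixity) li <- apply_end_fixity(li, geoms[[g]])
      v_def <- pi * pracma::trapz(geoms[[g]]$z_mm,
                                  (li * geoms[[g]]$r_inner_mm)^2) / 1000
      out[g, j] <- v_def - v_ref[g]
    }
  }
  out
}
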