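# Seeded generators for everything the test-bench needs without downloads:
# in-vivo-style pressure-volume observation points with inter-subject
# geometric scatter, and calibration tables forward-simulated from known
# material parameters. Noise is multiplicative lognormal, parametrised by a
# coefficient of variation (volumes are positive and right-skewed); the
# lognormal sigma is sqrt(log(1 + cv^2)), so a noisy cell has expectation
# noiseless * exp(sigma^2 / 2) and sample CV ~= cv.

.lognormal_sigma <- function(cv) sqrt(log(1 + cv^2))

# truncated normal (lower bound only) by rejection; deterministic under the
# caller's RNG state
.rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate synthetic in-vivo-style pressure-volume observations
#'
#' Emulates a cohort of sleeved stomachs calibrated on a single bougie size
#' whose pressure-volume points scatter because of inter-patient geometric
#' differences, dominated by sleeve length. Each subject draws a length from
#' a truncated normal (lower bound 100 mm), its deterministic curve is
#' simulated, and multiplicative lognormal noise with coefficient of
#' variation `noise_cv` is applied to the sampled volumes.
#'
#' @param n Number of subjects (>= 1).
#' @param bougie_fr Bougie calibre shared by the cohort.
#' @param length_mean_mm,length_sd_mm Mean and SD of the sleeve-length
#'   distribution (mm).
#' @param noise_cv Coefficient of variation of the multiplicative volume
#'   noise (>= 0).
#' @param stack A [material_stack()].
#' @param pressures Pressures sampled per subject (mmHg).
#' @param seed Integer seed; the output is a pure function of the arguments.
#' @param flare,antrum_length_mm Geometry parameters passed to
#'   [build_sleeve()].
#' @return An object of class `observation_set`: data.frame with columns
#'   `subject`, `pressure_mmhg`, `volume_ml` and a `meta` attribute
#'   sufficient to regenerate it bit-for-bit.
#' @export
gen_pv_observations <- function(n, bougie_fr = 50, length_mean_mm = 150,
                                length_sd_mm = 10, noise_cv = 0.1,
                                stack = default_stack(),
                                pressures = c(7.5, 15, 22.5, 37.5, 75),
                                seed = 1, flare = default_flare(),
                                antrum_length_mm = 50) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1")
  if (noise_cv < 0 || length_sd_mm < 0) stop("noise and length SD must be >= 0")
  if (length_sd_mm > 0 && length_mean_mm - 3 * length_sd_mm < 100) {
    warning("length distribution truncates heavily at the 100 mm lower bound")
  }
  meta <- list(
    n = n, bougie_fr = bougie_fr, length_mean_mm = length_mean_mm,
    length_sd_mm = length_sd_mm, noise_cv = noise_cv,
    pressures = pressures, seed = seed, flare = flare,
    antrum_length_mm = antrum_length_mm,
    stack = list(
      mucosa = c(stack$mucosa$c_kpa, stack$mucosa$a_dimless),
      muscularis = c(stack$muscularis$c_kpa, stack$muscularis$a_dimless)
    )
  )
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lengths <- .rtruncnorm_lower(n, length_mean_mm, length_sd_mm, 100)
  sig <- .lognormal_sigma(noise_cv)
  curve_for <- local({
    cache <- NULL # all subjects share one curve when lengths do not vary
    function(len) {
      if (length_sd_mm == 0 && !is.null(cache)) return(cache)
      geom <- build_sleeve(
        bougie_spec(bougie_fr, length_mm = len),
        flare = flare, antrum_length_mm = antrum_length_mm
      )
      out <- pv_curve(geom, stack, pressures)
      if (length_sd_mm == 0) cache <<- out
      out
    }
  })
  rows <- lapply(seq_len(n), function(i) {
    cv <- curve_for(lengths[i])
    noise <- if (noise_cv > 0) exp(sig * stats::rnorm(nrow(cv))) else 1
    data.frame(subject = i, pressure_mmhg = cv$pressure_mmhg,
               volume_ml = cv$volume_ml * noise)
  })
  out <- do.call(rbind, rows)
  attr(out, "meta") <- meta
  class(out) <- c("observation_set", "data.frame")
  out
}

#' Forward-simulate a calibration pressure-volume table
#'
#' Simulates every (bougie size, pressure) cell from a known material stack
#' under the default sleeve geometry and applies multiplicative lognormal
#' noise; with `noise_cv = 0` the table equals the forward simulation
#' exactly. Feeds [recovery_report()] and calibration tests.
#'
#' @param true_stack The generating [material_stack()].
#' @param sizes Bougie sizes in Fr.
#' @param pressures Pressures in mmHg.
#' @param noise_cv Coefficient of variation of the noise (>= 0).
#' @param seed Integer seed.
#' @param flare,antrum_length_mm Geometry parameters passed to
#'   [build_sleeve()].
#' @return A pressure-volume table (`bougie_fr`, `pressure_mmhg`,
#'   `volume_ml`).
#' @export
gen_calibration_dataset <- function(true_stack,
                                    sizes = c(27, 30, 34, 36, 38, 40, 42,
                                              46, 48, 50, 54),
                                    pressures = c(7.5, 15, 22.5, 37.5, 75),
                                    noise_cv = 0, seed = 1,
                                    flare = default_flare(),
                                    antrum_length_mm = 50) {
  if (length(sizes) == 0) stop("`sizes` must be non-empty")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sig <- .lognormal_sigma(noise_cv)
  rows <- lapply(sizes, function(fr) {
    geom <- build_sleeve(bougie_spec(fr), flare = flare,
                         antrum_length_mm = antrum_length_mm)
    cv <- pv_curve(geom, true_stack, pressures)
    noise <- if (noise_cv > 0) exp(sig * stats::rnorm(nrow(cv))) else 1
    data.frame(bougie_fr = fr, pressure_mmhg = cv$pressure_mmhg,
               volume_ml = cv$volume_ml * noise)
  })
  out <- do.call(rbind, rows)
  validate_pv_table(out)
  out
}

#' Write / read an observation set with its metadata sidecar
#'
#' The points round-trip as CSV; the generating metadata (sizes, lengths,
#' noise, seed) as a JSON sidecar at `<path>.meta.json`.
#'
#' @param obs An [gen_pv_observations()] observation set.
#' @param path CSV output path.
#' @return `write_observations` returns `path` invisibly;
#'   `read_observations` the observation set.
#' @export
write_observations <- function(obs, path) {
  stopifnot(inherits(obs, "observation_set"))
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE)
  jsonlite::write_json(attr(obs, "meta"), paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  out <- utils::read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    attr(out, "meta") <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  }
  class(out) <- c("observation_set", "data.frame")
  out
}
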