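# Run orchestration: a validated configuration block, the simulation /
# calibration / table-statistics entry points that back the command-line
# script in inst/scripts/, and deterministic file outputs.

#' Default run configuration
#'
#' Nested key-value configuration consumed by [run_simulation()] and
#' [run_calibration()]. Keys: `geometry` (bougie_fr, length_mm,
#' mucosa_thickness_mm, muscularis_thickness_mm, flare, antrum_length_mm,
#' end_taper_length_mm), `material` (per-layer c_kpa / a_dimless),
#' `schedule` (pressures_mmhg), `calibration` (n_starts, fit_flare,
#' maxiter), `volume_convention`, `seed`. Unknown keys are rejected at
#' validation time, before any computation.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  st <- default_stack()
  list(
    geometry = list(
      bougie_fr = c(27, 30, 34, 36, 38, 40, 42, 46, 48, 50, 54),
      length_mm = 150,
      mucosa_thickness_mm = 1.0,
      muscularis_thickness_mm = 1.5,
      flare = default_flare(),
      antrum_length_mm = 50,
      end_taper_length_mm = 10
    ),
    material = list(
      mucosa = list(c_kpa = st$mucosa$c_kpa, a_dimless = st$mucosa$a_dimless),
      muscularis = list(c_kpa = st$muscularis$c_kpa,
                        a_dimless = st$muscularis$a_dimless)
    ),
    schedule = list(pressures_mmhg = c(7.5, 15, 22.5, 37.5, 75)),
    calibration = list(n_starts = 8, fit_flare = TRUE, maxiter = 40),
    volume_convention = "delta",
    seed = 1
  )
}

.validate_keys <- function(x, ref, path = "") {
  extra <- setdiff(names(x), names(ref))
  if (length(extra) > 0) {
    stop(sprintf("unknown configuration key%s: %s",
                 if (length(extra) > 1) "s" else "",
                 paste0(path, extra, collapse = ", ")))
  }
  for (k in names(x)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      if (!is.list(x[[k]])) stop("configuration block expected at ", path, k)
      .validate_keys(x[[k]], ref[[k]], paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

.merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !is.null(names(base[[k]]))) {
      base[[k]] <- .merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Read and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys, and merges it over
#' [default_config()] (file values override defaults).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- yaml::read_yaml(path)
    if (length(user) > 0) {
      .validate_keys(user, cfg)
      cfg <- .merge_config(cfg, user)
    }
  }
  cfg
}

.config_stack <- function(config) {
  material_stack(
    layer_material("mucosa", config$material$mucosa$c_kpa,
                   config$material$mucosa$a_dimless),
    layer_material("muscularis", config$material$muscularis$c_kpa,
                   config$material$muscularis$a_dimless)
  )
}

.config_geometry <- function(config, bougie_fr) {
  g <- config$geometry
  build_sleeve(
    bougie_spec(bougie_fr, length_mm = g$length_mm),
    layers = default_layers(g$mucosa_thickness_mm, g$muscularis_thickness_mm),
    flare = g$flare, antrum_length_mm = g$antrum_length_mm,
    end_taper_length_mm = g$end_taper_length_mm
  )
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the simulation campaign and write its outputs
#'
#' Inflates one sleeve per requested bougie size over the configured
#' pressure schedule and writes, under `out_dir`: one tidy per-size result
#' CSV (`result_<fr>fr.csv`: pressure_mmhg, z_mm, layer, region,
#' lambda_theta, strain_percent), a volume table `volumes.csv`, a strain
#' summary `strain_summary.csv`, and a `run_log.json` recording the seed
#' and the configuration hash. Outputs are deterministic for a given
#' configuration.
#'
#' @param config Configuration list from [read_run_config()].
#' @param sizes Bougie sizes (default: from the configuration).
#' @param pressures Pressures in mmHg (default: from the configuration).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named list of [inflate()] results.
#' @export
run_simulation <- function(config = default_config(), sizes = NULL,
                           pressures = NULL, out_dir = ".") {
  .validate_keys(config, default_config())
  if (is.null(sizes)) sizes <- config$geometry$bougie_fr
  if (is.null(pressures)) pressures <- config$schedule$pressures_mmhg
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stack <- .config_stack(config)

  results <- stats::setNames(lapply(sizes, function(fr) {
    geom <- .config_geometry(config, fr)
    res <- inflate(geom, stack, pressure_schedule(pressures),
                   volume_convention = config$volume_convention)
    tidy <- res$samples[, c("pressure_mmhg", "z_mm", "layer", "region",
                            "lambda_theta", "strain_percent")]
    utils::write.csv(tidy, file.path(out_dir, sprintf("result_%gfr.csv", fr)),
                     row.names = FALSE)
    res
  }), as.character(sizes))

  vt <- volume_table(results, pressures)
  vt$volume_ml <- round(vt$volume_ml, 2)
  utils::write.csv(vt, file.path(out_dir, "volumes.csv"), row.names = FALSE)

  st <- do.call(rbind, lapply(names(results), function(nm) {
    s <- strain_summary_table(results[[nm]])
    cbind(bougie_fr = as.numeric(nm), s)
  }))
  st$mean_percent <- round(st$mean_percent, 2)
  st$sd_percent <- round(st$sd_percent, 2)
  utils::write.csv(st, file.path(out_dir, "strain_summary.csv"),
                   row.names = FALSE)

  jsonlite::write_json(
    list(command = "simulate", seed = config$seed,
         config_hash = .config_hash(config), sizes = sizes,
         pressures = pressures,
         volume_convention = config$volume_convention),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(results)
}

#' Calibrate wall materials from a table file and write JSON output
#'
#' @param table Path to a pressure-volume CSV (columns `bougie_fr`,
#'   `pressure_mmhg`, `volume_ml`), or a data.frame; defaults to the
#'   packaged reference table.
#' @param config Configuration list (calibration block + seed are used).
#' @param out_path Output JSON path.
#' @return Invisibly, the [fit_materials()] result.
#' @export
run_calibration <- function(table = NULL, config = default_config(),
                            out_path = "calibration.json") {
  .validate_keys(config, default_config())
  if (is.null(table)) {
    table <- read_table1()
  } else if (is.character(table)) {
    if (!file.exists(table)) stop("table file not found: ", table)
    table <- utils::read.csv(table)
  }
  validate_pv_table(table)
  fit <- fit_materials(
    table,
    fit_flare = isTRUE(config$calibration$fit_flare),
    flare = config$geometry$flare,
    seed = config$seed,
    n_starts = config$calibration$n_starts,
    antrum_length_mm = config$geometry$antrum_length_mm,
    maxiter = config$calibration$maxiter
  )
  dir.create(dirname(out_path), showWarnings = FALSE, recursive = TRUE)
  write_calibration_json(fit, out_path)
  invisible(fit)
}

#' Cross-size statistics of the packaged reference tables
#'
#' Recomputes, from the packaged fixtures, the headline arithmetic quoted
#' about the tables: cross-size mean strains, the 54-vs-27 Fr volume
#' ratios at 22.5 and 75 mmHg, and the layer/region mean-strain
#' differences, each under its stated rounding convention.
#'
#' @param correct_typo Use the back-solved value for the inconsistent
#'   46 Fr antrum cell (see [read_table2()]) in cross-size means.
#' @return data.frame with columns `statistic`, `value`.
#' @export
table_stats <- function(correct_typo = TRUE) {
  t1 <- read_table1()
  t2 <- read_table2(correct_typo = correct_typo)
  data.frame(
    statistic = c(
      "mean_whole_7p5_percent",
      "mean_whole_37p5_percent",
      "mean_antrum_37p5_percent",
      "ratio_54_27_at_22p5_rounded",
      "ratio_54_27_at_75_half",
      "diff_mucosa_muscularis_7p5_points",
      "diff_mucosa_muscularis_22p5_points",
      "diff_mucosa_muscularis_37p5_points",
      "diff_antrum_corpus_22p5_points"
    ),
    value = c(
      mean_over_sizes(t2, "whole", 7.5),
      mean_over_sizes(t2, "whole", 37.5),
      mean_over_sizes(t2, "antrum", 37.5),
      size_ratio(t1, 22.5, 54, 27, rounding = "integer"),
      size_ratio(t1, 75, 54, 27, rounding = "half"),
      group_difference(t2, 7.5, "mucosa", "muscularis", rounding = "round"),
      group_difference(t2, 22.5, "mucosa", "muscularis", rounding = "round"),
      group_difference(t2, 37.5, "mucosa", "muscularis", rounding = "round"),
      group_difference(t2, 22.5, "antrum", "corpus", rounding = "truncate")
    )
  )
}
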