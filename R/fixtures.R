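# Packaged reference tables: the published basal-volume table (11 bougie
# sizes x 5 intragastric pressures) and the elongation-strain summary table
# (11 sizes x 4 pressures x 5 groupings), both shipped as plain CSV.

.fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "sleevemech")
  if (p == "") stop("packaged fixture not found: ", name)
  p
}

.fixture_md5 <- c(
  table1.csv = "1a26571c2f51a0e4374b2f8e422b37bf",
  table2.csv = "0b4322f3f27002d9da58e12b73a1af7e"
)

.check_fixture <- function(path, name) {
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(.fixture_md5[[name]]))) {
    stop(sprintf("fixture %s failed its integrity checksum (%s)", name, md5))
  }
  invisible(TRUE)
}

#' Packaged basal-volume table
#'
#' Published basal (insufflated) volumes of the sleeved stomach at five
#' intragastric pressures (7.5, 15, 22.5, 37.5, 75 mmHg) for eleven bougie
#' sizes (27--54 Fr): 55 cells.
#'
#' @param check Verify the fixture checksum before reading (default TRUE).
#' @return data.frame with columns `bougie_fr`, `pressure_mmhg`, `volume_ml`.
#' @export
read_table1 <- function(check = TRUE) {
  path <- .fixture_path("table1.csv")
  if (check) .check_fixture(path, "table1.csv")
  df <- utils::read.csv(path)
  validate_pv_table(df)
  df
}

#' Packaged elongation-strain summary table
#'
#' Published elongation strain (mean +/- SD, percent) for the whole model
#' and by region (antrum/corpus) and layer (mucosa/muscularis), for eleven
#' bougie sizes at four intragastric pressures.
#'
#' The printed 46 Fr / antrum / 22.5 mmHg mean ("4.12") is inconsistent
#' with the table's own printed cross-size Mean row (38.45): back-solving
#' that row gives 41.22. `correct_typo = TRUE` substitutes the back-solved
#' value; the default returns the table exactly as printed.
#'
#' @param correct_typo Replace the inconsistent cell by its back-solved
#'   value (default FALSE).
#' @param check Verify the fixture checksum before reading (default TRUE).
#' @return data.frame with columns `bougie_fr`, `pressure_mmhg`, `grouping`,
#'   `mean_percent`, `sd_percent`.
#' @export
read_table2 <- function(correct_typo = FALSE, check = TRUE) {
  path <- .fixture_path("table2.csv")
  if (check) .check_fixture(path, "table2.csv")
  df <- utils::read.csv(path)
  if (correct_typo) {
    i <- df$bougie_fr == 46 & df$pressure_mmhg == 22.5 &
      df$grouping == "antrum"
    df$mean_percent[i] <- 41.22
  }
  df
}

#' Validate a pressure-volume table
#'
#' @param table data.frame with columns `bougie_fr`, `pressure_mmhg`,
#'   `volume_ml`.
#' @return The table, invisibly, or an error.
#' @export
validate_pv_table <- function(table) {
  need <- c("bougie_fr", "pressure_mmhg", "volume_ml")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    stop("pressure-volume table needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(table) == 0) stop("pressure-volume table is empty")
  if (any(table$volume_ml <= 0)) stop("volumes must be positive")
  if (anyDuplicated(table[, c("bougie_fr", "pressure_mmhg")])) {
    stop("duplicate (bougie size, pressure) keys")
  }
  invisible(table)
}
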