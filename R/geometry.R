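# Parametric sleeved-stomach geometry: an axisymmetric two-layer tube whose
# luminal calibre is set by the surgical bougie, with an antral flare, smooth
# end tapers towards the fixed gastroesophageal and gastroduodenal junctions,
# and a fixed axial station spacing.

#' Convert bougie calibre from French units to diameter in mm
#'
#' The French catheter scale defines 1 Fr = 1/3 mm of diameter, so the
#' luminal diameter of a sleeve calibrated on an `x` Fr bougie is `x / 3` mm.
#'
#' @param size_fr Bougie calibre in French units. Must be positive; may be a
#'   vector.
#' @return Diameter(s) in mm.
#' @examples
#' fr_to_diameter(27) # 9 mm
#' fr_to_diameter(54) # 18 mm
#' @export
fr_to_diameter <- function(size_fr) {
  if (!is.numeric(size_fr) || length(size_fr) == 0 || any(!is.finite(size_fr))) {
    stop("`size_fr` must be finite numeric")
  }
  if (any(size_fr <= 0)) {
    stop("bougie calibre must be positive (French units)")
  }
  size_fr / 3
}

#' Bougie specification
#'
#' Records the calibre of the surgical bougie and the derived luminal
#' geometry of the sleeve: inner diameter (French scale, 1 Fr = 1/3 mm) and
#' greater-curvature length.
#'
#' @param size_fr Bougie calibre in French units, in the clinical range
#'   27--54 Fr.
#' @param length_mm Greater-curvature length of the sleeve in mm
#'   (default 150).
#' @return An object of class `bougie_spec`.
#' @export
bougie_spec <- function(size_fr, length_mm = 150) {
  if (!is.numeric(size_fr) || length(size_fr) != 1 || !is.finite(size_fr)) {
    stop("`size_fr` must be a single finite number")
  }
  if (size_fr < 27 || size_fr > 54) {
    stop("bougie calibre must lie in the clinical range [27, 54] Fr")
  }
  if (!is.numeric(length_mm) || length(length_mm) != 1 || length_mm <= 0) {
    stop("`length_mm` must be a single positive number")
  }
  structure(
    list(
      size_fr = size_fr,
      inner_diameter_mm = fr_to_diameter(size_fr),
      length_mm = length_mm
    ),
    class = "bougie_spec"
  )
}

#' @export
print.bougie_spec <- function(x, ...) {
  cat(sprintf(
    "Bougie %g Fr: inner diameter %.4g mm, sleeve length %g mm\n",
    x$size_fr, x$inner_diameter_mm, x$length_mm
  ))
  invisible(x)
}

#' Default gastric wall layer stack
#'
#' Reference thicknesses of the two modelled wall layers: the inner
#' mucosa--submucosa (1.0 mm) and the outer muscularis (1.5 mm), summing to
#' the 2.5 mm average wall thickness measured on excised sleeve specimens.
#'
#' @param mucosa_mm Mucosa thickness in mm.
#' @param muscularis_mm Muscularis thickness in mm.
#' @return A data.frame with columns `name`, `thickness_mm`, ordered
#'   lumen-outward.
#' @export
default_layers <- function(mucosa_mm = 1.0, muscularis_mm = 1.5) {
  if (mucosa_mm <= 0 || muscularis_mm <= 0) {
    stop("layer thicknesses must be positive")
  }
  data.frame(
    name = c("mucosa", "muscularis"),
    thickness_mm = c(mucosa_mm, muscularis_mm),
    stringsAsFactors = FALSE
  )
}

# Continuous reference inner-radius profile r(z) in mm. Corpus stations sit
# at the bougie radius; the antrum carries a `flare` multiplier with a cosine
# blend of width `blend_length_mm` centred on the region boundary; both ends
# taper smoothly (cosine) to `junction_radius_mm` over `end_taper_length_mm`.
.sleeve_profile <- function(z, length_mm, r_bougie, flare, antrum_length_mm,
                            end_taper_length_mm, junction_radius_mm,
                            blend_length_mm) {
  z_boundary <- length_mm - antrum_length_mm
  r <- rep(r_bougie, length(z))
  if (flare != 1) {
    t <- (z - (z_boundary - blend_length_mm / 2)) / blend_length_mm
    t <- pmin(pmax(t, 0), 1)
    r <- r_bougie * (1 + (flare - 1) * 0.5 * (1 - cos(pi * t)))
  }
  if (end_taper_length_mm > 0) {
    for (d in list(z, length_mm - z)) {
      w <- 0.5 * (1 - cos(pi * pmin(d, end_taper_length_mm) /
                            end_taper_length_mm))
      r <- junction_radius_mm + (r - junction_radius_mm) * w
    }
  }
  r
}

#' Build a parametric sleeve geometry
#'
#' Discretises the sleeved stomach as an axisymmetric two-layer tube along
#' the axis from the gastroesophageal junction (z = 0) to the pylorus
#' (z = length). Corpus stations carry the bougie radius; the distal antrum
#' carries `flare` times the bougie radius, joined by a smooth cosine blend;
#' both ends taper to a small junction radius representing the fixed
#' gastroesophageal and gastroduodenal junctions. Layer interfaces are offset
#' outward by the cumulative reference layer thicknesses.
#'
#' @param bougie A [bougie_spec()] (or a bare calibre in Fr).
#' @param layers Layer table as from [default_layers()].
#' @param flare Dimensionless antrum radius multiplier (>= 1). The default
#'   1.3 encodes the wider antral pouch left by the stapling line.
#' @param antrum_length_mm Axial extent of the antrum measured from the
#'   pylorus; must be shorter than the sleeve.
#' @param end_taper_length_mm Length of the junction tapers at each end
#'   (0 disables; at most a quarter of the sleeve length).
#' @param junction_radius_mm Luminal radius at the two junctions.
#' @param blend_length_mm Width of the cosine blend across the antrum/corpus
#'   boundary.
#' @param spacing_mm Axial station spacing (default 2 mm).
#' @return An object of class `sleeve_geometry` with per-station axial
#'   positions, inner radius, layer interface radii and region labels.
#' @export
build_sleeve <- function(bougie,
                         layers = default_layers(),
                         flare = 1.3,
                         antrum_length_mm = 50,
                         end_taper_length_mm = 10,
                         junction_radius_mm = 3,
                         blend_length_mm = 20,
                         spacing_mm = 2) {
  if (is.numeric(bougie)) bougie <- bougie_spec(bougie)
  stopifnot(inherits(bougie, "bougie_spec"))
  L <- bougie$length_mm
  if (antrum_length_mm >= L) stop("`antrum_length_mm` must be < sleeve length")
  if (flare < 1) stop("`flare` must be >= 1")
  if (end_taper_length_mm < 0 || end_taper_length_mm > L / 4) {
    stop("`end_taper_length_mm` must lie in [0, length/4]")
  }
  if (spacing_mm <= 0) stop("`spacing_mm` must be positive")

  z <- seq(0, L, by = spacing_mm)
  if (z[length(z)] < L) z <- c(z, L)
  r_bougie <- bougie$inner_diameter_mm / 2
  r_inner <- .sleeve_profile(
    z, L, r_bougie, flare, antrum_length_mm,
    end_taper_length_mm, junction_radius_mm, blend_length_mm
  )

  if (!identical(layers$name, c("mucosa", "muscularis"))) {
    stop("`layers` must list mucosa then muscularis")
  }
  r_mucosa_outer <- r_inner + layers$thickness_mm[1]
  r_outer <- r_mucosa_outer + layers$thickness_mm[2]
  if (any(diff(rbind(r_inner, r_mucosa_outer, r_outer)) <= 0) ||
      any(r_inner <= 0)) {
    stop("invalid configuration: wall interface radii must increase lumen -> exterior")
  }

  # station centres own half-open intervals; the station exactly on the
  # boundary belongs to the proximal (corpus) block
  region <- ifelse(z > L - antrum_length_mm, "antrum", "corpus")

  structure(
    list(
      z_mm = z,
      r_inner_mm = r_inner,
      r_mucosa_outer_mm = r_mucosa_outer,
      r_outer_mm = r_outer,
      region = region,
      spacing_mm = spacing_mm,
      bougie = bougie,
      layers = layers,
      flare = flare,
      antrum_length_mm = antrum_length_mm,
      end_taper_length_mm = end_taper_length_mm,
      junction_radius_mm = junction_radius_mm,
      blend_length_mm = blend_length_mm
    ),
    class = "sleeve_geometry"
  )
}

#' @export
print.sleeve_geometry <- function(x, ...) {
  cat(sprintf(
    "Sleeve geometry: %g Fr, length %g mm, %d stations (%g mm spacing)\n",
    x$bougie$size_fr, x$bougie$length_mm, length(x$z_mm), x$spacing_mm
  ))
  cat(sprintf(
    "  inner radius %.3g-%.3g mm, flare %.3g, antrum %g mm, taper %g mm\n",
    min(x$r_inner_mm), max(x$r_inner_mm), x$flare,
    x$antrum_length_mm, x$end_taper_length_mm
  ))
  cat(sprintf(
    "  reference lumen volume %.3f ml\n", reference_lumen_volume(x)
  ))
  invisible(x)
}

#' @export
as.data.frame.sleeve_geometry <- function(x, ...) {
  data.frame(
    z_mm = x$z_mm,
    r_inner_mm = x$r_inner_mm,
    r_mucosa_outer_mm = x$r_mucosa_outer_mm,
    r_outer_mm = x$r_outer_mm,
    region = x$region,
    stringsAsFactors = FALSE
  )
}

#' Reference lumen volume of a sleeve geometry
#'
#' Integrates pi r_inner(z)^2 dz along the axis with the trapezoid rule on
#' r^2 and converts mm^3 to ml.
#'
#' @param geometry A [build_sleeve()] geometry.
#' @return Volume in ml.
#' @export
reference_lumen_volume <- function(geometry) {
  stopifnot(inherits(geometry, "sleeve_geometry"))
  pi * pracma::trapz(geometry$z_mm, geometry$r_inner_mm^2) / 1000
}

#' Write / read a sleeve geometry as CSV
#'
#' The CSV carries one row per station with columns `z_mm`, `r_inner_mm`,
#' `r_mucosa_outer_mm`, `r_outer_mm`, `region`.
#'
#' @param geometry A `sleeve_geometry`.
#' @param path Output file path.
#' @return `write_geometry_csv` returns `path` invisibly;
#'   `read_geometry_csv` returns the station table as a data.frame.
#' @export
write_geometry_csv <- function(geometry, path) {
  utils::write.csv(as.data.frame(geometry), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geometry_csv
#' @export
read_geometry_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("z_mm", "r_inner_mm", "r_mucosa_outer_mm", "r_outer_mm", "region")
  if (!all(need %in% names(df))) {
    stop("geometry CSV must have columns: ", paste(need, collapse = ", "))
  }
  df
}
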