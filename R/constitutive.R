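# Hyperelastic wall model. Each layer follows a plane-strain reduced
# Fung-type exponential strain energy in the circumferential stretch,
#   W(lambda) = (c/2) * (exp(a * (lambda^2 + lambda^-2 - 2)) - 1)   [kPa],
# with c a stress-like stiffness and a the dimensionless strain-stiffening
# exponent. Incompressibility plus plane strain (unit axial stretch, the
# junctions being fixed) collapse the wall kinematics to the map
# r(R)^2 = r_i^2 + R^2 - R_i^2, and the luminal pressure of a thick-walled
# ring follows from the classical identity P = int (sigma_th - sigma_r)/r dr.

MMHG_PER_KPA <- 1 / 0.1333224

#' Convert between mmHg and kPa
#'
#' Intragastric pressures are quoted in mmHg at the interface while all
#' internal mechanics run in kPa (1 mmHg = 0.1333224 kPa).
#'
#' @param p Pressure value(s).
#' @return Converted pressure value(s).
#' @export
mmhg_to_kpa <- function(p) p * 0.1333224

#' @rdname mmhg_to_kpa
#' @export
kpa_to_mmhg <- function(p) p / 0.1333224

#' Layer material
#'
#' Constitutive parameters of one gastric wall layer.
#'
#' @param layer_name `"mucosa"` or `"muscularis"`.
#' @param c_kpa Stress-like stiffness parameter in kPa (> 0).
#' @param a_dimless Exponential stiffening exponent (> 0).
#' @return An object of class `layer_material`.
#' @export
layer_material <- function(layer_name, c_kpa, a_dimless) {
  if (!layer_name %in% c("mucosa", "muscularis")) {
    stop("`layer_name` must be 'mucosa' or 'muscularis'")
  }
  if (!is.numeric(c_kpa) || length(c_kpa) != 1 || c_kpa <= 0) {
    stop("`c_kpa` must be a single positive number")
  }
  if (!is.numeric(a_dimless) || length(a_dimless) != 1 || a_dimless <= 0) {
    stop("`a_dimless` must be a single positive number")
  }
  structure(
    list(layer_name = layer_name, c_kpa = c_kpa, a_dimless = a_dimless),
    class = "layer_material"
  )
}

#' Material stack of the two-layer wall
#'
#' @param mucosa,muscularis [layer_material()] objects with matching names.
#' @return An object of class `material_stack`.
#' @export
material_stack <- function(mucosa, muscularis) {
  stopifnot(inherits(mucosa, "layer_material"),
            inherits(muscularis, "layer_material"))
  if (mucosa$layer_name != "mucosa" || muscularis$layer_name != "muscularis") {
    stop("layer names must match their slots")
  }
  structure(list(mucosa = mucosa, muscularis = muscularis),
            class = "material_stack")
}

#' @export
print.material_stack <- function(x, ...) {
  cat("Gastric wall material stack (Fung-type, plane strain):\n")
  for (nm in c("mucosa", "muscularis")) {
    cat(sprintf("  %-10s c = %.4g kPa, a = %.4g\n",
                nm, x[[nm]]$c_kpa, x[[nm]]$a_dimless))
  }
  invisible(x)
}

#' Default calibrated wall material
#'
#' Layer parameters obtained by calibrating the two-layer ring model (with
#' the antral flare as a shared geometric parameter) against the packaged
#' pressure-volume table with [fit_materials()] under the packaged defaults
#' (log-volume least squares, seed 1). They serve as the package's reference
#' material for simulation examples and trend studies.
#'
#' @return A [material_stack()].
#' @export
default_stack <- function() {
  material_stack(
    layer_material("mucosa", c_kpa = 4.29820385645024,
                   a_dimless = 1.25271116358391),
    layer_material("muscularis", c_kpa = 18.0487727131939,
                   a_dimless = 1.24327931228463)
  )
}

#' Default antral flare paired with [default_stack()]
#'
#' @return Dimensionless flare multiplier fitted jointly with the material.
#' @export
default_flare <- function() 1.8

#' Reduced Fung-type strain energy density
#'
#' `W(lambda) = (c/2) (exp(a (lambda^2 + lambda^-2 - 2)) - 1)` in kPa.
#' Vanishes at the reference state, is symmetric under `lambda <-> 1/lambda`,
#' and is strictly increasing for `lambda > 1`.
#'
#' @param material A [layer_material()].
#' @param lam Circumferential stretch(es), > 0.
#' @return Energy density in kPa.
#' @export
reduced_energy <- function(material, lam) {
  stopifnot(inherits(material, "layer_material"))
  if (any(!is.finite(lam)) || any(lam <= 0)) {
    stop("stretch must be positive and finite")
  }
  q <- lam^2 + lam^-2 - 2
  (material$c_kpa / 2) * (exp(material$a_dimless * q) - 1)
}

#' Circumferential-radial stress difference
#'
#' For an incompressible plane-strain ring the pressure integral needs only
#' `sigma_theta - sigma_r = lambda dW/dlambda`, evaluated here analytically:
#' `c a exp(a (lambda^2 + lambda^-2 - 2)) (lambda^2 - lambda^-2)` in kPa.
#'
#' @inheritParams reduced_energy
#' @return Stress difference in kPa (zero at `lambda = 1`).
#' @export
stress_difference <- function(material, lam) {
  stopifnot(inherits(material, "layer_material"))
  if (any(!is.finite(lam)) || any(lam <= 0)) {
    stop("stretch must be positive and finite")
  }
  q <- lam^2 + lam^-2 - 2
  material$c_kpa * material$a_dimless * exp(material$a_dimless * q) *
    (lam^2 - lam^-2)
}

# Gauss-Legendre nodes/weights on [-1, 1], cached per order.
.gl_cache <- new.env(parent = emptyenv())
.gauss_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    gl <- pracma::gaussLegendre(n, -1, 1)
    .gl_cache[[key]] <- list(x = gl$x, w = gl$w)
  }
  .gl_cache[[key]]
}

#' Ring cross-section specification
#'
#' Reference radii of the layered ring at one axial station: lumen surface,
#' mucosa/muscularis interface, outer surface.
#'
#' @param r_inner_mm Luminal reference radius in mm.
#' @param layers Layer table as from [default_layers()].
#' @return Named numeric vector `c(inner, interface, outer)` in mm.
#' @export
ring_spec <- function(r_inner_mm, layers = default_layers()) {
  if (r_inner_mm <= 0) stop("inner radius must be positive")
  r <- c(
    inner = r_inner_mm,
    interface = r_inner_mm + layers$thickness_mm[1],
    outer = r_inner_mm + sum(layers$thickness_mm)
  )
  if (any(diff(r) <= 0)) stop("ring radii must increase lumen -> exterior")
  r
}

# Precomputed through-wall quadrature geometry for a batch of rings: node
# radii and weights are reused across every pressure evaluation of a solve.
.ring_quad <- function(Ri, Rm, Ro, n_gauss = 16) {
  gl <- .gauss_nodes(n_gauss)
  rad <- list(c(1, 2), c(2, 3))
  radii <- cbind(Ri, Rm, Ro)
  blocks <- lapply(1:2, function(k) {
    a <- radii[, rad[[k]][1]]
    b <- radii[, rad[[k]][2]]
    half <- (b - a) / 2
    R <- outer(half, gl$x) + (a + b) / 2
    list(R = R, R2 = R^2, WR = outer(half, gl$w) * R)
  })
  list(blocks = blocks, Ri2 = Ri^2, n = length(Ri))
}

# Pressure (and optionally dP/dlam_inner) of the ring batch at luminal
# stretch lam, from a .ring_quad precomputation. The incompressible
# plane-strain map gives r^2 = R^2 + (lam^2 - 1) Ri^2 at every node, so
# with g(x) = x dW/dx the pressure is P = sum_nodes w g(lam(R)) R / r^2 and
# the derivative follows by differentiating through the map.
.ring_eval <- function(quad, stack, lam, deriv = FALSE) {
  delta <- (lam^2 - 1) * quad$Ri2
  p <- numeric(quad$n)
  dp <- if (deriv) numeric(quad$n) else NULL
  mats <- list(stack$mucosa, stack$muscularis)
  for (k in 1:2) {
    b <- quad$blocks[[k]]
    r2 <- b$R2 + delta # recycles delta down columns
    lamR <- sqrt(r2) / b$R
    l2 <- lamR^2
    il2 <- 1 / l2
    m <- mats[[k]]
    E <- exp(m$a_dimless * (l2 + il2 - 2))
    g <- m$c_kpa * m$a_dimless * E * (l2 - il2)
    p <- p + rowSums(g * b$WR / r2)
    if (deriv) {
      # dg/dlam = c a E [2a(l - l^-3)(l^2 - l^-2) + 2(l + l^-3)]
      gp <- m$c_kpa * m$a_dimless * E *
        (2 * m$a_dimless * (lamR - 1 / lamR^3) * (l2 - il2) +
           2 * (lamR + 1 / lamR^3))
      # d/d(delta) [w g R / r2] = w g' / (2 r2^{3/2}) - w g R / r2^2
      dp <- dp + rowSums((gp / (2 * b$R * sqrt(r2)) - g / r2) * b$WR / r2)
    }
  }
  if (deriv) list(p = p, dp = dp * 2 * lam * quad$Ri2) else list(p = p)
}

# Vectorised pressure of incompressible plane-strain rings.
# Ri, Rm, Ro, lam: equal-length vectors (one ring per entry). Returns kPa.
.ring_pressure_vec <- function(Ri, Rm, Ro, stack, lam, n_gauss = 16) {
  .ring_eval(.ring_quad(Ri, Rm, Ro, n_gauss), stack, lam)$p
}

#' Inflation pressure of an incompressible two-layer ring
#'
#' Evaluates the thick-walled generalisation of Laplace's law,
#' `P = int (sigma_theta - sigma_r) / r dr` across both layers, with the
#' incompressible plane-strain map `r(R)^2 = r_i^2 + R^2 - R_i^2` and
#' fixed-order Gauss-Legendre quadrature per layer. `P(1) = 0` and `P` is
#' strictly increasing in the luminal stretch, which makes the inverse
#' problem solved by [solve_ring()] well posed.
#'
#' @param ring A [ring_spec()] radii vector.
#' @param stack A [material_stack()].
#' @param lam_inner Circumferential stretch at the lumen surface (>= 1;
#'   deflation is not supported).
#' @param n_gauss Gauss-Legendre order per layer (default 16).
#' @return Pressure in kPa.
#' @export
ring_pressure <- function(ring, stack, lam_inner, n_gauss = 16) {
  stopifnot(inherits(stack, "material_stack"), length(ring) == 3)
  if (any(lam_inner < 1)) {
    stop("deflation regime (lam_inner < 1) is not supported")
  }
  n <- length(lam_inner)
  unname(.ring_pressure_vec(
    rep(ring[[1]], n), rep(ring[[2]], n), rep(ring[[3]], n),
    stack, lam_inner, n_gauss
  ))
}
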