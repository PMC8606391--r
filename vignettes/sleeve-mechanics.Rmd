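---
title: "Reduced-order mechanics of the sleeved stomach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order mechanics of the sleeved stomach}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sleevemech)
```

## The problem

Laparoscopic sleeve gastrectomy (LSG) resects most of the stomach along a
calibration tube (the bougie), leaving a narrow gastric sleeve whose
calibre is set by the bougie size, quoted in French units (1 Fr = 1/3 mm of
diameter, clinical range 27–54 Fr). Two mechanical quantities matter for
the operation's design: the **basal volume** the sleeve holds at a given
intragastric pressure, and the **elongation strain** of the gastric wall,
a proxy for the stimulation of the stretch mechanoreceptors implicated in
satiety. `sleevemech` computes both for a parametric family of sleeve
geometries, calibrates its wall material to a published pressure–volume
table, and reproduces the summary statistics quoted about those tables.

## Geometry

The sleeve is reduced to an axisymmetric two-layer tube along the axis
from the gastroesophageal junction (z = 0) to the pylorus (z = length,
150 mm by default — the greater-curvature length held fixed across bougie
sizes). The reduction is deliberate: the full organ is close to a hollow
cylinder once the fundus is removed, and an axisymmetric profile keeps
every operation closed-form and testable.

The luminal radius profile r(z) has four features, all parametric:

* **Corpus**: radius = bougie radius (size_fr / 6 mm).
* **Antrum** (distal `antrum_length_mm`, default 50 mm): radius = `flare` ×
  bougie radius. The antrum is wider than the stapled corpus in practice;
  since no antral dimensions are published, `flare` is exposed as a
  calibration parameter (bounds 1.0–1.8) rather than fixed a priori. The
  calibrated default is `default_flare()` = 1.8.
* A **cosine blend** of width 20 mm joins the two regions smoothly.
* **End tapers** (10 mm default) bring the radius down to a 3 mm junction
  radius at both ends, standing in for the anatomical constrictions at the
  fixed gastroesophageal and gastroduodenal junctions.

The wall carries two layers offset outward from the lumen: mucosa–submucosa
(1.0 mm) and muscularis (1.5 mm), totalling the 2.5 mm mean wall thickness
measured on excised sleeve specimens. Axial stations are spaced 2 mm apart
(matching the element size a volumetric discretisation of this organ would
use); halving the spacing changes computed volumes by well under 0.5%, which
the test suite asserts.

```{r geometry}
geom <- build_sleeve(bougie_spec(40), flare = default_flare())
reference_lumen_volume(geom)
```

## Wall mechanics

Each layer follows a reduced Fung-type exponential strain energy in the
circumferential stretch λ:

$$W(\lambda) = \frac{c}{2}\left(e^{a(\lambda^2 + \lambda^{-2} - 2)} - 1\right)
\quad [\mathrm{kPa}],$$

with *c* a stress-like stiffness and *a* the dimensionless
strain-stiffening exponent. The kinematics assume incompressibility and
plane strain (unit axial stretch) — the latter justified by the fixed
junctions at both ends — which collapse the wall motion to the map
$r(R)^2 = r_i^2 + R^2 - R_i^2$ and make wall cross-section area exactly
conserved. The luminal pressure of a station's two-layer ring is the
thick-walled generalisation of Laplace's law,

$$P = \int_{r_i}^{r_o} \frac{\sigma_\theta - \sigma_r}{r}\, dr,
\qquad \sigma_\theta - \sigma_r = \lambda \frac{dW}{d\lambda},$$

evaluated per layer by fixed-order Gauss–Legendre quadrature (order 16,
fixed for determinism; doubling the order moves the value by less than
1e-12 relative, asserted in the tests). In the thin-wall limit
(t/r = 0.001) the integral agrees with the membrane Laplace formula within
0.5%. P(λ) is strictly increasing, so inverting it per station
(`solve_ring()`) is well posed; the solver is a safeguarded Newton
iteration with an analytic Jacobian, bracketed in λ ∈ [1, 5], converging
to a pressure residual of 1e-10 kPa (the documented contract is 1e-8).
Pressures are mmHg at every interface and kPa internally
(1 mmHg = 0.1333224 kPa).

The anisotropic, visco-elastic behaviour of real gastric tissue is out of
scope: all reported quantities are quasi-static equilibrium states, and the
in-plane isotropic Fung law is the simplest form whose parameters can be
re-identified from the packaged pressure–volume table alone.

## Inflation, end fixity, volumes, strains

`inflate()` walks an increasing pressure schedule (default 7.5, 15, 22.5,
37.5, 75 mmHg — the upper value probes the wall far beyond physiological
intragastric pressure), warm-starting each station's solve from the
previous pressure (the model is elastic, so results are path independent;
a test asserts this). Because the junctions are clamped, the stretch
profile is attenuated near the ends by a squared-exponential factor of the
distance to each end, with characteristic length equal to the deformed
luminal radius **at that end**: the clamp sets the size of its own boundary
layer. (Using each station's own radius instead would give flared antra a
~20 mm decay length that suppresses the very regional contrast the model
exists to quantify.) Terminal stations return to λ = 1 exactly; stations a
few characteristic lengths away are numerically untouched.

Volumes are reported under the **insufflated-volume convention**
(ΔV = deformed − reference lumen volume), because the published basal
volumes at low pressure are far below the geometric lumen volume of a
150 mm tube — they are volumes of air pushed in, not total capacity. The
`"total"` convention is available and stamped into every result.

Elongation strain is the nominal circumferential strain (λ − 1) × 100, the
maximum principal nominal strain under plane-strain inflation. It is
sampled at 4 Gauss points through each layer at every station, and
summaries (whole model, antrum/corpus by station, mucosa/muscularis by
through-wall position) are means and SDs weighted by reference sample
volume, so the SD reflects axial (taper, blend, end fixity) and
through-wall variation. Whether the original study weighted its element
statistics by volume is not stated; weighting is this package's documented
choice. Two orderings are structural: stretch decreases monotonically
through the wall, so the inner mucosa always leads the muscularis; and a
flared antrum carries a larger radius, hence more stretch than the corpus,
consistent with the wall-tension ∝ pressure × radius rationale.

One known shape feature: the pressure–volume curve has a mildly *concave*
toe below roughly 15 mmHg, because dV/dλ itself grows with stretch before
the exponential stiffening dominates; from 15 mmHg upward the curve is
convex-increasing (the "exponential trend"). Trend tests assert convexity
above the toe.

## Calibration

The published constitutive parameters live in an external reference, so the
package re-identifies its own: `fit_materials()` minimises the sum of
squared **log**-volume residuals over all 55 table cells (volumes span
3.2–150.8 ml; the log scale weighs cells equitably) with bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`), one global material stack for
all bougie sizes, optionally fitting the shared antral flare. Bounds:
c ∈ [0.1, 200] kPa, a ∈ [0.05, 20], flare ∈ [1.0, 1.8]. Eight starts — the
supplied initial stack plus seven points of a seeded Latin-hypercube sample
of the bounds — with ties broken by lower objective, then lower mucosa
stiffness; the whole fit is a pure function of (table, init, bounds, seed).
Under the defaults the fit reaches a median absolute volume error of ~5%
(maximum ~16%) while preserving the table's ordering across sizes and
pressures exactly. The per-cell published values are calibration data, not
blind predictions: the package makes no claim of reproducing them a priori,
only of how well one global two-layer Fung material can represent them.
`default_stack()` and `default_flare()` freeze the seed-1 fit as the
package's reference material.

### Identifiability

`recovery_report()` closes the loop: simulate a table from known
parameters, refit, compare. With a noiseless table the global optimum is
the truth and all four layer parameters return within 1% (machine-level in
practice). With realistic multiplicative noise, however, the per-layer
split is weakly identified: the two layers occupy nearly the same
through-wall stretch window, so pressure–volume data constrain their
*combined* stiffness tightly but individual (c, a) pairs only along a
shallow ridge — at 5% noise the best-fit parameters can land tens of
percent from the truth while fitting the data better than the truth does.
This is a property of calibrating layered walls from lumen pressure–volume
data alone, not an optimiser artefact; identifying layers individually
requires layer-resolved experiments. The acceptance suite keeps the strict
per-parameter recovery check under noise, and it fails for this documented
reason.

## Synthetic data

`gen_pv_observations()` emulates in-vivo-style measurement cohorts: one
bougie size shared by all subjects, inter-subject scatter through sleeve
length (drawn from a truncated normal, lower bound 100 mm) — the named
anatomical source of variability — plus multiplicative lognormal volume
noise parametrised by a coefficient of variation
(σ² = log(1 + cv²), so the sample CV matches the parameter and a noisy cell
has expectation exp(σ²/2) times the clean one). `gen_calibration_dataset()`
forward-simulates whole tables the same way. Both are pure functions of
their arguments including the seed. What the generators do **not** emulate:
patient-specific cross-sectional shape, tissue heterogeneity between
subjects (material jitter is deliberately absent by default), measurement
drift, or any cohort beyond the stated noise model — so passing tests show
internal consistency of the pipeline, not fidelity to any clinical
population.

## Band analytics

`band_envelope()` takes the pointwise min/max over a family of
pressure–volume curves on a shared pressure grid (for this model the edges
are always the smallest and largest bougie sizes); `band_coverage()` scores
observation points against the band with linear interpolation between grid
pressures and closed-interval membership. The published ~65% in-vivo
coverage cannot be recomputed — those points exist only in a figure — so
coverage is exercised on synthetic observations only.

## Problem sizes and numerical defaults

* Station spacing 2 mm (76 stations at 150 mm); convergence asserted
  against 1 mm.
* Gauss–Legendre order 16 per layer for the pressure integral; 4
  through-wall strain samples per layer.
* Ring solves to |ΔP| ≤ 1e-10 kPa within λ ∈ [1, 5]; a wall unable to carry
  the requested pressure at λ = 5 raises "material too soft" with the
  offending station.
* Calibration: 8 starts, Levenberg–Marquardt capped at 40 iterations per
  start (enough for the objective to plateau; the cap is reported in the
  per-start diagnostics); unit tests use 2–3 sizes and 3 pressures, the
  acceptance suite the full 11 × 5 table.
* Degenerate inputs rejected at construction: non-increasing wall radii,
  deflation (λ < 1), non-monotone pressure schedules, pressures above
  75 mmHg, unknown configuration keys.

## Known limitations

* Axisymmetric reduction: no greater/lesser-curvature asymmetry, no staple
  line, no His angle; the antrum flare is a stand-in for unpublished
  antral dimensions, not a reconstruction.
* Quasi-static elasticity only — no viscoelastic relaxation, motility or
  food-bolus interaction.
* Plane-strain kinematics suppress axial stretch redistribution; end
  fixity is a boundary-layer model, not a solved bending problem.
* Layer parameters are only jointly identifiable from pressure–volume
  data (see above).
* The fundus is not modelled (mostly resected in this operation).
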