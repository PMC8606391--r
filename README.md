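# sleevemech

Reduced-order biomechanics of the sleeved stomach after laparoscopic
sleeve gastrectomy (LSG).

LSG resects most of the stomach along a calibration bougie, leaving a
narrow tube whose calibre (27–54 Fr; 1 Fr = 1/3 mm of diameter) is a key
design choice of the operation. `sleevemech` models the retained sleeve as
an axisymmetric two-layer tube — mucosa–submucosa (1 mm) inside muscularis
(1.5 mm) — and computes, for quasi-static inflation to prescribed
intragastric pressures:

* **basal (insufflated) volumes** and pressure–volume curves per bougie
  size,
* **elongation strain** of the wall, (λ<sub>θ</sub> − 1)·100, summarised by
  region (antrum / corpus) and layer (mucosa / muscularis) as a proxy for
  mechanoreceptor stimulation,
* the **computational band** (envelope of the curve family across sizes)
  and the coverage of observation points against it.

Each wall layer follows a plane-strain reduced Fung-type law
W(λ) = (c/2)(exp(a(λ² + λ⁻² − 2)) − 1); a station's equilibrium is the
thick-walled pressure integral P = ∫ (σ<sub>θ</sub> − σ<sub>r</sub>)/r dr
under the incompressible map r(R)² = r<sub>i</sub>² + R² − R<sub>i</sub>²,
inverted by a safeguarded Newton solve. Layer parameters (and the antral
flare) are identified from the packaged 11-size × 5-pressure basal-volume
table by seeded multi-start log-volume least squares; the packaged
strain table backs the summary statistics. See the vignette
(`vignettes/sleeve-mechanics.Rmd`) for the model, its assumptions and
limitations.

## Worked example

```r
library(sleevemech)

geom <- build_sleeve(bougie_spec(40), flare = default_flare())
print(geom)
#> Sleeve geometry: 40 Fr, length 150 mm, 76 stations (2 mm spacing)
#>   inner radius 3-12 mm, flare 1.8, antrum 50 mm, taper 10 mm
#>   reference lumen volume 33.310 ml

res <- inflate(geom, default_stack())
print(res)
#> Inflation of 40 Fr sleeve (delta volume convention)
#>  pressure_mmhg volume_ml
#>            7.5      7.84
#>           15.0     17.92
#>           22.5     27.87
#>           37.5     43.85
#>           75.0     67.86

strain_summary_table(res, 37.5)
#>     grouping pressure_mmhg mean_percent sd_percent
#> 1      whole          37.5     39.42354  10.220192
#> 2     antrum          37.5     46.14757   9.443201
#> 3     corpus          37.5     34.36547   7.506704
#> 4     mucosa          37.5     45.26378   9.067852
#> 5 muscularis          37.5     36.02808   9.274429
```

The volumes are millilitres of insufflated air relative to the unloaded
sleeve (the published table's convention); the strain summary shows the
two structural orderings the mechanics enforces — the inner mucosa is
stretched more than the muscularis, and the flared antrum more than the
corpus — with volume-weighted means and SDs.

Calibration and the packaged tables:

```r
fit <- fit_materials(read_table1(), fit_flare = TRUE, seed = 1)  # ~1 min
print(fit)          # fitted c/a per layer, flare, median |rel. error| ~5%
table_stats()       # cross-size means, 6x / 5.5x volume ratios, layer gaps
```

A thin command-line wrapper with subcommands
`simulate | calibrate | table-stats | band | synth | recover` is installed
at `inst/scripts/sleevemech-cli.R`:

```sh
Rscript inst/scripts/sleevemech-cli.R simulate --bougie-fr 27,54 \
        --pressures 7.5,75 --out out/
```

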