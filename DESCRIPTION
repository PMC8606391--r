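Package: sleevemech
Title: Biomechanics of the Sleeved Stomach After Sleeve Gastrectomy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reduced-order biomechanical models of the post-surgical
    sleeved stomach. Builds parametric two-layer (mucosa/muscularis)
    axisymmetric sleeve geometries sized by bougie calibre, inflates them
    quasi-statically with a Fung-type hyperelastic wall model to prescribed
    intragastric pressures, and extracts basal volumes, pressure-volume
    curves and elongation-strain statistics by region and layer. Includes
    calibration of the wall material to published pressure-volume tables,
    parameter-recovery audits on synthetic data, computational-band
    analytics against observation points, and seeded synthetic-data
    generators for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    lhs,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
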