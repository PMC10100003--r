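Package: vodcarbon
Title: Above-Ground Carbon Accounting from L-Band Vegetation Optical Depth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for tropical-forest above-ground carbon (AGC)
    accounting that combines a top-down satellite estimate with a bottom-up
    bookkeeping model. Daily L-band vegetation optical depth (L-VOD) series
    are quality-filtered (RFI, orbit reconciliation, outliers, inundation),
    decomposed into seasonal and trend components, aggregated to annual
    wet-season indices and calibrated to AGC with a saturating four-parameter
    curve. Annual fine-resolution land-cover maps are turned into
    deforestation, secondary-forest age, forest-edge and non-edge degradation
    layers; a bookkeeping model converts these into per-process carbon fluxes
    using reference densities, a regrowth curve and an edge-loss curve.
    Old-growth forest change is attributed as the residual between the
    satellite change and the modelled fluxes in old-growth-dominated cells.
    Includes a synthetic-scene generator with known per-process ground truth,
    Theil-Sen/Mann-Kendall trend statistics and uncertainty propagation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
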