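Package: cropshock
Title: Crop Yield Reductions Under Global Catastrophic Infrastructure Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for estimating staple-crop yield reductions when
    the industrial inputs of modern agriculture (synthetic fertilizer,
    pesticides, fuel-driven machinery, powered irrigation) are abruptly lost,
    for example after a worldwide electrical-grid failure. Gridded 5-arcmin
    crop, input and agro-climatic layers are harmonized into a per-cell table,
    cleaned with an auditable ledger (area filter, missing-data handling,
    percentile trimming, multicollinearity screening via generalized variance
    inflation factors), and modelled with per-crop gamma generalized linear
    models with a log link. Counterfactual input scenarios for the first year
    after the catastrophe (rationed stocks) and for subsequent years (stocks
    depleted) are built from global surplus, fuel-stock and draft-cattle
    accounting, and yield changes are aggregated as production-weighted means
    by crop, phase and region. A synthetic-landscape generator with known
    ground truth makes every stage testable without the global source
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    car,
    tiff,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
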