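Package: maxentsdm
Title: Presence-Only Maximum-Entropy Species Distribution Modelling and
    Range Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Presence-background (maximum-entropy) species distribution
    modelling with tunable feature classes (linear, quadratic, product,
    hinge, threshold) and L1 regularization, model selection over a
    regularization-multiplier by feature-class grid using AICc, AUC,
    omission rates and the continuous Boyce index, projection of fitted
    models across climate periods with climate-model ensembling, and
    downstream range analytics: suitability classification, spherical
    area accounting, binary change maps, range centroid shifts,
    multi-species overlap stacking and glacial refugium inference.
    Includes occurrence thinning, raster stack preparation (ESRI ASCII
    grids), environmental variable screening, spatial block and
    jackknife partitions, and a synthetic-data generator so the whole
    pipeline can be exercised and validated at desk scale.
License: MIT
Encoding: UTF-8
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
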