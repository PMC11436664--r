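Package: reefcomplexity
Title: Structural Complexity Metrics and Complexity Targets for Artificial Reef 3D Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pre-immersion assessment of artificial reef designs from their
    triangulated 3D CAD surface models (STL). Computes three geometric
    complexity metrics (convexity, packing, box-counting fractal dimension)
    and three informational complexity metrics (orientation richness,
    Shannon orientation diversity, Pielou orientation evenness) from
    area-weighted surface point clouds and normal vectors, combines them
    into a Complexity Index, and runs the downstream statistical pipeline:
    grouped multiple factor analysis with a supplementary variable,
    Karlis-Saporta-Spinaki dimension retention, hierarchical clustering on
    principal components with v-test cluster description, and selection of
    Complexity Target Points (per-metric design targets derived from the
    most complex models). Includes parametric synthetic mesh generators
    (cube, icosphere, open box, Menger sponge, perforated shell, rough
    sphere) with analytically known reference values for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
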