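Package: stackhull
Title: Semi-3D Morphometrics of Light Objects on Dark Slides from Focus
    Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: High-throughput extraction of semi-3D "half-hull" meshes and
    bounded volume/surface-area estimates from reflected-light z-stacks of
    light-coloured objects (such as planktonic foraminifera) mounted on black
    slides. Implements shape-from-focus height mapping with a local-variance
    operator, slide segmentation with a physical size filter, 2D outline
    morphometrics with aperture masking, sliding-neighbourhood quartile
    denoising, z-level pruning, heightfield triangulation with OBJ/OFF/CSV
    export, exact top-hull volumetry with three base-shape completions
    (irregular cone, irregular cylinder, spheroidal dome) and their
    uncertainty bound, assemblage size-distribution summaries, and the
    downstream comparative machinery: multi-linkage hierarchical clustering
    with majority-rule consensus, Jaccard trait distances, and the
    topological path-difference metric with random multifurcation
    resolution. A synthetic z-stack generator with analytic ground truth
    makes the whole pipeline testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    Rcpp,
    tiff,
    yaml,
    ape,
    phangorn,
    vegan,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
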