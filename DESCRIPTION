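Package: pairtrack
Title: Multi-Animal Tracking by Contrastive Identity Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks multiple visually similar animals in video by learning an
    image-embedding in which single-animal images cluster by identity. Image
    pairs with known same/different identity are mined without labels from the
    fragment structure of the video (fragments are runs of single-animal
    detections between crossings; coexisting fragments must hold different
    animals). A double-margin contrastive loss trains the embedding, k-means
    with one cluster per animal assigns identities, and the mean Silhouette
    score gates training and reports clustering quality. Includes trajectory
    post-processing (fragment-level identity enforcement, impossible-jump
    correction, crossing interpolation), IDF1 evaluation, sector-occlusion
    stress tests, and a ground-truthed synthetic video generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
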