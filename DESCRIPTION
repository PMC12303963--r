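Package: chromascape
Title: Color Structure Metrics and Psychometric Evaluation of Landscape Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the color structure of landscape photographs and links
    it to perceived restorative quality. Images are segmented into six named
    color categories by inclusive RGB range rules; each color layer is
    characterized by its box-counting fractal dimension, a Shannon-Wiener
    diversity index of composition and spatial evenness, and a Moran's I
    concentration index on a block-presence lattice. The psychometric arm
    summarizes healing ratings with a consensus-based sample filter, performs
    principal-axis factor analysis with varimax rotation on semantic
    differential ratings, clusters scenes by Ward's method on factor scores,
    and correlates color metrics with perceptual factors. A synthetic-data
    module generates fractal masks, composite landscape images, and rating
    matrices with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    png,
    tiff,
    jpeg,
    cluster,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
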