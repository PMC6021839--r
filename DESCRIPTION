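Package: touchsplit
Title: Separation of Two Touching Objects in Binary Depth-Camera Masks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Separates a single connected blob formed by two touching animals
    (e.g., weaning pigs viewed top-down by a depth camera) into two labelled
    instances. Candidate detector bounding boxes are scored with explicit size,
    boundary and coverage conditions plus a confidence value; when a box-based
    cut passes the segmentation quality gates it is used, otherwise a shape
    analysis built on holes (natural, erosion-generated, or medial-axis
    generated), hole guidelines and convex-hull concave points draws the
    boundary line. Includes a synthetic touching-ellipse fixture generator
    with per-pixel ground truth, a pixel-identity accuracy metric, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
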