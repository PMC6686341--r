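Package: lekfire
Title: Fire Refugia and Postfire Lek Attendance Trends in Sagebrush
    Ecosystems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the role of unburned islands (fire refugia)
    in the postfire population dynamics of lekking birds such as the greater
    sage-grouse. Classifies leks by fire context (unburned island, fire
    perimeter, small and large buffer), fits per-lek before/after interaction
    Poisson trend models to yearly peak male counts, compares pre- and
    postfire trend distributions across fire categories, simulates postfire
    habitat composition (sagebrush height, cheatgrass cover, elevation) at
    multiple spatial scales around leks, and explains postfire trends with
    AICc-based multimodel inference and coefficient averaging. Includes a
    synthetic fire-mosaic landscape and lek-count generator so the whole
    pipeline can be exercised end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    mgcv,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
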