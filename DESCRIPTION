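Package: facoda
Title: Compositional Data Analysis of Dietary Fatty Acids and Cardiometabolic Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing the composition of dietary fatty acids
    (saturated, monounsaturated, omega-6 and omega-3 polyunsaturated, as
    shares of total fatty-acid energy) in relation to cardiometabolic risk
    markers. Provides Aitchison-geometry primitives (closure, centered and
    isometric log-ratio transforms with pivot coordinates, variation matrix,
    reallocation), compositional linear regression with sequential rotation
    of the first pivot part, traditional isocaloric substitution models,
    reallocation change matrices, and a seedable logistic-normal synthetic
    cohort generator calibrated to published summary statistics so the whole
    pipeline is testable without access to subject-level data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
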