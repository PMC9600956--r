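Package: owhtoplan
Title: Hinge Position and Osteotomy Height Effects in Medial Opening-Wedge
    High Tibial Osteotomy Planning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coronal-plane simulation of medial opening-wedge high tibial
    osteotomy (mOWHTO) planning by the weight-bearing-line (Miniaci) method.
    Models a lower limb as a 2D landmark set, solves the valgising correction
    angle that shifts the weight-bearing line to a target fraction of the
    tibial plateau (default 55%) by rigid rotation of the distal fragment
    about the lateral hinge, and measures the resulting medial wedge width as
    the chord 2*L*sin(alpha/2). Includes a seeded synthetic-cohort generator
    reproducing a published varus-knee case mix, a six-condition experiment
    (osteotomy heights 3/4 cm by hinge offsets 5/10/15 mm), and the study's
    statistical battery: one-way ANOVA, Tukey HSD, Pearson correlations, and
    ICC(A,k) agreement with Landis-style grading.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
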