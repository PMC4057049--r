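Package: screwgait
Title: Screw-Theoretic Knee Axes and Contact-Force Decomposition from Gait Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing knee function during the stance phase of gait
    with Ball's screw theory. Provides Pluecker-coordinate screw algebra
    (virtual coefficients, reciprocity, rigid transforms), construction of the
    cylindroid (Pluecker's conoid) spanned by two screws with its principal
    screws, estimation of instantaneous screw axes and the instantaneous axes
    of the knee (IAK) from marker trajectories, nullspace computation of the
    fifth-order reciprocal screw system of an anatomical constraint set (ACL,
    PCL, MCL, LCL and medial/lateral tibiofemoral contact normals),
    decomposition of the ground-reaction wrench into constraint-line
    intensities under the one-degree-of-freedom equilibrium condition, a small
    finite Markov decision process module implementing the reciprocity-seeking
    perception-action policy by value iteration, and seeded synthetic gait
    trials with forward-constructed ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
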