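Package: vcgscar
Title: Rate-Dependent Vectorcardiogram Analysis for Ventricular Scar Localisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates 12-lead electrocardiograms of ventricular depolarisation
    from a patch-based equivalent-dipole model containing stochastic replacement
    fibrosis, reconstructs the vectorcardiogram (VCG) with the Kors transform,
    delimits the QRS complex from the spatial velocity of the filtered VCG, and
    computes a suite of QRS-loop metrics at slow and rapid pacing. Paired
    slow/fast differences in these metrics (QRS duration and area, dipole
    magnitudes, weighted angles, and dipole-angle differences at QRS landmarks)
    feed per-metric ROC analysis and random-forest classifiers that localise
    scar to the left-ventricular free wall or the septum.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    signal,
    randomForest,
    jsonlite,
    yaml,
    MASS,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
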