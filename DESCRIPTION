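Package: stressmix
Title: Model-Based Clustering and Factorial Analysis of Combined
    Nitrogen and Water Stress Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing gene expression under crossed nitrogen
    and water stress in a factorial design: detection filtering and
    baseline transformation of summarized microarray intensities,
    fold-change-prefiltered equal-variance t-tests with
    Benjamini-Hochberg correction, two-way type-III ANOVA screening for
    nitrogen-by-water interaction effects, model-based clustering of
    five-point water-response expression trajectories with a Gaussian
    mixture whose covariance is parameterized by the modified Cholesky
    decomposition (fitted by EM, with BIC selection of the number of
    groups), and a two-component mixture test for genes whose
    trajectory shape changes between nitrogen regimes. Includes a
    synthetic-data generator emulating the 30-condition factorial
    design so the whole pipeline is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
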