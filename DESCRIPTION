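Package: ploidyfit
Title: Genome Size and Ploidy from Flow Cytometry Histograms by Nonlinear Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based analysis of DNA-content flow cytometry histograms for
    plant genome size and ploidy determination. Reads FCS 2.0/3.0/3.1 list-mode
    files, optionally gates events on a two-channel scatterplot, bins one
    fluorescence channel into a histogram, and decomposes the histogram into
    Gaussian G1/G2 nuclei peaks, single-cut or multi-cut debris, a broadened
    rectangle S phase, and a continuous (doublet) aggregate component. The
    composite model is fitted by Levenberg-Marquardt nonlinear least squares;
    results include modeled nuclei counts, peak coefficients of variation,
    the sample/standard G1 peak ratio, a residual chi-square goodness-of-fit
    statistic, and genome size in picograms calibrated against an internal
    standard of known DNA content. Includes an event-level simulator with
    known ground truth and a batch driver for directories of FCS files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    grDevices,
    graphics,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
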