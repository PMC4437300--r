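Package: amygasic
Title: Quantitative Analysis of Acid-Sensing Ion Channel Currents,
    Cell Classification, Plasticity and Fear Behavior in Amygdala Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested analysis chain for slice-electrophysiology studies of
    acid-sensing ion channel (ASIC) currents across amygdala cell types.
    Extracts formula-defined spike-train features (accommodating ratio,
    spike delay, maximal CV of interspike-interval ratios, maximal mean
    firing rate, input resistance) from current-clamp step families;
    classifies neurons by Ward's-method agglomerative clustering on
    min-max-normalized, uniformity-filtered features; fits proton-gated
    current kinetics (exponential desensitization, Hill pH-response in
    proton concentration, second-order-polynomial reversal interpolation
    with a Nernst reference, single-exponential tachyphylaxis) and
    nucleated-patch current densities from ellipsoid patch geometry;
    quantifies long-term potentiation from baseline-normalized synaptic
    response series with series-resistance quality control; scores
    conditioned-fear freezing from bout annotations; and provides exact
    small-sample Wilcoxon and Kruskal-Wallis tests with enumerated nulls.
    A seeded synthetic-data module generates every input class with known
    planted parameters so the full pipeline is testable without raw
    recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
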