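Package: caburst
Title: Calcium Event Detection and Burst-Spike Analysis for In Vivo
    Neural Pharmacology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies in vivo frontal-cortex neural activity from
    two-photon calcium imaging and single-unit recordings. Converts ROI
    fluorescence to dF/F, detects calcium transients by a noise-scaled
    threshold, and summarises amplitude, event frequency and integrated
    activity per minute; segments spike trains into bursts by inter-spike
    interval criteria, classifies fast- versus regular-spiking units, and
    classifies per-unit drug responses from baseline-normalised rate
    changes. Includes group-level statistics (t-tests, two-way ANOVA with
    Bonferroni post-tests, baseline-normalised time courses) and a
    synthetic-data generator with ground truth emulating control,
    schizophrenia-like, and pharmacological conditions, so every stage of
    the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
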