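Package: meriparray
Title: Differential m6A Methylation Analysis for Two-Color Epitranscriptomic Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for MeRIP-based two-color epitranscriptomic
    microarrays that measure N6-methyladenosine (m6A) on mRNA and lncRNA. Takes
    probe-level immunoprecipitated (IP, Cy5) and supernatant (Sup, Cy3)
    intensities through spike-in normalization, limma quantile normalization and
    Present/Marginal/Absent flag filtering to per-probe "% Modified" methylation
    levels, m6A quantities and expression levels; computes fold changes and
    unpaired t-tests between patient and control groups and classifies probes
    into hyper-/hypo-methylated x up-/down-regulated classes; provides
    hierarchical clustering, Pearson correlation and cohort-characteristic
    tests, and Fisher-exact over-representation analysis on GMT gene sets. A
    synthetic array generator with planted differential effects makes every
    stage testable without raw arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
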