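#!/usr/bin/env Rscript
# Quantify the simulated arrays: spike-in normalization of both channels,
# quantile normalization of the expression matrix, the "All Targets Value"
# P/M flag filter, then % Modified methylation levels, m6A quantities and
# expression levels.

suppressPackageStartupMessages(library(meriparray))

ds <- read_array_dataset("results/data/intensities.tsv",
                         "results/data/annotation.tsv",
                         "results/data/samples.tsv")
profile <- quantify(ds)
paths <- write_methylation_profile(profile, "results/quantify")

message(sprintf("kept %d / %d probes after the flag filter",
                sum(profile$kept_probes), length(profile$kept_probes)))
message(sprintf("methylation level range: %.3f - %.3f",
                min(profile$meth_level, na.rm = TRUE),
                max(profile$meth_level, na.rm = TRUE)))
message("wrote: ", paste(basename(paths), collapse = ", "))
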