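#!/usr/bin/env Rscript
# Simulate a two-color m6A epitranscriptomic array study: two groups of five
# CD71+ immature-RBC samples (patients T, controls N) with planted
# hypo-methylation (log2 IP effect -3) and expression effects, and write the
# raw tables the rest of the workflow reads.

suppressPackageStartupMessages(library(meriparray))

out <- "results/data"
cfg <- sim_config(n_probes = 2000, seed = 20211014)
sim <- generate_dataset(cfg)

paths <- write_array_dataset(sim$dataset, out)
write.table(sim$truth, file.path(out, "ground_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("simulated %d probes (+%d spike-ins) x %d samples",
                cfg$n_probes, cfg$n_spikeins, nrow(sim$dataset$samples)))
message(sprintf("planted: %d diff-methylated (log2 %.1f), %d diff-expressed (log2 %.1f)",
                sum(sim$truth$is_diff_meth != 0), cfg$meth_effect_log2,
                sum(sim$truth$is_diff_expr != 0), cfg$expr_effect_log2))
message("wrote: ", paste(paths, collapse = ", "))
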