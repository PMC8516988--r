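#!/usr/bin/env Rscript
# Association statistics: cohort-characteristics tests recomputed from the
# published HbH-CS group summaries, and correlation analyses of the kind used
# to link a target's methylation status to regulator expression — here run on
# the simulated arrays (methylation level of the most hypo-methylated probe
# vs per-sample expression of an anti-correlated probe, and per-sample mean
# methylation vs mean m6A quantity).

suppressPackageStartupMessages(library(meriparray))

dir.create("results/association", showWarnings = FALSE, recursive = TRUE)

cs <- hbhcs_cohort_summary()
cohort <- cohort_tests(cs$age_T, cs$age_N, cs$sex_counts)
write.table(cohort, "results/association/cohort_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("cohort: age p = %.3f, sex p = %.3f", cohort$p[1], cohort$p[2]))

ds <- read_array_dataset("results/data/intensities.tsv",
                         "results/data/annotation.tsv",
                         "results/data/samples.tsv")
profile <- quantify(ds)
tab <- differential_table(profile)

top_probe <- top_table(tab, n = 1, key = "m6a_fc_asc",
                       filter = list(meth_status = "hypo"))$probe_id
meth_top <- profile$meth_level[top_probe, ]
expr_all <- log2(profile$expression)
r_all <- apply(expr_all, 1, function(e) cor(meth_top, e))
partner <- rownames(expr_all)[which.min(r_all)]

cors <- rbind(
  data.frame(pair = sprintf("meth[%s] vs log2 expr[%s]", top_probe, partner),
             as.data.frame(pearson_correlation(meth_top, expr_all[partner, ]))),
  data.frame(pair = "per-sample mean meth vs mean log2 m6A quantity",
             as.data.frame(pearson_correlation(
               colMeans(profile$meth_level, na.rm = TRUE),
               colMeans(log2(profile$m6a_quantity), na.rm = TRUE))))
)
write.table(cors, "results/association/correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(cors))) {
  message(sprintf("%s: r = %.4f, p = %.4g (n = %d)",
                  cors$pair[i], cors$r[i], cors$p[i], cors$n[i]))
}
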