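#!/usr/bin/env Rscript
# Differential methylation/expression between T and N: fold changes, unpaired
# t-tests, hyper/hypo x up/down classes, published-style top tables, and
# hierarchical clustering of samples on their methylation-level profiles.

suppressPackageStartupMessages(library(meriparray))

ds <- read_array_dataset("results/data/intensities.tsv",
                         "results/data/annotation.tsv",
                         "results/data/samples.tsv")
profile <- quantify(ds)
tab <- differential_table(profile, adjust = TRUE)

dir.create("results/differential", showWarnings = FALSE, recursive = TRUE)
write_differential_table(tab, "results/differential/differential_table.tsv")

top_mrna <- top_table(tab, n = 20, key = "m6a_fc_asc",
                      filter = list(rna_type = "mRNA",
                                    regulation = c("Hypo-down", "Hypo-up")))
write_differential_table(top_mrna, "results/differential/top20_hypo_mrna.tsv")
top_nc <- top_table(tab, n = 20, key = "meth_ratio_asc",
                    filter = list(rna_type = setdiff(unique(tab$rna_type), "mRNA"),
                                  meth_status = "hypo"))
if (nrow(top_nc) > 0) {
  write_differential_table(top_nc, "results/differential/top20_hypo_noncoding.tsv")
}

cl <- hierarchical_cluster(t(profile$meth_level))
writeLines(cl$newick, "results/differential/sample_tree.nwk")

message("regulation classes:")
print(table(tab$regulation))
message("most hypo-methylated mRNA: ", top_mrna$gene_symbol[1],
        sprintf(" (m6A log2 FC %.2f)", top_mrna$fc_m6a_log2[1]))
message("sample dendrogram leaf order: ", paste(cl$order, collapse = " "))

# recovery against the planted truth
truth <- read.delim("results/data/ground_truth.tsv")
truth <- truth[match(tab$probe_id, truth$probe_id), ]
planted <- truth$is_diff_meth != 0
message(sprintf("planted hypo-methylation detected: %.1f%% (%d probes)",
                100 * mean(tab$meth_status[planted] == "hypo", na.rm = TRUE),
                sum(planted)))
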