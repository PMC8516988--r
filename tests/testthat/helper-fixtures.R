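# hand-built tiny datasets, written to disk and read back through array_io so
# every fixture also exercises the reader

write_fixture_files <- function(dir, probe_id, gene_symbol, rna_type, ip, sup,
                                flags, sample_id, group) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  intens <- data.frame(probe_id = probe_id, stringsAsFactors = FALSE)
  for (j in seq_along(sample_id)) {
    intens[[paste0(sample_id[j], "_IP")]] <- sprintf("%.17g", ip[, j])
    intens[[paste0(sample_id[j], "_Sup")]] <- sprintf("%.17g", sup[, j])
    intens[[paste0(sample_id[j], "_flag")]] <- flags[, j]
  }
  annot <- data.frame(
    probe_id = probe_id, gene_symbol = gene_symbol, rna_type = rna_type,
    locus = sprintf("chr1:%d-%d:+", seq_along(probe_id),
                    seq_along(probe_id) + 100L),
    stringsAsFactors = FALSE
  )
  samples <- data.frame(sample_id = sample_id, group = group,
                        stringsAsFactors = FALSE)
  paths <- c(intensities = file.path(dir, "intensities.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             samples = file.path(dir, "samples.tsv"))
  for (nm in names(paths)) {
    df <- switch(nm, intensities = intens, annotation = annot,
                 samples = samples)
    utils::write.table(df, paths[nm], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  paths
}

# a dataset with hand-chosen intensities: `n_spike` spike-ins appended, all
# spike intensities `spike_value` in both channels
tiny_dataset <- function(ip, sup, flags = NULL, rna_type = NULL,
                         group = NULL, n_spike = 1, spike_value = 1) {
  np <- nrow(ip); ns <- ncol(ip)
  if (is.null(flags)) flags <- matrix("P", np, ns)
  if (is.null(rna_type)) rna_type <- rep("mRNA", np)
  if (is.null(group)) group <- rep(c("T", "N"), length.out = ns)
  probe_id <- sprintf("P%03d", seq_len(np))
  sample_id <- paste0("S", seq_len(ns))
  ip2 <- rbind(ip, matrix(spike_value, n_spike, ns))
  sup2 <- rbind(sup, matrix(spike_value, n_spike, ns))
  flags2 <- rbind(flags, matrix("P", n_spike, ns))
  paths <- write_fixture_files(
    withr::local_tempdir(.local_envir = parent.frame()),
    probe_id = c(probe_id, sprintf("SPIKE%02d", seq_len(n_spike))),
    gene_symbol = c(sprintf("G%03d", seq_len(np)),
                    sprintf("ERCC%02d", seq_len(n_spike))),
    rna_type = c(rna_type, rep("spike-in", n_spike)),
    ip = ip2, sup = sup2, flags = flags2,
    sample_id = sample_id, group = group
  )
  read_array_dataset(paths["intensities"], paths["annotation"],
                     paths["samples"])
}

# a minimal MethylationProfile built directly from matrices (bypasses
# normalization; for testing fold_changes / differential_table arithmetic)
manual_profile <- function(meth, expression, group) {
  np <- nrow(meth)
  probe_id <- sprintf("P%03d", seq_len(np))
  rownames(meth) <- rownames(expression) <- probe_id
  structure(list(
    meth_level = meth,
    m6a_quantity = expression * meth,
    expression = expression,
    probes = data.frame(probe_id = probe_id,
                        gene_symbol = sprintf("G%03d", seq_len(np)),
                        rna_type = "mRNA", chrom = "chr1",
                        start = seq_len(np), end = seq_len(np) + 10L,
                        strand = "+", stringsAsFactors = FALSE),
    samples = data.frame(sample_id = colnames(meth) %||% paste0("S", seq_len(ncol(meth))),
                         group = group, stringsAsFactors = FALSE),
    kept_probes = stats::setNames(rep(TRUE, np), probe_id)
  ), class = "MethylationProfile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reference-table rows as DifferentialTable-shaped records with significant
# p-values on both axes (the published table prints the classes, not the ps)
reference_mrna_records <- function() {
  ref <- hbhcs_reference_table("mrna")
  data.frame(probe_id = ref$gene_symbol, gene_symbol = ref$gene_symbol,
             rna_type = "mRNA",
             fc_m6a_log2 = ref$fc_m6a_log2, fc_ge_log2 = ref$fc_ge_log2,
             fc_meth_ratio = 2^ref$fc_m6a_log2,
             p_meth = 0.001, p_m6a = 0.001, p_ge = 0.001,
             locus = ref$locus, stringsAsFactors = FALSE)
}
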