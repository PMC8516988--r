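#' Spike-in normalization of two-channel raw intensities
#'
#' Normalizes each channel of each sample against its spike-in controls:
#' the normalized log2 intensity of a probe is `log2(raw)` minus the mean of
#' the log2-scaled spike-in intensities of that sample and channel
#' (equivalently, division by the spike-ins' geometric mean on the linear
#' scale). Spike-in probes are removed from the returned matrices; they exist
#' only to set the scale.
#'
#' @param raw a `RawArrayDataset` whose annotation marks spike-in probes with
#'   `rna_type == "spike-in"`.
#' @param shared_spikein_mean if `TRUE`, subtract a single spike-in mean
#'   pooled over both channels instead of channel-specific means. The
#'   channel-specific default additionally cancels per-channel dye effects.
#' @return A list of class `NormalizedChannels`: `ip_norm` and `sup_norm`
#'   (log2-scale matrices, non-spike-in probes x samples), plus the matching
#'   `probes` annotation, `samples` sheet and `flags` matrix.
#' @export
spikein_normalize <- function(raw, shared_spikein_mean = FALSE) {
  stopifnot(inherits(raw, "RawArrayDataset"))
  is_spike <- raw$probes$rna_type == "spike-in"
  if (!any(is_spike)) {
    stop("spike-in normalization requires at least one spike-in probe",
         call. = FALSE)
  }
  spike_ip <- log2(raw$ip[is_spike, , drop = FALSE])
  spike_sup <- log2(raw$sup[is_spike, , drop = FALSE])
  if (any(!is.finite(spike_ip)) || any(!is.finite(spike_sup))) {
    stop("spike-in probes must have positive intensity in every sample and channel",
         call. = FALSE)
  }
  if (shared_spikein_mean) {
    mu <- colMeans(rbind(spike_ip, spike_sup))
    mu_ip <- mu_sup <- mu
  } else {
    mu_ip <- colMeans(spike_ip)
    mu_sup <- colMeans(spike_sup)
  }
  ip_norm <- sweep(log2(raw$ip[!is_spike, , drop = FALSE]), 2, mu_ip)
  sup_norm <- sweep(log2(raw$sup[!is_spike, , drop = FALSE]), 2, mu_sup)
  structure(list(ip_norm = ip_norm, sup_norm = sup_norm,
                 probes = raw$probes[!is_spike, , drop = FALSE],
                 samples = raw$samples,
                 flags = raw$flags[!is_spike, , drop = FALSE]),
            class = "NormalizedChannels")
}

#' Probe filter on Present/Marginal QC flags
#'
#' Keeps a probe when its signal is called Present (`P`) or Marginal (`M`) in
#' at least `min_present` of the loaded samples, both groups pooled — the
#' "All Targets Value" rule (a minimum of 1 in 10 samples) generalized to any
#' sample count.
#'
#' @param flags character matrix of `P`/`M`/`A` calls, probes x samples.
#' @param min_present minimum number of P-or-M samples required (default 1).
#' @return Logical vector, one element per probe (`TRUE` = keep).
#' @export
filter_by_flags <- function(flags, min_present = 1) {
  stopifnot(min_present >= 1)
  rowSums(flags == "P" | flags == "M") >= min_present
}

#' The % Modified methylation-level statistic
#'
#' The m6A methylation level of a transcript is the fraction of it captured
#' in the IP fraction: `% Modified = IP / (IP + Sup)` on linear-scale
#' normalized intensities. A (probe, sample) whose total intensity
#' `IP + Sup` falls at or below the floor `eps` is returned as `NA`
#' (missing, not zero).
#'
#' @param ip_linear,sup_linear non-negative linear-scale intensities
#'   (vectors or matrices of equal shape).
#' @param eps total-intensity floor below which the ratio is undefined.
#' @return Values in `[0, 1]` with `NA` where the total is at or below `eps`.
#' @export
percent_modified <- function(ip_linear, sup_linear, eps = 2^-20) {
  if (any(ip_linear < 0, na.rm = TRUE) || any(sup_linear < 0, na.rm = TRUE)) {
    stop("percent_modified: intensities must be non-negative", call. = FALSE)
  }
  total <- ip_linear + sup_linear
  out <- ip_linear / total
  out[!is.na(total) & total <= eps] <- NA_real_
  out
}

#' Quantile normalization (limma)
#'
#' Forces every column (sample) of a matrix onto the identical distribution:
#' each value is replaced by the mean, across samples, of the values sharing
#' its within-column rank, with ties averaged. Backed by
#' [limma::normalizeQuantiles()]. Idempotent; within-column rank order is
#' preserved.
#'
#' @param x numeric matrix (probes x samples) with no missing values.
#' @return Matrix of the same shape; a single-column input is returned
#'   unchanged with a warning.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) {
    warning("quantile_normalize: fewer than 2 columns; returning input unchanged",
            call. = FALSE)
    return(x)
  }
  if (anyNA(x)) stop("quantile_normalize: input contains missing values",
                     call. = FALSE)
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Quantify methylation level, m6A quantity and expression
#'
#' Runs the full quantification chain on a raw dataset:
#' spike-in normalization ([spikein_normalize()]), quantile normalization of
#' the linear expression (IP+Sup) matrix ([quantile_normalize()], applied
#' before flag screening), the Present/Marginal flag filter
#' ([filter_by_flags()]), and the per-probe statistics:
#' \describe{
#'   \item{meth_level}{`% Modified = IP/(IP+Sup)` on spike-in-normalized
#'     linear intensities ([percent_modified()]); a within-sample ratio,
#'     untouched by quantile normalization.}
#'   \item{expression}{quantile-normalized linear `IP + Sup`.}
#'   \item{m6a_quantity}{the modified-RNA share of normalized expression,
#'     `expression * meth_level`, so the identity
#'     `expression x meth_level = m6a_quantity` holds exactly.}
#' }
#'
#' @param raw a `RawArrayDataset`.
#' @param min_present flag-filter threshold, see [filter_by_flags()].
#' @param quantile_norm apply quantile normalization to the expression matrix
#'   (default `TRUE`).
#' @param shared_spikein_mean see [spikein_normalize()].
#' @param eps missing-value floor on linear total intensity, see
#'   [percent_modified()].
#' @return A list of class `MethylationProfile`: matrices `meth_level`,
#'   `m6a_quantity`, `expression` (kept probes x samples), the kept probes'
#'   annotation (`probes`), the `samples` sheet, and `kept_probes`, a named
#'   logical over all non-spike-in probes recording the flag-filter outcome.
#' @export
quantify <- function(raw, min_present = 1, quantile_norm = TRUE,
                     shared_spikein_mean = FALSE, eps = 2^-20) {
  nc <- spikein_normalize(raw, shared_spikein_mean = shared_spikein_mean)
  ip_lin <- 2^nc$ip_norm
  sup_lin <- 2^nc$sup_norm
  expression <- ip_lin + sup_lin
  if (quantile_norm && ncol(expression) >= 2) {
    expression <- quantile_normalize(expression)
  }
  kept <- filter_by_flags(nc$flags, min_present = min_present)
  names(kept) <- nc$probes$probe_id

  meth <- percent_modified(ip_lin, sup_lin, eps = eps)
  keep <- which(kept)
  meth <- meth[keep, , drop = FALSE]
  expression <- expression[keep, , drop = FALSE]
  structure(list(meth_level = meth,
                 m6a_quantity = expression * meth,
                 expression = expression,
                 probes = nc$probes[keep, , drop = FALSE],
                 samples = nc$samples,
                 kept_probes = kept),
            class = "MethylationProfile")
}

#' Write a methylation profile as tab-delimited matrices
#'
#' Emits `meth_level.tsv`, `m6a_quantity.tsv`, `expression.tsv` (probes in
#' rows, samples in columns, full numeric precision) and `kept_probes.tsv`
#' (the flag-filter outcome for every non-spike-in probe).
#'
#' @param profile a `MethylationProfile`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the four file paths.
#' @export
write_methylation_profile <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mat <- function(m, path) {
    df <- data.frame(probe_id = rownames(m), stringsAsFactors = FALSE)
    for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- fmt_num(m[, j])
    write_tsv(df, path)
  }
  paths <- c(meth_level = file.path(dir, "meth_level.tsv"),
             m6a_quantity = file.path(dir, "m6a_quantity.tsv"),
             expression = file.path(dir, "expression.tsv"),
             kept_probes = file.path(dir, "kept_probes.tsv"))
  write_mat(profile$meth_level, paths["meth_level"])
  write_mat(profile$m6a_quantity, paths["m6a_quantity"])
  write_mat(profile$expression, paths["expression"])
  write_tsv(data.frame(probe_id = names(profile$kept_probes),
                       kept = unname(profile$kept_probes)),
            paths["kept_probes"])
  invisible(paths)
}
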