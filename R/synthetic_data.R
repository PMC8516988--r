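#' Simulation configuration for synthetic epitranscriptomic arrays
#'
#' Builds a validated configuration for [generate_dataset()]. The defaults
#' emulate an 8 x 60K-style two-color m6A array at toy scale: two groups of
#' five samples (patients `T`, controls `N`), lognormal probe intensities in
#' the IP (Cy5) and Sup (Cy3) channels, a handful of spike-in control probes,
#' and planted differential methylation and expression effects of the
#' magnitude seen in real hypo-methylation screens (about 3 log2 units).
#'
#' The generative model works on the log2 scale. Each probe gets a baseline
#' log2 expression drawn from `N(baseline_log2_mean, baseline_log2_sd)` and a
#' baseline methylation level (fraction of transcripts carrying m6A) drawn
#' uniformly from `meth_baseline_range`. The noiseless linear IP intensity is
#' `expression * meth` and the Sup intensity `expression * (1 - meth)`, so the
#' downstream % Modified statistic IP/(IP+Sup) recovers the configured level
#' exactly in the zero-noise limit. Differential methylation adds
#' `meth_effect_log2` to the log2 IP channel of affected probes in group `T`
#' only; differential expression adds `expr_effect_log2` to both channels.
#' Gaussian log2 noise (`noise_log2_sd`) is then added independently per
#' probe, sample and channel, and optional per-sample/per-channel dye offsets
#' (`dye_effect_log2_sd`, off by default) are applied to every probe
#' including the spike-ins, which is exactly the distortion spike-in
#' normalization removes.
#'
#' @param n_probes number of non-spike-in probes.
#' @param n_spikeins number of spike-in control probes (appended after the
#'   regular probes).
#' @param n_T,n_N samples per group (patients `T`, controls `N`).
#' @param baseline_log2_mean,baseline_log2_sd mean and SD of per-probe
#'   baseline log2 expression.
#' @param noise_log2_sd SD of iid Gaussian measurement noise on log2
#'   intensities, per probe x sample x channel.
#' @param frac_diff_meth,frac_diff_expr fractions of probes carrying a
#'   planted methylation / expression effect; the number of affected probes
#'   is `round(frac * n_probes)`, selected by seeded sampling without
#'   replacement.
#' @param meth_effect_log2 signed log2 shift applied to the IP channel of
#'   affected probes in group `T` (negative = hypo-methylation in patients).
#' @param expr_effect_log2 signed log2 shift applied to both channels of
#'   affected probes in group `T`.
#' @param flag_absent_rate probability that a (probe, sample) is flagged
#'   Absent; remaining flags are Present or Marginal in a 9:1 ratio.
#'   Spike-ins are always Present.
#' @param meth_baseline_range interval for the uniform baseline methylation
#'   level; the default `[0.2, 0.8]` keeps % Modified away from boundary
#'   saturation.
#' @param spikein_log2 true log2 intensity of every spike-in in both
#'   channels (equal across channels so spike-in normalization is
#'   ratio-preserving).
#' @param dye_effect_log2_sd SD of per-sample, per-channel dye offsets
#'   (default 0: no dye effect).
#' @param seed integer seed; a fixed seed makes [generate_dataset()]
#'   bit-reproducible.
#'
#' @return A list of class `sim_config`.
#' @seealso [generate_dataset()]
#' @export
sim_config <- function(n_probes = 200, n_spikeins = 8, n_T = 5, n_N = 5,
                       baseline_log2_mean = 10, baseline_log2_sd = 1.5,
                       noise_log2_sd = 0.5,
                       frac_diff_meth = 0.1, meth_effect_log2 = -3,
                       frac_diff_expr = 0.1, expr_effect_log2 = 2,
                       flag_absent_rate = 0.05,
                       meth_baseline_range = c(0.2, 0.8),
                       spikein_log2 = baseline_log2_mean,
                       dye_effect_log2_sd = 0,
                       seed = 1L) {
  cfg <- list(
    n_probes = as.integer(n_probes), n_spikeins = as.integer(n_spikeins),
    n_T = as.integer(n_T), n_N = as.integer(n_N),
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    noise_log2_sd = noise_log2_sd,
    frac_diff_meth = frac_diff_meth, meth_effect_log2 = meth_effect_log2,
    frac_diff_expr = frac_diff_expr, expr_effect_log2 = expr_effect_log2,
    flag_absent_rate = flag_absent_rate,
    meth_baseline_range = meth_baseline_range,
    spikein_log2 = spikein_log2,
    dye_effect_log2_sd = dye_effect_log2_sd,
    seed = as.integer(seed)
  )
  num <- unlist(cfg[setdiff(names(cfg), "meth_baseline_range")])
  if (any(!is.finite(c(num, cfg$meth_baseline_range)))) {
    stop("sim_config: all configuration values must be finite", call. = FALSE)
  }
  fr <- c(cfg$frac_diff_meth, cfg$frac_diff_expr, cfg$flag_absent_rate)
  if (any(fr < 0 | fr > 1)) {
    stop("sim_config: fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(c(cfg$n_probes, cfg$n_spikeins, cfg$n_T, cfg$n_N) < 0)) {
    stop("sim_config: counts must be non-negative", call. = FALSE)
  }
  if (cfg$baseline_log2_sd < 0 || cfg$noise_log2_sd < 0 ||
      cfg$dye_effect_log2_sd < 0) {
    stop("sim_config: standard deviations must be non-negative", call. = FALSE)
  }
  rng <- cfg$meth_baseline_range
  if (length(rng) != 2 || rng[1] > rng[2] || rng[1] <= 0 || rng[2] >= 1) {
    stop("sim_config: meth_baseline_range must be within (0, 1), low <= high",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

rna_types_regular <- c("mRNA", "lncRNA", "pri-miRNA", "pre-miRNA", "snoRNA")

#' Generate a synthetic two-color m6A array dataset with known truth
#'
#' Draws a [RawArrayDataset][read_array_dataset] from the generative model
#' described in [sim_config()] together with a ground-truth table recording
#' exactly which probes carry planted differential-methylation and
#' differential-expression effects. Deterministic for a fixed seed.
#'
#' @param config a `sim_config` object.
#' @return A list with elements
#'   \describe{
#'     \item{dataset}{a `RawArrayDataset`: probe annotation (spike-ins
#'       carry `rna_type = "spike-in"`), sample sheet, positive linear-scale
#'       `ip` and `sup` intensity matrices, and a `P`/`M`/`A` flag matrix.}
#'     \item{truth}{one row per non-spike-in probe: planted effect
#'       directions `is_diff_meth`, `is_diff_expr` (-1/0/+1) and the true
#'       methylation level in each group.}
#'   }
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)

  np <- config$n_probes
  ns <- config$n_spikeins
  n_samp <- config$n_T + config$n_N
  if (n_samp < 1L) stop("generate_dataset: need at least one sample", call. = FALSE)

  probe_id <- sprintf("P%05d", seq_len(np))
  spike_id <- if (ns > 0) sprintf("SPIKE%02d", seq_len(ns)) else character(0)
  sample_id <- c(if (config$n_T > 0) sprintf("T%d", seq_len(config$n_T)),
                 if (config$n_N > 0) sprintf("N%d", seq_len(config$n_N)))
  group <- c(rep("T", config$n_T), rep("N", config$n_N))

  # annotation: arbitrary but reproducible gene symbols and loci
  rna_type <- sample(rna_types_regular, np, replace = TRUE,
                     prob = c(0.70, 0.15, 0.05, 0.05, 0.05))
  chrom <- paste0("chr", sample(c(1:22, "X"), np, replace = TRUE))
  start <- sample.int(2e8, np)
  width <- sample.int(1e5, np)
  probes <- data.frame(
    probe_id = c(probe_id, spike_id),
    gene_symbol = c(sprintf("GENE%04d", seq_len(np)),
                    if (ns > 0) sprintf("ERCC%02d", seq_len(ns))),
    rna_type = c(rna_type, rep("spike-in", ns)),
    chrom = c(chrom, rep("spikein_ctrl", ns)),
    start = c(start, rep(1L, ns)),
    end = c(start + width, rep(100L, ns)),
    strand = c(sample(c("+", "-"), np, replace = TRUE), rep("+", ns)),
    stringsAsFactors = FALSE
  )

  # planted truth
  n_meth <- round(config$frac_diff_meth * np)
  n_expr <- round(config$frac_diff_expr * np)
  meth_idx <- if (n_meth > 0) sort(sample.int(np, n_meth)) else integer(0)
  expr_idx <- if (n_expr > 0) sort(sample.int(np, n_expr)) else integer(0)
  meth_dir <- sign(config$meth_effect_log2)
  expr_dir <- sign(config$expr_effect_log2)

  base_expr <- stats::rnorm(np, config$baseline_log2_mean, config$baseline_log2_sd)
  base_meth <- stats::runif(np, config$meth_baseline_range[1],
                            config$meth_baseline_range[2])

  # true methylation level in T after the planted IP-channel shift
  shift <- numeric(np)
  shift[meth_idx] <- config$meth_effect_log2
  meth_T <- base_meth * 2^shift / (base_meth * 2^shift + (1 - base_meth))

  truth <- data.frame(
    probe_id = probe_id,
    is_diff_meth = ifelse(seq_len(np) %in% meth_idx, meth_dir, 0L),
    is_diff_expr = ifelse(seq_len(np) %in% expr_idx, expr_dir, 0L),
    true_meth_level_T = meth_T,
    true_meth_level_N = base_meth,
    stringsAsFactors = FALSE
  )

  in_T <- group == "T"
  ip_log2 <- matrix(base_expr + log2(base_meth), np, n_samp)
  sup_log2 <- matrix(base_expr + log2(1 - base_meth), np, n_samp)
  ip_log2[meth_idx, in_T] <- ip_log2[meth_idx, in_T] + config$meth_effect_log2
  ip_log2[expr_idx, in_T] <- ip_log2[expr_idx, in_T] + config$expr_effect_log2
  sup_log2[expr_idx, in_T] <- sup_log2[expr_idx, in_T] + config$expr_effect_log2

  if (ns > 0) {
    ip_log2 <- rbind(ip_log2, matrix(config$spikein_log2, ns, n_samp))
    sup_log2 <- rbind(sup_log2, matrix(config$spikein_log2, ns, n_samp))
  }
  ntot <- np + ns

  dye_ip <- stats::rnorm(n_samp, 0, config$dye_effect_log2_sd)
  dye_sup <- stats::rnorm(n_samp, 0, config$dye_effect_log2_sd)
  ip_log2 <- ip_log2 + rep(dye_ip, each = ntot) +
    stats::rnorm(ntot * n_samp, 0, config$noise_log2_sd)
  sup_log2 <- sup_log2 + rep(dye_sup, each = ntot) +
    stats::rnorm(ntot * n_samp, 0, config$noise_log2_sd)

  flags <- matrix(
    sample(c("P", "M", "A"), ntot * n_samp, replace = TRUE,
           prob = c(0.9 * (1 - config$flag_absent_rate),
                    0.1 * (1 - config$flag_absent_rate),
                    config$flag_absent_rate)),
    ntot, n_samp)
  if (ns > 0) flags[np + seq_len(ns), ] <- "P"

  ids <- probes$probe_id
  dimnames(ip_log2) <- dimnames(sup_log2) <- dimnames(flags) <-
    list(ids, sample_id)

  dataset <- new_raw_array_dataset(
    probes = probes,
    samples = data.frame(sample_id = sample_id, group = group,
                         stringsAsFactors = FALSE),
    ip = 2^ip_log2, sup = 2^sup_log2, flags = flags
  )
  list(dataset = dataset, truth = truth)
}
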