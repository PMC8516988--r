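#' Two-sample unpaired t-test
#'
#' Two-sided unpaired t-test between two groups of values, pooled-variance
#' (Student) by default or Welch. Degenerate zero-variance inputs follow the
#' documented limits instead of erroring: both groups constant and equal
#' gives `t = 0, p = 1`; both constant but unequal gives `p = 0` with
#' infinite `t`.
#'
#' @param x,y numeric vectors, each of length >= 2, finite.
#' @param variant `"student"` (pooled variance, the default) or `"welch"`.
#' @return A list with `t`, `df` and the two-sided `p`.
#' @export
unpaired_t_test <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) {
    stop("unpaired_t_test: each group needs at least 2 values", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("unpaired_t_test: values must be finite", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    df <- length(x) + length(y) - 2
    if (mean(x) == mean(y)) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = df, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = (variant == "student"))
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Classification thresholds for regulation calls
#'
#' @param alpha significance level for both axes (default 0.05, the level the
#'   field conventionally reports).
#' @param fc_log2_min minimum |log2 fold change| on the m6A axis; the default
#'   0 makes the call sign-only.
#' @param meth_ratio_bounds `(lower, upper)` bounds on the linear methylation
#'   ratio when classifying on the `meth` axis; the default `(1, 1)` is
#'   sign-only.
#' @return A list of class `classification_thresholds`.
#' @export
classification_thresholds <- function(alpha = 0.05, fc_log2_min = 0,
                                      meth_ratio_bounds = c(1, 1)) {
  stopifnot(alpha > 0, alpha < 1, fc_log2_min >= 0,
            length(meth_ratio_bounds) == 2,
            meth_ratio_bounds[1] <= meth_ratio_bounds[2])
  structure(list(alpha = alpha, fc_log2_min = fc_log2_min,
                 meth_ratio_bounds = meth_ratio_bounds),
            class = "classification_thresholds")
}

# both axes assessed independently; returns meth_status / expr_status /
# combined regulation label
classify_axes <- function(records, thresholds, axis = c("m6a", "meth")) {
  axis <- match.arg(axis)
  a <- thresholds$alpha
  if (axis == "m6a") {
    p <- records$p_m6a
    fc <- records$fc_m6a_log2
    hypo <- !is.na(p) & !is.na(fc) & p <= a & fc < -thresholds$fc_log2_min
    hyper <- !is.na(p) & !is.na(fc) & p <= a & fc > thresholds$fc_log2_min
  } else {
    p <- records$p_meth
    r <- records$fc_meth_ratio
    hypo <- !is.na(p) & !is.na(r) & p <= a & r < thresholds$meth_ratio_bounds[1]
    hyper <- !is.na(p) & !is.na(r) & p <= a & r > thresholds$meth_ratio_bounds[2]
  }
  meth_status <- ifelse(hypo, "hypo", ifelse(hyper, "hyper", "ns"))
  pg <- records$p_ge
  fg <- records$fc_ge_log2
  down <- !is.na(pg) & !is.na(fg) & pg <= a & fg < 0
  up <- !is.na(pg) & !is.na(fg) & pg <= a & fg > 0
  expr_status <- ifelse(down, "down", ifelse(up, "up", "ns"))
  both <- meth_status != "ns" & expr_status != "ns"
  regulation <- ifelse(
    both,
    paste0(ifelse(meth_status == "hypo", "Hypo", "Hyper"), "-", expr_status),
    "ns")
  list(meth_status = meth_status, expr_status = expr_status,
       regulation = regulation)
}

#' Classify probes into hyper/hypo x up/down regulation classes
#'
#' A probe is hypo-methylated when its m6A statistic is significantly lower
#' in patients (T) than controls (N) — `p <= alpha` and fold change below the
#' threshold — and hyper-methylated in the mirror case; the `-up`/`-down`
#' suffix comes from the analogous call on the expression axis. The two axes
#' are assessed independently; a probe significant on both gets one of
#' `Hyper-up`, `Hyper-down`, `Hypo-up`, `Hypo-down`, anything else is `ns`.
#' Exactly one label per record.
#'
#' @param records data.frame carrying `fc_m6a_log2`, `p_m6a` (or, for
#'   `axis = "meth"`, `fc_meth_ratio`, `p_meth`) and `fc_ge_log2`, `p_ge`.
#' @param thresholds a [classification_thresholds()] object.
#' @param axis which methylation statistic drives the hyper/hypo call:
#'   `"m6a"` (log2 m6A-quantity fold change, default) or `"meth"` (linear
#'   methylation-level ratio).
#' @return Character vector of regulation labels, one per row.
#' @export
classify_regulation <- function(records, thresholds = classification_thresholds(),
                                axis = c("m6a", "meth")) {
  classify_axes(records, thresholds, axis)$regulation
}

#' Per-probe fold changes between patient and control groups
#'
#' Fold changes are T relative to N (negative log2 values = lower in
#' patients):
#' `fc_meth_ratio` — linear ratio of group means of the methylation level;
#' `fc_m6a_log2` — difference of group means of log2 m6A quantity;
#' `fc_ge_log2` — the same on log2 expression. Missing values are excluded
#' per group; a group with fewer than 2 usable samples, or a zero control
#' mean in the denominator, yields `NA` for that statistic.
#'
#' @param profile a `MethylationProfile` (see [quantify()]).
#' @param groups optional character vector of group labels per sample;
#'   defaults to `profile$samples$group`.
#' @return data.frame with `probe_id`, `fc_meth_ratio`, `fc_m6a_log2`,
#'   `fc_ge_log2`.
#' @export
fold_changes <- function(profile, groups = NULL) {
  if (is.null(groups)) groups <- profile$samples$group
  t_idx <- which(groups == "T")
  n_idx <- which(groups == "N")
  if (length(t_idx) < 2 || length(n_idx) < 2) {
    stop("fold_changes: each group needs at least 2 samples", call. = FALSE)
  }
  grp_mean <- function(m, idx) {
    mm <- m[, idx, drop = FALSE]
    mu <- rowMeans(mm, na.rm = TRUE)
    mu[rowSums(!is.na(mm)) < 2] <- NA_real_
    mu
  }
  meth_T <- grp_mean(profile$meth_level, t_idx)
  meth_N <- grp_mean(profile$meth_level, n_idx)
  fc_meth <- meth_T / meth_N
  fc_meth[!is.na(meth_N) & meth_N == 0] <- NA_real_

  lq <- log2(profile$m6a_quantity)
  le <- log2(profile$expression)
  data.frame(
    probe_id = rownames(profile$meth_level),
    fc_meth_ratio = fc_meth,
    fc_m6a_log2 = grp_mean(lq, t_idx) - grp_mean(lq, n_idx),
    fc_ge_log2 = grp_mean(le, t_idx) - grp_mean(le, n_idx),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# row-wise two-group t-test p-values with per-probe missing-value exclusion
row_t_p <- function(m, t_idx, n_idx, variant) {
  vapply(seq_len(nrow(m)), function(i) {
    x <- m[i, t_idx]; y <- m[i, n_idx]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    unpaired_t_test(x, y, variant = variant)$p
  }, numeric(1))
}

#' Differential methylation/expression table
#'
#' For every probe in a methylation profile, computes the three fold changes
#' ([fold_changes()]), unpaired t-test p-values on the methylation level, the
#' log2 m6A quantity and the log2 expression ([unpaired_t_test()]), and the
#' regulation class ([classify_regulation()]).
#'
#' @inheritParams fold_changes
#' @inheritParams classify_regulation
#' @param variant t-test variant, `"student"` (default) or `"welch"`.
#' @param adjust add Benjamini-Hochberg adjusted p-value columns
#'   (`padj_meth`, `padj_m6a`, `padj_ge`); raw p-values stay the basis of the
#'   regulation call.
#' @return data.frame of class `DifferentialTable`, one row per probe:
#'   annotation columns, `fc_meth_ratio`, `fc_m6a_log2`, `fc_ge_log2`,
#'   `p_meth`, `p_m6a`, `p_ge`, `meth_status`, `expr_status`, `regulation`.
#' @export
differential_table <- function(profile, thresholds = classification_thresholds(),
                               variant = c("student", "welch"),
                               axis = c("m6a", "meth"), adjust = FALSE,
                               groups = NULL) {
  variant <- match.arg(variant)
  axis <- match.arg(axis)
  if (is.null(groups)) groups <- profile$samples$group
  t_idx <- which(groups == "T")
  n_idx <- which(groups == "N")

  fc <- fold_changes(profile, groups = groups)
  tab <- data.frame(
    probe_id = profile$probes$probe_id,
    gene_symbol = profile$probes$gene_symbol,
    rna_type = profile$probes$rna_type,
    locus = format_locus(profile$probes$chrom, profile$probes$start,
                         profile$probes$end, profile$probes$strand),
    fc[c("fc_meth_ratio", "fc_m6a_log2", "fc_ge_log2")],
    p_meth = row_t_p(profile$meth_level, t_idx, n_idx, variant),
    p_m6a = row_t_p(log2(profile$m6a_quantity), t_idx, n_idx, variant),
    p_ge = row_t_p(log2(profile$expression), t_idx, n_idx, variant),
    stringsAsFactors = FALSE
  )
  cls <- classify_axes(tab, thresholds, axis)
  tab$meth_status <- cls$meth_status
  tab$expr_status <- cls$expr_status
  tab$regulation <- cls$regulation
  if (adjust) {
    tab$padj_meth <- stats::p.adjust(tab$p_meth, method = "BH")
    tab$padj_m6a <- stats::p.adjust(tab$p_m6a, method = "BH")
    tab$padj_ge <- stats::p.adjust(tab$p_ge, method = "BH")
  }
  class(tab) <- c("DifferentialTable", class(tab))
  tab
}

top_table_keys <- c(
  m6a_fc_asc = "fc_m6a_log2", m6a_fc_desc = "fc_m6a_log2",
  meth_ratio_asc = "fc_meth_ratio", meth_ratio_desc = "fc_meth_ratio",
  ge_fc_asc = "fc_ge_log2", ge_fc_desc = "fc_ge_log2",
  p_m6a_asc = "p_m6a", p_meth_asc = "p_meth"
)

#' Top-N selection from a differential table
#'
#' Stable sort by the chosen key with ties broken by `probe_id`
#' (lexicographic), optional row filters, at most `n` rows. Sorting
#' ascending by m6A log2 fold change over the hypo-down class, for example,
#' reproduces the published style of "top 20 hypo-methylated" tables.
#'
#' @param records a `DifferentialTable` (or any data.frame with the key
#'   columns).
#' @param n maximum rows to return.
#' @param key sort key: one of `m6a_fc_asc`, `m6a_fc_desc`, `meth_ratio_asc`,
#'   `meth_ratio_desc`, `ge_fc_asc`, `ge_fc_desc`, `p_m6a_asc`, `p_meth_asc`.
#' @param filter optional named list; each element restricts the
#'   corresponding column to the given values, e.g.
#'   `list(regulation = c("Hypo-down"))` or `list(meth_status = "hypo",
#'   rna_type = "mRNA")`.
#' @return The selected rows in sorted order.
#' @export
top_table <- function(records, n = 20, key = names(top_table_keys),
                      filter = NULL) {
  key <- match.arg(key)
  stopifnot(n >= 1)
  rows <- rep(TRUE, nrow(records))
  for (col in names(filter)) {
    rows <- rows & records[[col]] %in% filter[[col]]
  }
  out <- records[rows, , drop = FALSE]
  val <- out[[top_table_keys[[key]]]]
  if (grepl("_desc$", key)) val <- -val
  out <- out[order(val, out$probe_id), , drop = FALSE]
  utils::head(out, n)
}

#' Agglomerative hierarchical clustering with deterministic leaf order
#'
#' Clusters the rows of a matrix (e.g. samples by their methylation-level
#' profiles). Rows are sorted by their names before clustering so that the
#' tree, and the tie-breaking inside [stats::hclust()], do not depend on
#' input order. Output includes a Newick serialization (via
#' [ape::as.phylo()]) with branch lengths from the merge heights.
#'
#' @param x numeric matrix with unique, non-empty rownames; no missing
#'   values.
#' @param distance `"euclidean"`, `"manhattan"`, or `"correlation"`
#'   (`1 - Pearson r` between rows).
#' @param linkage agglomeration method: `"average"` (default), `"complete"`,
#'   `"single"` or `"ward"` (ward.D2).
#' @return A list with the `hclust` object (`tree`), the leaf `order`
#'   (labels, left to right) and the `newick` string.
#' @export
hierarchical_cluster <- function(x,
                                 distance = c("euclidean", "manhattan",
                                              "correlation"),
                                 linkage = c("average", "complete", "single",
                                             "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("hierarchical_cluster: need at least 2 items",
                        call. = FALSE)
  if (any(!is.finite(x))) {
    stop("hierarchical_cluster: non-finite entries in input", call. = FALSE)
  }
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    stop("hierarchical_cluster: rows must have unique names", call. = FALSE)
  }
  x <- x[order(rownames(x)), , drop = FALSE]
  d <- switch(distance,
              euclidean = stats::dist(x, method = "euclidean"),
              manhattan = stats::dist(x, method = "manhattan"),
              correlation = stats::as.dist(1 - stats::cor(t(x))))
  hc <- stats::hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
  list(tree = hc,
       order = hc$labels[hc$order],
       newick = ape::write.tree(ape::as.phylo(hc)))
}
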