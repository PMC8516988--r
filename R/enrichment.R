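#' Fisher-exact over-representation analysis
#'
#' Tests each gene set for over-representation of a hit list against a
#' background universe. Gene sets are intersected with the background before
#' testing; the p-value is the one-sided (enrichment) Fisher exact test,
#' i.e. the hypergeometric upper tail
#' `P(overlap >= observed)` with the background as the urn, and the
#' enrichment score is `-log10(p)`. No multiple-testing correction is applied
#' to the score (published enrichment bar/dot plots show raw `-log10 p`); BH
#' adjusted p-values can be added as an extra column.
#'
#' @param hits character vector of hit identifiers (e.g. hypo-methylated
#'   gene symbols); must be a subset of `background`.
#' @param background character vector: the measurable universe (typically all
#'   flag-filtered probes collapsed to unique gene symbols).
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @param categories optional named character vector mapping set names to a
#'   category (`BP`, `CC`, `MF`, `pathway`, ...); defaults to `"custom"`.
#' @param adjust add a BH-adjusted p-value column `padj`.
#' @return data.frame of class `EnrichmentResult`, one row per gene set,
#'   ordered by `(p, term_id)`: `term_id`, `term_name`, `category`,
#'   `n_hits_in_set`, `set_size`, `n_hits`, `background_size`, `p`, `score`.
#' @export
fisher_enrichment <- function(hits, background, gene_sets, categories = NULL,
                              adjust = FALSE) {
  hits <- unique(as.character(hits))
  background <- unique(as.character(background))
  if (length(background) == 0) {
    stop("fisher_enrichment: background is empty", call. = FALSE)
  }
  offenders <- setdiff(hits, background)
  if (length(offenders) > 0) {
    stop("fisher_enrichment: hits not contained in background: ",
         paste(offenders, collapse = ", "), call. = FALSE)
  }
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    stop("fisher_enrichment: gene_sets must be a named list", call. = FALSE)
  }
  N <- length(background)
  n_hits <- length(hits)
  descr <- attr(gene_sets, "descriptions")

  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(unique(gene_sets[[nm]]), background)
    K <- length(members)
    k <- length(intersect(members, hits))
    p <- stats::phyper(k - 1, n_hits, N - n_hits, K, lower.tail = FALSE)
    data.frame(term_id = nm,
               term_name = if (!is.null(descr) && nzchar(descr[[nm]])) descr[[nm]] else nm,
               category = if (!is.null(categories) && nm %in% names(categories))
                 categories[[nm]] else "custom",
               n_hits_in_set = k, set_size = K, n_hits = n_hits,
               background_size = N, p = p, score = -log10(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  if (adjust) out$padj <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("EnrichmentResult", class(out))
  out
}

#' Select the most enriched terms
#'
#' The `n` lowest-p terms, optionally the `n` lowest per category (the usual
#' "top 10 per BP/CC/MF" presentation). Ties broken by `term_id`.
#'
#' @param records an `EnrichmentResult` (see [fisher_enrichment()]).
#' @param n maximum terms (per category when `per_category`).
#' @param per_category select within each `category` separately.
#' @return The selected rows, ordered by `(category,) p, term_id`.
#' @export
top_terms <- function(records, n = 10, per_category = FALSE) {
  stopifnot(n >= 1)
  pick <- function(df) {
    df <- df[order(df$p, df$term_id), , drop = FALSE]
    utils::head(df, n)
  }
  if (!per_category) {
    out <- pick(records)
  } else {
    parts <- split(records, records$category)
    out <- do.call(rbind, lapply(parts[order(names(parts))], pick))
  }
  rownames(out) <- NULL
  out
}
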