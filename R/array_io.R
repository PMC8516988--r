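#' @keywords internal
new_raw_array_dataset <- function(probes, samples, ip, sup, flags) {
  ds <- list(probes = probes, samples = samples, ip = ip, sup = sup,
             flags = flags)
  class(ds) <- "RawArrayDataset"
  validate_raw_array_dataset(ds)
}

validate_raw_array_dataset <- function(ds) {
  p <- ds$probes
  if (anyDuplicated(p$probe_id)) {
    stop("duplicate probe_id: ",
         paste(unique(p$probe_id[duplicated(p$probe_id)]), collapse = ", "),
         call. = FALSE)
  }
  dims_ok <- all(dim(ds$ip) == c(nrow(p), nrow(ds$samples))) &&
    identical(dim(ds$ip), dim(ds$sup)) && identical(dim(ds$ip), dim(ds$flags))
  if (!dims_ok) stop("intensity/flag matrix dimensions do not match the ",
                     "annotation and sample sheet", call. = FALSE)
  if (!setequal(unique(ds$samples$group), c("T", "N"))) {
    stop("sample sheet must contain exactly the two groups 'T' and 'N'",
         call. = FALSE)
  }
  for (ch in c("ip", "sup")) {
    m <- ds[[ch]]
    bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("non-positive raw intensity in channel %s at probe '%s', sample '%s'",
                   toupper(ch), p$probe_id[bad[1, 1]],
                   ds$samples$sample_id[bad[1, 2]]), call. = FALSE)
    }
  }
  if (!all(ds$flags %in% c("P", "M", "A"))) {
    stop("QC flags must be one of 'P', 'M', 'A'", call. = FALSE)
  }
  any_bad <- !is.finite(p$start) | !is.finite(p$end) | p$start > p$end
  if (any(any_bad)) {
    stop("annotation has start > end for probe(s): ",
         paste(p$probe_id[any_bad], collapse = ", "), call. = FALSE)
  }
  ds
}

#' @export
print.RawArrayDataset <- function(x, ...) {
  cat(sprintf("RawArrayDataset: %d probes (%d spike-in) x %d samples (%d T, %d N)\n",
              nrow(x$probes), sum(x$probes$rna_type == "spike-in"),
              nrow(x$samples), sum(x$samples$group == "T"),
              sum(x$samples$group == "N")))
  invisible(x)
}

#' Serialize and parse genomic loci
#'
#' Loci are carried as annotation strings in the style
#' `chr15:80253234-80263511:-` (1-based, fully closed interval, strand as the
#' trailing token). The parser additionally tolerates comma-grouped digits and
#' en-dash separators as they appear in printed tables; the writer always
#' emits plain ungrouped digits and a hyphen.
#'
#' @param chrom,start,end,strand vectors of locus components.
#' @param x character vector of locus strings.
#' @return `format_locus()` a character vector; `parse_locus()` a data.frame
#'   with columns `chrom`, `start`, `end`, `strand`.
#' @export
format_locus <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d:%s", chrom, as.integer(start), as.integer(end), strand)
}

#' @rdname format_locus
#' @export
parse_locus <- function(x) {
  x <- gsub(",", "", trimws(x))
  x <- gsub("–", "-", x)              # en dash used in printed tables
  m <- regmatches(x, regexec("^(.+):([0-9]+)-([0-9]+):([+-])$", x))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) {
    stop("unparseable locus: ", paste(x[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    strand = vapply(m, `[`, "", 5L),
    stringsAsFactors = FALSE
  )
}

# full-precision numeric serialization so read(write(x)) is bit-exact
fmt_num <- function(x) sprintf("%.17g", x)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write a raw array dataset as tab-delimited files
#'
#' Writes the three files [read_array_dataset()] reads: an intensity table
#' (`probe_id` plus `<sample>_IP`, `<sample>_Sup` and `<sample>_flag` columns
#' per sample), a probe annotation table (`probe_id`, `gene_symbol`,
#' `rna_type`, `locus`) and a sample sheet (`sample_id`, `group`). Numeric
#' intensities are serialized at full precision so a read-back reproduces the
#' in-memory dataset exactly.
#'
#' @param dataset a `RawArrayDataset`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the three file paths (named `intensities`,
#'   `annotation`, `samples`).
#' @export
write_array_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(intensities = file.path(dir, "intensities.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             samples = file.path(dir, "samples.tsv"))

  intens <- data.frame(probe_id = dataset$probes$probe_id,
                       stringsAsFactors = FALSE)
  for (j in seq_len(nrow(dataset$samples))) {
    s <- dataset$samples$sample_id[j]
    intens[[paste0(s, "_IP")]] <- fmt_num(dataset$ip[, j])
    intens[[paste0(s, "_Sup")]] <- fmt_num(dataset$sup[, j])
    intens[[paste0(s, "_flag")]] <- dataset$flags[, j]
  }
  write_tsv(intens, paths["intensities"])

  annot <- data.frame(
    probe_id = dataset$probes$probe_id,
    gene_symbol = dataset$probes$gene_symbol,
    rna_type = dataset$probes$rna_type,
    locus = format_locus(dataset$probes$chrom, dataset$probes$start,
                         dataset$probes$end, dataset$probes$strand),
    stringsAsFactors = FALSE
  )
  write_tsv(annot, paths["annotation"])
  write_tsv(dataset$samples, paths["samples"])
  invisible(paths)
}

#' Read a two-color array dataset from tab-delimited files
#'
#' Loads probe intensities, probe annotation and a sample sheet into a
#' validated `RawArrayDataset`. The intensity table must carry, for every
#' sample named in the sample sheet, the columns `<sample>_IP`,
#' `<sample>_Sup` (positive linear-scale intensities, Cy5 and Cy3) and
#' `<sample>_flag` (`P`/`M`/`A` quality calls). Probes present in the
#' intensity table but missing from the annotation are kept with
#' `rna_type = "other"` and a warning. Flag-based filtering is deliberately
#' not applied here; see [filter_by_flags()].
#'
#' @param intensity_path,annotation_path,sample_sheet_path file paths.
#' @return A `RawArrayDataset`: `probes` (annotation data.frame), `samples`
#'   (sample sheet), `ip`, `sup` (probes x samples numeric matrices) and
#'   `flags` (character matrix).
#' @export
read_array_dataset <- function(intensity_path, annotation_path,
                               sample_sheet_path) {
  intens <- read_tsv(intensity_path)
  annot <- read_tsv(annotation_path)
  samples <- read_tsv(sample_sheet_path)

  if (!all(c("sample_id", "group") %in% names(samples))) {
    stop("sample sheet must have columns 'sample_id' and 'group'", call. = FALSE)
  }
  if (anyDuplicated(intens$probe_id)) {
    stop("duplicate probe_id in intensity table: ",
         paste(unique(intens$probe_id[duplicated(intens$probe_id)]),
               collapse = ", "), call. = FALSE)
  }
  need <- as.vector(t(outer(samples$sample_id, c("_IP", "_Sup", "_flag"),
                            paste0)))
  missing_cols <- setdiff(need, names(intens))
  if (length(missing_cols) > 0) {
    stop("intensity table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  ids <- as.character(intens$probe_id)
  grab <- function(suffix) {
    m <- as.matrix(intens[paste0(samples$sample_id, suffix)])
    dimnames(m) <- list(ids, samples$sample_id)
    m
  }
  ip <- grab("_IP"); storage.mode(ip) <- "double"
  sup <- grab("_Sup"); storage.mode(sup) <- "double"
  flags <- grab("_flag")

  loc <- parse_locus(annot$locus)
  annot <- data.frame(probe_id = annot$probe_id,
                      gene_symbol = annot$gene_symbol,
                      rna_type = annot$rna_type,
                      loc, stringsAsFactors = FALSE)
  unannotated <- setdiff(ids, annot$probe_id)
  if (length(unannotated) > 0) {
    warning(length(unannotated), " probe(s) without annotation assigned ",
            "rna_type = 'other': ",
            paste(utils::head(unannotated, 5), collapse = ", "),
            if (length(unannotated) > 5) ", ...", call. = FALSE)
    annot <- rbind(annot, data.frame(
      probe_id = unannotated, gene_symbol = unannotated, rna_type = "other",
      chrom = "unknown", start = 1L, end = 1L, strand = "+",
      stringsAsFactors = FALSE))
  }
  probes <- annot[match(ids, annot$probe_id), ]
  rownames(probes) <- NULL

  new_raw_array_dataset(probes = probes, samples = samples, ip = ip,
                        sup = sup, flags = flags)
}

differential_columns <- c(
  "probe_id", "gene_symbol", "rna_type", "regulation", "meth_status",
  "expr_status", "fc_meth_ratio", "fc_m6a_log2", "fc_ge_log2",
  "p_meth", "p_m6a", "p_ge", "locus"
)

#' Write a differential methylation/expression table
#'
#' Tab-delimited, one row per probe, in the stable column order
#' `probe_id, gene_symbol, rna_type, regulation, meth_status, expr_status,
#' fc_meth_ratio, fc_m6a_log2, fc_ge_log2, p_meth, p_m6a, p_ge, locus`
#' (any BH-adjusted columns appended after), mirroring published top-table
#' layouts (gene, regulation class such as `Hypo-down`, log2 fold changes for
#' m6A and gene expression, locus). Loci are serialized as
#' `chr:start-end:strand`; numerics at full precision.
#'
#' @param table a `DifferentialTable` (see [differential_table()]).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_differential_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    stop("differential table is empty; nothing to write", call. = FALSE)
  }
  out <- as.data.frame(table)
  if (!"locus" %in% names(out)) {
    out$locus <- format_locus(out$chrom, out$start, out$end, out$strand)
  }
  extra <- setdiff(names(out),
                   c(differential_columns, "chrom", "start", "end", "strand"))
  out <- out[c(differential_columns, extra)]
  for (nm in names(out)) if (is.numeric(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  write_tsv(out, path)
  invisible(path)
}

#' @rdname write_differential_table
#' @description `read_differential_table()` reads the format back (used for
#'   round-trip verification and by downstream scripts).
#' @export
read_differential_table <- function(path) {
  out <- read_tsv(path, colClasses = "character")
  num_cols <- intersect(c("fc_meth_ratio", "fc_m6a_log2", "fc_ge_log2",
                          "p_meth", "p_m6a", "p_ge",
                          "padj_meth", "padj_m6a", "padj_ge"), names(out))
  for (nm in num_cols) out[[nm]] <- as.numeric(out[[nm]])
  class(out) <- c("DifferentialTable", class(out))
  out
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one gene set per line, tab-delimited fields
#' `name, description, member, member, ...`. Duplicate members within a line
#' are collapsed.
#'
#' @param path a GMT file.
#' @return A named list of character vectors of unique member identifiers.
#'   The set descriptions are kept in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(structure(list(), descriptions = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short) > 0) {
    stop("GMT line ", short[1], " has fewer than 3 fields", call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1L)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(fields, `[`, "", 2L), names(sets))
  sets
}
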