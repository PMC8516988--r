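#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Exactly
#' one data source must be given: either `simulation` (a list of
#' [sim_config()] arguments) or `input` (a list with paths `intensities`,
#' `annotation`, `samples` for [read_array_dataset()]).
#'
#' @param simulation list of [sim_config()] arguments, or `NULL`.
#' @param input list of input file paths, or `NULL`.
#' @param out_dir output directory.
#' @param thresholds a [classification_thresholds()] object.
#' @param variant t-test variant (`"student"`/`"welch"`).
#' @param axis methylation axis for the regulation call (`"m6a"`/`"meth"`).
#' @param min_present flag-filter threshold.
#' @param top_n_tables rows in the top tables (default 20).
#' @param top_n_terms terms in the enrichment selection (default 10).
#' @param gmt optional GMT file for over-representation analysis.
#' @param seed integer seed for every stochastic stage.
#' @param log_level `"info"` to narrate stages, `"quiet"` to suppress.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, input = NULL, out_dir,
                            thresholds = classification_thresholds(),
                            variant = "student", axis = "m6a",
                            min_present = 1, top_n_tables = 20,
                            top_n_terms = 10, gmt = NULL, seed = 1L,
                            log_level = c("info", "quiet")) {
  if (is.null(simulation) == is.null(input)) {
    stop("pipeline_config: exactly one of 'simulation' or 'input' must be given",
         call. = FALSE)
  }
  if (!is.null(input) &&
      !all(c("intensities", "annotation", "samples") %in% names(input))) {
    stop("pipeline_config: 'input' needs paths 'intensities', 'annotation', 'samples'",
         call. = FALSE)
  }
  if (!inherits(thresholds, "classification_thresholds")) {
    thresholds <- do.call(classification_thresholds, as.list(thresholds))
  }
  structure(list(simulation = simulation, input = input, out_dir = out_dir,
                 thresholds = thresholds, variant = variant, axis = axis,
                 min_present = min_present, top_n_tables = top_n_tables,
                 top_n_terms = top_n_terms, gmt = gmt, seed = as.integer(seed),
                 log_level = match.arg(log_level)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [pipeline_config()]; `simulation` is
#' a nested block of [sim_config()] keys, `input` a nested block of the three
#' file paths.
#'
#' @param path YAML file.
#' @param out_dir optional override of the configured output directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  if (!is.null(y$thresholds)) {
    y$thresholds <- do.call(classification_thresholds, y$thresholds)
  }
  do.call(pipeline_config, y)
}

run_stage <- function(name, expr, quiet) {
  if (!quiet) message("[", name, "] running")
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load, quantification, differential analysis,
#' clustering, association statistics and (when a GMT file is configured)
#' over-representation analysis, writing every result under
#' `config$out_dir`:
#' `meth_level.tsv`, `m6a_quantity.tsv`, `expression.tsv`,
#' `kept_probes.tsv`, `differential_table.tsv`, `top_hypo_mrna.tsv`
#' (mRNA probes in a `Hypo-*` class, most negative m6A log2 fold changes
#' first), `top_hypo_noncoding.tsv` (non-mRNA hypo-methylated probes by
#' ascending methylation ratio), `cluster_tree.nwk` (sample tree on
#' methylation levels) plus `cluster_leaf_order.txt`, `stats_report.tsv`, and
#' a `manifest.json` recording the configuration, seed, package/R versions
#' and the output inventory. Identical configuration and seed give identical
#' outputs.
#'
#' @param config a [pipeline_config()] (or a list accepted by it).
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  quiet <- config$log_level == "quiet"
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  add_out <- function(paths) outputs <<- c(outputs, unname(paths))

  dataset <- run_stage("data", {
    if (!is.null(config$simulation)) {
      sim_args <- config$simulation
      sim_args$seed <- config$seed
      sim <- generate_dataset(do.call(sim_config, sim_args))
      truth_path <- file.path(config$out_dir, "ground_truth.tsv")
      write_tsv(sim$truth, truth_path)
      add_out(truth_path)
      sim$dataset
    } else {
      read_array_dataset(config$input$intensities, config$input$annotation,
                         config$input$samples)
    }
  }, quiet)

  profile <- run_stage("quantify", {
    p <- quantify(dataset, min_present = config$min_present)
    add_out(write_methylation_profile(p, config$out_dir))
    p
  }, quiet)

  diff_tab <- run_stage("differential", {
    tab <- differential_table(profile, thresholds = config$thresholds,
                              variant = config$variant, axis = config$axis)
    path <- file.path(config$out_dir, "differential_table.tsv")
    write_differential_table(tab, path)
    add_out(path)

    top_mrna <- top_table(tab, n = config$top_n_tables, key = "m6a_fc_asc",
                          filter = list(rna_type = "mRNA",
                                        regulation = c("Hypo-down", "Hypo-up")))
    top_nc <- top_table(tab, n = config$top_n_tables, key = "meth_ratio_asc",
                        filter = list(
                          rna_type = setdiff(unique(tab$rna_type), "mRNA"),
                          meth_status = "hypo"))
    p1 <- file.path(config$out_dir, "top_hypo_mrna.tsv")
    p2 <- file.path(config$out_dir, "top_hypo_noncoding.tsv")
    if (nrow(top_mrna) > 0) { write_differential_table(top_mrna, p1); add_out(p1) }
    if (nrow(top_nc) > 0) { write_differential_table(top_nc, p2); add_out(p2) }
    tab
  }, quiet)

  run_stage("clustering", {
    cl <- hierarchical_cluster(t(profile$meth_level))
    nwk <- file.path(config$out_dir, "cluster_tree.nwk")
    writeLines(cl$newick, nwk)
    ord <- file.path(config$out_dir, "cluster_leaf_order.txt")
    writeLines(cl$order, ord)
    add_out(c(nwk, ord))
  }, quiet)

  run_stage("association", {
    grp <- profile$samples$group
    mean_meth <- colMeans(profile$meth_level, na.rm = TRUE)
    mean_q <- colMeans(log2(profile$m6a_quantity), na.rm = TRUE)
    tt <- unpaired_t_test(mean_meth[grp == "T"], mean_meth[grp == "N"],
                          variant = config$variant)
    # per-sample mean methylation vs mean log2 m6A quantity (expression is
    # quantile-normalized, so its per-sample mean is constant by design)
    pc <- pearson_correlation(mean_meth, mean_q)
    report <- data.frame(
      statistic = c("mean_meth_level_T", "mean_meth_level_N",
                    "t_mean_meth_T_vs_N", "p_mean_meth_T_vs_N",
                    "pearson_r_meth_vs_m6a", "pearson_p_meth_vs_m6a"),
      value = c(mean(mean_meth[grp == "T"]), mean(mean_meth[grp == "N"]),
                tt$t, tt$p, pc$r, pc$p),
      stringsAsFactors = FALSE
    )
    path <- file.path(config$out_dir, "stats_report.tsv")
    write_tsv(report, path)
    add_out(path)
  }, quiet)

  if (!is.null(config$gmt)) {
    run_stage("enrichment", {
      sets <- read_gmt(config$gmt)
      background <- unique(diff_tab$gene_symbol)
      hits <- unique(diff_tab$gene_symbol[diff_tab$meth_status == "hypo"])
      enr <- fisher_enrichment(hits, background, sets)
      enr <- top_terms(enr, n = config$top_n_terms)
      path <- file.path(config$out_dir, "enrichment.tsv")
      write_tsv(enr, path)
      add_out(path)
    }, quiet)
  }

  manifest <- list(
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    versions = list(package = as.character(utils::packageVersion("meriparray")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    outputs = sort(basename(outputs))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  if (!quiet) message("pipeline complete: ", length(outputs),
                      " output files in ", config$out_dir)
  invisible(config$out_dir)
}
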