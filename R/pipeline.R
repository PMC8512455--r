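#' Load a pipeline configuration
#'
#' A flat YAML (or list) of pipeline settings: input paths, assay, rule,
#' thresholds, estimation choices, output directory, and simulation
#' parameters. Every threshold the screen uses (valid-value minima via the
#' rule, gate alpha, FDR) is surfaced here, with the defaults of the
#' reference workflow (gate alpha 0.05, FDR 0.05).
#'
#' @param x path to a YAML file, or a named list.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x)
    yaml::read_yaml(x)
  } else {
    as.list(x)
  }
  defaults <- list(dialect = "generic_wide", fdr = 0.05, gate_alpha = 0.05,
                   method = "ML", omnibus = "wald_f", ci_df = "normal",
                   output_dir = ".", seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (!(cfg$fdr > 0 && cfg$fdr < 1)) stop("fdr must be in (0, 1)")
  if (!(cfg$gate_alpha > 0 && cfg$gate_alpha < 1)) {
    stop("gate_alpha must be in (0, 1)")
  }
  structure(cfg, class = "pipeline_config")
}

default_rule_for_assay <- function(assay) {
  switch(assay,
         serum_tmt = "serum_rule",
         sev_lfq = "sev_rule",
         csf_lfq = "csf_rule",
         stop("unknown assay: ", assay))
}

pipeline_log <- function(dir, lines) {
  cat(paste0(format(Sys.time(), "%H:%M:%S "), lines, "\n"),
      file = file.path(dir, "pipeline.log"), append = TRUE, sep = "")
}

#' Normalization pipeline command
#'
#' Reads the raw intensity table and annotation, applies the assay's
#' exclusion rules, then the assay-appropriate normalization chain — TMT:
#' within-set loading -> between-set reference calibration -> log2;
#' label-free: log2 -> per-sample median centering — and writes the
#' normalized table, normalization reports, exclusion log, and PCA QC
#' scores.
#'
#' @param config a [pipeline_config()] (or path/list coercible to one) with
#'   `assay`, `intensity_table`, `annotation`, optional `dialect` and
#'   `exclusion_config`, and `output_dir`.
#' @return Named character vector of output paths, invisibly.
#' @export
cmd_normalize <- function(config) {
  cfg <- as_pipeline_config(config)
  for (req in c("assay", "intensity_table", "annotation")) {
    if (is.null(cfg[[req]])) stop("config is missing '", req, "'")
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  table <- read_intensity_table(cfg$intensity_table, dialect = cfg$dialect)
  ann <- read_sample_annotation(cfg$annotation)
  rules <- if (is.null(cfg$exclusion_config)) exclusion_rules(cfg$assay)
           else exclusion_rules(cfg$assay, cfg$exclusion_config)
  excl <- exclude_proteins(table, rules)
  table <- excl$table
  pipeline_log(cfg$output_dir,
               c(paste("normalize: assay", cfg$assay),
                 paste("excluded", nrow(excl$log), "proteins;",
                       nrow(table$values), "retained")))
  out <- c(exclusion_log = file.path(cfg$output_dir, "exclusion_log.tsv"))
  write_exclusion_log(excl$log, out["exclusion_log"])

  if (cfg$assay == "serum_tmt") {
    w <- tmt_within_set_normalize(table, ann)
    b <- tmt_between_set_normalize(w$table, ann)
    log2_table <- log2_missing_aware(b$table)
    out["within_set_report"] <- file.path(cfg$output_dir,
                                          "within_set_factors.tsv")
    out["between_set_report"] <- file.path(cfg$output_dir,
                                           "between_set_factors.tsv")
    utils::write.table(w$report, out["within_set_report"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(b$report, out["between_set_report"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    pipeline_log(cfg$output_dir,
                 paste("between-set: uncalibratable (protein, set) pairs:",
                       nrow(b$uncalibratable)))
  } else {
    log2_table <- log2_missing_aware(table)
    m <- median_center(log2_table)
    log2_table <- m$table
    out["median_report"] <- file.path(cfg$output_dir, "sample_medians.tsv")
    utils::write.table(m$report, out["median_report"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out["normalized_table"] <- file.path(cfg$output_dir,
                                       "normalized_table.tsv")
  write_intensity_table(log2_table, out["normalized_table"])
  qc <- tryCatch(pca_qc_scores(log2_table, ann), error = function(e) NULL)
  if (!is.null(qc)) {
    out["pca_scores"] <- file.path(cfg$output_dir, "pca_qc_scores.tsv")
    utils::write.table(qc, out["pca_scores"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(out)
}

#' Screening pipeline command
#'
#' Runs eligibility filtering and the per-protein mixed-model screen on a
#' normalized log2 table, writing the full result table, the disposition
#' counts, the significant-protein gene list (one symbol per line, for
#' external enrichment tools), and long-format coefficient/CI data for
#' effect plots.
#'
#' @param config a [pipeline_config()] with `assay`, `intensity_table`
#'   (normalized, log2-marked), `annotation`, optional `rule`, `fdr`,
#'   `gate_alpha`, `method`, `omnibus`, and `output_dir`.
#' @return Named character vector of output paths, invisibly.
#' @export
cmd_screen <- function(config) {
  cfg <- as_pipeline_config(config)
  for (req in c("assay", "intensity_table", "annotation")) {
    if (is.null(cfg[[req]])) stop("config is missing '", req, "'")
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  table <- read_intensity_table(cfg$intensity_table, dialect = cfg$dialect)
  if (table$scale != "log2") {
    stop("screen expects a normalized log2 table (run cmd_normalize first)")
  }
  ann <- read_sample_annotation(cfg$annotation)
  rule <- eligibility_rule(cfg$rule %||% default_rule_for_assay(cfg$assay))
  result <- run_screen(table, ann, rule, fdr = cfg$fdr,
                       gate_alpha = cfg$gate_alpha, method = cfg$method,
                       omnibus = cfg$omnibus, ci_df = cfg$ci_df)
  counts <- attr(result, "counts")
  pipeline_log(cfg$output_dir,
               c(paste("screen: rule", rule$name, "fdr", cfg$fdr,
                       "gate_alpha", cfg$gate_alpha, "method", cfg$method,
                       "omnibus", cfg$omnibus),
                 paste("dispositions:",
                       paste(names(counts), unlist(counts),
                             sep = "=", collapse = " "))))
  out <- c(screen_result = file.path(cfg$output_dir, "screen_result.tsv"),
           counts = file.path(cfg$output_dir, "disposition_counts.tsv"),
           gene_list = file.path(cfg$output_dir, "significant_genes.txt"),
           plot_data = file.path(cfg$output_dir,
                                 "coefficient_plot_data.tsv"))
  write_screen_result(result, out["screen_result"])
  utils::write.table(
    data.frame(disposition = names(counts), n = unlist(counts),
               row.names = NULL),
    out["counts"], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(significant_gene_list(result), out["gene_list"])
  utils::write.table(coefficient_plot_data(result), out["plot_data"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Simulation pipeline command
#'
#' Generates a synthetic dataset from a preset (or explicit simulation
#' parameters), applies the configured missingness, and writes the raw
#' table, annotation, and ground truth in the same TSV formats the rest of
#' the pipeline reads.
#'
#' @param config a [pipeline_config()] with `seed`, optional `preset`, any
#'   [simulation_config()] overrides, and `output_dir`.
#' @return Named character vector of output paths, invisibly.
#' @export
cmd_simulate <- function(config) {
  cfg <- as_pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  sim_args <- cfg[intersect(names(cfg), names(formals(simulation_config)))]
  sim_cfg <- if (!is.null(cfg$preset)) {
    do.call(simulation_preset, c(list(name = cfg$preset), sim_args))
  } else {
    do.call(simulation_config, sim_args)
  }
  sim <- simulate_longitudinal(sim_cfg)
  thinned <- apply_missingness(sim$table, sim$annotation, sim_cfg)
  pipeline_log(cfg$output_dir,
               paste("simulate: seed", sim_cfg$seed, "design",
                     sim_cfg$design, "proteins", sim_cfg$n_proteins,
                     "mice", sim_cfg$n_mice))
  out <- c(intensity_table = file.path(cfg$output_dir,
                                       "simulated_table.tsv"),
           annotation = file.path(cfg$output_dir,
                                  "simulated_annotation.tsv"),
           truth = file.path(cfg$output_dir, "simulated_truth.tsv"))
  write_intensity_table(thinned$table, out["intensity_table"])
  write_sample_annotation(thinned$annotation, out["annotation"])
  utils::write.table(as.data.frame(sim$truth), out["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Evaluation pipeline command
#'
#' Scores a written screen result against written simulation truth and
#' writes a metrics TSV (false discovery proportion, sensitivity,
#' coefficient bias/RMSE, CI coverage).
#'
#' @param config a [pipeline_config()] with `screen_result`, `truth`, and
#'   `output_dir`.
#' @return Named character vector of output paths, invisibly.
#' @export
cmd_evaluate <- function(config) {
  cfg <- as_pipeline_config(config)
  for (req in c("screen_result", "truth")) {
    if (is.null(cfg[[req]])) stop("config is missing '", req, "'")
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  result <- read_screen_result(cfg$screen_result)
  truth <- read_simulation_truth(cfg$truth)
  metrics <- evaluate_screen(result, truth)
  out <- c(metrics = file.path(cfg$output_dir, "evaluation_metrics.tsv"))
  utils::write.table(
    data.frame(metric = names(metrics), value = unlist(metrics),
               row.names = NULL),
    out["metrics"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read back a written screen-result TSV
#'
#' @param path path written by [write_screen_result()].
#' @return A `screen_result` data.frame.
#' @export
read_screen_result <- function(path) {
  if (!file.exists(path)) stop("screen result not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  df$significant <- parse_flag(df$significant)
  df$gene_symbol <- as.character(df$gene_symbol)
  class(df) <- c("screen_result", "data.frame")
  df
}

#' Read back a written simulation-truth TSV
#'
#' @param path path written by [cmd_simulate()].
#' @return A `simulation_truth` data.frame.
#' @export
read_simulation_truth <- function(path) {
  if (!file.exists(path)) stop("truth file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  df$affected <- parse_flag(df$affected)
  class(df) <- c("simulation_truth", "data.frame")
  df
}

as_pipeline_config <- function(config) {
  if (inherits(config, "pipeline_config")) config else pipeline_config(config)
}

#' Command-line entry point
#'
#' Dispatches `longiprot <normalize|screen|simulate|evaluate> <config.yaml>`
#' to the corresponding `cmd_*` function. Used by the shipped Rscript at
#' `system.file("cli", "longiprot.R", package = "longiprot")`.
#'
#' @param args character vector of command-line arguments.
#' @return 0 on success (integer exit status); errors propagate to the
#'   caller, which the CLI script converts to a nonzero exit.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: longiprot <normalize|screen|simulate|evaluate> <config.yaml>"
  if (length(args) != 2) stop(usage, call. = FALSE)
  cmd <- switch(args[1],
                normalize = cmd_normalize,
                screen = cmd_screen,
                simulate = cmd_simulate,
                evaluate = cmd_evaluate,
                stop(usage, call. = FALSE))
  cmd(pipeline_config(args[2]))
  0L
}
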