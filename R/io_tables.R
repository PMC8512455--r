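#' Read a wide protein-intensity table
#'
#' Two dialects are supported. `generic_wide`: first column protein accession,
#' optional second column gene symbol (recognized by a header of
#' `gene_symbol`, `gene_symbols`, `gene`, or `Gene names`), all remaining
#' columns one sample each. `maxquant_protein_groups`: a MaxQuant
#' proteinGroups-style export with `Intensity <sample>` columns and `+` flags
#' in `Reverse` / `Potential contaminant`; flagged rows are tagged, not
#' removed.
#'
#' Empty cells and `NA` are missing. On the raw scale a stored `0` is treated
#' as missing (the search-engine convention for "not quantified"); a
#' `# scale: log2` marker line written by [write_intensity_table()] switches
#' the ingest to log2 semantics, where 0 is a real value.
#'
#' @param path path to a tab-separated file.
#' @param dialect `"generic_wide"` or `"maxquant_protein_groups"`.
#' @param zero_as_missing override zero handling for raw-scale generic tables
#'   (e.g. non-MS matrices in which 0 is a measured value).
#' @return An [intensity_table()] on the scale declared by the file (raw
#'   unless marked log2).
#' @export
read_intensity_table <- function(path,
                                 dialect = c("generic_wide",
                                             "maxquant_protein_groups"),
                                 zero_as_missing = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("intensity table not found: ", path)
  first <- readLines(path, n = 1L)
  scale <- "raw"
  if (grepl("^#\\s*scale:", first)) {
    scale <- trimws(sub("^#\\s*scale:", "", first))
    if (!scale %in% c("raw", "log2")) stop("unknown scale marker: ", scale)
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "#",
                          colClasses = "character")
  if (dialect == "generic_wide") {
    parse_generic_wide(df, scale, zero_as_missing)
  } else {
    parse_maxquant(df, zero_as_missing)
  }
}

gene_col_names <- c("gene_symbol", "gene_symbols", "gene", "Gene names")

parse_generic_wide <- function(df, scale, zero_as_missing) {
  if (ncol(df) < 2) stop("no intensity columns found")
  protein_ids <- df[[1]]
  start <- 2L
  gene_symbols <- NULL
  if (ncol(df) >= 2 && names(df)[2] %in% gene_col_names) {
    gene_symbols <- df[[2]]
    start <- 3L
  }
  if (ncol(df) < start) stop("no intensity columns found")
  values <- numeric_matrix(df[, start:ncol(df), drop = FALSE])
  intensity_table(values, protein_ids = protein_ids,
                  gene_symbols = gene_symbols, scale = scale,
                  zero_as_missing = zero_as_missing)
}

parse_maxquant <- function(df, zero_as_missing) {
  id_col <- intersect(c("Majority protein IDs", "Protein IDs"), names(df))
  if (length(id_col) == 0) {
    stop("maxquant dialect requires a 'Majority protein IDs' or ",
         "'Protein IDs' column")
  }
  protein_ids <- df[[id_col[1]]]
  gene_symbols <- if ("Gene names" %in% names(df)) df[["Gene names"]]
  # per-sample intensities are 'Intensity <sample>'; plain 'Intensity' is the
  # summed column and is not a sample
  int_cols <- grep("^Intensity .+", names(df), value = TRUE)
  if (length(int_cols) == 0) stop("no intensity columns found")
  values <- numeric_matrix(df[, int_cols, drop = FALSE])
  colnames(values) <- sub("^Intensity ", "", int_cols)
  contaminant <- rep(FALSE, nrow(df))
  for (flag_col in c("Potential contaminant", "Contaminant", "Reverse")) {
    if (flag_col %in% names(df)) {
      contaminant <- contaminant | trimws(df[[flag_col]]) == "+"
    }
  }
  intensity_table(values, protein_ids = protein_ids,
                  gene_symbols = gene_symbols, scale = "raw",
                  contaminant = contaminant,
                  zero_as_missing = zero_as_missing)
}

numeric_matrix <- function(char_df) {
  out <- matrix(NA_real_, nrow(char_df), ncol(char_df),
                dimnames = list(NULL, names(char_df)))
  for (j in seq_along(char_df)) {
    x <- trimws(char_df[[j]])
    empty <- is.na(x) | x == "" | x == "NA" | x == "NaN"
    conv <- suppressWarnings(as.numeric(x))
    bad <- !empty & is.na(conv)
    if (any(bad)) {
      i <- which(bad)[1]
      stop("non-numeric cell '", x[i], "' at row ", i,
           ", column '", names(char_df)[j], "'")
    }
    out[, j] <- conv
  }
  out
}

#' Write a protein-intensity table as TSV
#'
#' Emits a `# scale: <raw|log2>` marker line followed by the generic wide
#' layout (`protein_id`, `gene_symbol`, one column per sample), so
#' [read_intensity_table()] round-trips values, missing mask, and ids.
#' Missing values are written as empty cells.
#'
#' @param table an `intensity_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(table, path) {
  stopifnot(inherits(table, "intensity_table"))
  df <- data.frame(protein_id = table$protein_ids,
                   gene_symbol = table$gene_symbols,
                   check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.data.frame(table$values, check.names = FALSE)
  df <- cbind(df, vals)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# scale: ", table$scale), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Load protein-exclusion rules for an assay
#'
#' Exclusion lists live in an editable YAML config, shipped at
#' `system.file("extdata", "exclusion_rules.yaml", package = "longiprot")`.
#' The shipped accession lists for albumin, serotransferrin, and
#' immunoglobulins are a configurable stand-in (mouse UniProt accessions),
#' not a reconstruction of any specific search database; edit the file to
#' match your own database. Serum rules drop contaminants, albumin,
#' serotransferrin, and IgGs (depletion-dependent intensities); sEV rules
#' drop albumin and IgGs only (isolation-efficiency-dependent).
#'
#' @param assay one of `serum_tmt`, `sev_lfq`, `csf_lfq`.
#' @param config_path path to a rules YAML; defaults to the shipped file.
#' @return A list of class `exclusion_rules` with `assay`,
#'   `excluded_accessions` (named by accession, value = reason),
#'   `drop_contaminants`, and `contaminant_prefix`.
#' @export
exclusion_rules <- function(assay = c("serum_tmt", "sev_lfq", "csf_lfq"),
                            config_path = system.file(
                              "extdata", "exclusion_rules.yaml",
                              package = "longiprot")) {
  assay <- match.arg(assay)
  cfg <- yaml::read_yaml(config_path)
  rule <- cfg$rules[[assay]]
  if (is.null(rule)) stop("no exclusion rule configured for assay ", assay)
  acc <- character(0)
  for (cat_name in rule$exclude_categories) {
    ids <- cfg$accessions[[cat_name]]
    if (is.null(ids)) stop("unknown accession category: ", cat_name)
    reason <- rule$reason %||% "excluded by rule"
    add <- stats::setNames(rep(reason, length(ids)), unlist(ids))
    acc <- c(acc, add)
  }
  structure(
    list(assay = assay,
         excluded_accessions = acc,
         drop_contaminants = isTRUE(rule$drop_contaminants),
         contaminant_prefix = cfg$contaminant_prefix %||% "CON__"),
    class = "exclusion_rules"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove excluded proteins from a table
#'
#' Drops rows whose accession matches the rule's exclusion list (any
#' semicolon-separated member of a protein-group id counts), rows carrying a
#' contaminant tag, and rows whose id bears the configured contaminant prefix
#' — per the assay's rule. Retained rows are untouched.
#'
#' @param table an `intensity_table`.
#' @param rules an [exclusion_rules()] object.
#' @return A list with `table` (filtered `intensity_table`) and `log`
#'   (data.frame of `accession`, `reason` for each removed row).
#' @export
exclude_proteins <- function(table, rules) {
  stopifnot(inherits(table, "intensity_table"),
            inherits(rules, "exclusion_rules"))
  ids <- table$protein_ids
  reason <- rep(NA_character_, length(ids))
  excl_ids <- names(rules$excluded_accessions)
  for (i in seq_along(ids)) {
    members <- strsplit(ids[i], ";", fixed = TRUE)[[1]]
    if (rules$drop_contaminants &&
        (table$contaminant[i] ||
           any(startsWith(members, rules$contaminant_prefix)))) {
      reason[i] <- "contaminant"
    } else {
      hit <- match(members, excl_ids)
      hit <- hit[!is.na(hit)]
      if (length(hit) > 0) reason[i] <- rules$excluded_accessions[[hit[1]]]
    }
  }
  drop <- !is.na(reason)
  log <- data.frame(accession = ids[drop], reason = reason[drop],
                    stringsAsFactors = FALSE)
  out <- subset_proteins(table, !drop)
  if (nrow(out$values) == 0) {
    warning("all proteins were excluded; table is empty")
  }
  list(table = out, log = log)
}

#' Write an exclusion log as TSV
#'
#' @param log the `log` component returned by [exclude_proteins()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
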