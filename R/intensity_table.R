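#' Protein intensity table
#'
#' The central container of the package: a protein x sample matrix of
#' intensities with an implicit missing-value mask (`NA`), carried gene
#' symbols, and a scale flag distinguishing raw (linear, nonnegative)
#' intensities from log2-transformed ones.
#'
#' @param values numeric matrix, proteins in rows, samples in columns.
#'   `NA` marks a missing (invalid) value. On the raw scale, stored zeros are
#'   converted to missing unless `zero_as_missing = FALSE`.
#' @param protein_ids character vector of unique protein accessions, one per
#'   row of `values`.
#' @param gene_symbols optional character vector of gene symbols aligned with
#'   `protein_ids`; may contain duplicates or empty strings.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   column of `values`.
#' @param scale `"raw"` or `"log2"`.
#' @param contaminant optional logical vector flagging rows marked as
#'   contaminants by the upstream search engine (flag only; rows are not
#'   removed here).
#' @param zero_as_missing treat raw-scale zeros as missing (the convention of
#'   label-free search-engine exports, where 0 means "not quantified").
#'
#' @return An object of class `intensity_table`.
#' @export
intensity_table <- function(values, protein_ids, gene_symbols = NULL,
                            sample_ids = colnames(values),
                            scale = c("raw", "log2"),
                            contaminant = NULL,
                            zero_as_missing = TRUE) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) {
    stop("sample_ids must be supplied (or values must have column names)")
  }
  if (length(protein_ids) != nrow(values)) {
    stop("protein_ids length (", length(protein_ids),
         ") does not match row count (", nrow(values), ")")
  }
  if (length(sample_ids) != ncol(values)) {
    stop("sample_ids length does not match column count")
  }
  dup <- unique(protein_ids[duplicated(protein_ids)])
  if (length(dup) > 0) {
    stop("duplicate protein accessions: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (is.null(gene_symbols)) gene_symbols <- rep("", length(protein_ids))
  if (length(gene_symbols) != length(protein_ids)) {
    stop("gene_symbols length does not match protein_ids")
  }
  if (is.null(contaminant)) contaminant <- rep(FALSE, length(protein_ids))
  if (scale == "raw") {
    if (zero_as_missing) values[!is.na(values) & values == 0] <- NA_real_
    if (any(values < 0, na.rm = TRUE)) {
      stop("raw-scale intensities must be nonnegative")
    }
    if (any(!is.finite(values[!is.na(values)]))) {
      stop("raw-scale intensities must be finite or missing")
    }
  } else {
    if (any(!is.finite(values[!is.na(values)]))) {
      stop("log2-scale intensities must be finite or missing")
    }
  }
  dimnames(values) <- list(protein_ids, sample_ids)
  structure(
    list(values = values,
         protein_ids = as.character(protein_ids),
         gene_symbols = as.character(gene_symbols),
         sample_ids = as.character(sample_ids),
         scale = scale,
         contaminant = as.logical(contaminant)),
    class = "intensity_table"
  )
}

#' @export
print.intensity_table <- function(x, ...) {
  n_obs <- sum(!is.na(x$values))
  cat(sprintf("intensity_table: %d proteins x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  observed values: %d (%.1f%%), missing: %d\n",
              n_obs, 100 * n_obs / length(x$values),
              sum(is.na(x$values))))
  if (any(x$contaminant)) {
    cat(sprintf("  contaminant-flagged rows: %d\n", sum(x$contaminant)))
  }
  invisible(x)
}

#' @export
dim.intensity_table <- function(x) dim(x$values)

#' Subset an intensity table by protein row index or accession
#'
#' @param table an `intensity_table`.
#' @param i integer, logical, or character (accession) row index.
#' @return The subset `intensity_table`.
#' @export
subset_proteins <- function(table, i) {
  stopifnot(inherits(table, "intensity_table"))
  if (is.character(i)) i <- match(i, table$protein_ids)
  if (is.logical(i)) i <- which(i)
  intensity_table(table$values[i, , drop = FALSE],
                  protein_ids = table$protein_ids[i],
                  gene_symbols = table$gene_symbols[i],
                  sample_ids = table$sample_ids,
                  scale = table$scale,
                  contaminant = table$contaminant[i],
                  zero_as_missing = FALSE)
}

#' Subset an intensity table by sample
#'
#' @param table an `intensity_table`.
#' @param j integer, logical, or character (sample id) column index.
#' @return The subset `intensity_table`.
#' @export
subset_samples <- function(table, j) {
  stopifnot(inherits(table, "intensity_table"))
  if (is.character(j)) j <- match(j, table$sample_ids)
  if (is.logical(j)) j <- which(j)
  intensity_table(table$values[, j, drop = FALSE],
                  protein_ids = table$protein_ids,
                  gene_symbols = table$gene_symbols,
                  sample_ids = table$sample_ids[j],
                  scale = table$scale,
                  contaminant = table$contaminant,
                  zero_as_missing = FALSE)
}
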