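#' Within-set TMT loading normalization
#'
#' Corrects per-channel loading differences inside each TMT set: every
#' channel's observed intensities are multiplied by
#' (mean over the set's channels of total observed intensity) / (that
#' channel's total observed intensity). Afterwards all channel totals within
#' a set are equal. Totals use observed values only; missing entries are
#' untouched. The transform is idempotent and invariant to any positive
#' per-channel rescaling of the input.
#'
#' @param table raw-scale `intensity_table`.
#' @param annotation `sample_annotation`; every sample of the table must carry
#'   a TMT set.
#' @return A list with `table` (normalized) and `report` (data.frame of
#'   `tmt_set`, `sample_id`, `tmt_channel`, `total_before`, `factor`).
#' @export
tmt_within_set_normalize <- function(table, annotation) {
  stopifnot(inherits(table, "intensity_table"))
  if (table$scale != "raw") stop("within-set normalization expects raw scale")
  ann <- align_annotation(table, annotation)
  if (anyNA(ann$tmt_set)) {
    stop("sample(s) without TMT set: ",
         paste(ann$sample_id[is.na(ann$tmt_set)], collapse = ", "))
  }
  values <- table$values
  totals <- colSums(values, na.rm = TRUE)
  n_obs <- colSums(!is.na(values))
  if (any(n_obs == 0 | totals <= 0)) {
    stop("channel(s) with zero total observed intensity: ",
         paste(table$sample_ids[n_obs == 0 | totals <= 0], collapse = ", "))
  }
  factors <- numeric(ncol(values))
  for (s in unique(ann$tmt_set)) {
    j <- which(ann$tmt_set == s)
    factors[j] <- mean(totals[j]) / totals[j]
  }
  values <- sweep(values, 2, factors, `*`)
  report <- data.frame(tmt_set = ann$tmt_set,
                       sample_id = ann$sample_id,
                       tmt_channel = ann$tmt_channel,
                       total_before = unname(totals),
                       factor = factors,
                       stringsAsFactors = FALSE)
  list(table = replace_values(table, values), report = report)
}

#' Between-set TMT normalization via pooled reference channels
#'
#' Equalizes each protein across TMT sets using the pooled-reference
#' channels: for protein p and set s, `ref(p,s)` is the arithmetic mean of
#' p's observed intensities in s's reference channels, and every value of p
#' in set s is multiplied by `mean_s ref(p, .) / ref(p, s)`. Afterwards the
#' reference average of a fully observed protein is identical across sets.
#' Reference averaging operates on raw (pre-log) intensities, after
#' within-set loading normalization.
#'
#' A protein with no observed reference value in some set cannot be
#' calibrated for that set: its values there are set to missing and the
#' (protein, set) pair is reported, so calibrated and uncalibrated values
#' never mix within one protein.
#'
#' @param table raw-scale `intensity_table`, already within-set normalized.
#' @param annotation `sample_annotation` with `is_reference_pool` flags;
#'   every set needs at least one reference channel.
#' @return A list with `table`, `report` (data.frame `protein_id`, `tmt_set`,
#'   `ref_mean`, `factor`), and `uncalibratable` (data.frame `protein_id`,
#'   `tmt_set` of pairs made missing).
#' @export
tmt_between_set_normalize <- function(table, annotation) {
  stopifnot(inherits(table, "intensity_table"))
  if (table$scale != "raw") stop("between-set normalization expects raw scale")
  ann <- align_annotation(table, annotation)
  sets <- sort(unique(ann$tmt_set))
  if (anyNA(ann$tmt_set)) stop("sample(s) without TMT set")
  for (s in sets) {
    if (!any(ann$is_reference_pool & ann$tmt_set == s)) {
      stop("TMT set ", s, " has no reference-pool channel")
    }
  }
  values <- table$values
  n_prot <- nrow(values)
  ref_mean <- matrix(NA_real_, n_prot, length(sets),
                     dimnames = list(table$protein_ids, sets))
  for (si in seq_along(sets)) {
    j <- which(ann$is_reference_pool & ann$tmt_set == sets[si])
    ref_mean[, si] <- rowMeans(values[, j, drop = FALSE], na.rm = TRUE)
  }
  ref_mean[is.nan(ref_mean)] <- NA_real_
  grand <- rowMeans(ref_mean, na.rm = TRUE)   # over sets with an observed ref
  factor_mat <- grand / ref_mean              # NA where uncalibratable
  uncal <- which(is.na(ref_mean), arr.ind = TRUE)
  for (si in seq_along(sets)) {
    j <- which(ann$tmt_set == sets[si])
    values[, j] <- values[, j, drop = FALSE] * factor_mat[, si]
  }
  report <- data.frame(
    protein_id = rep(table$protein_ids, times = length(sets)),
    tmt_set = rep(sets, each = n_prot),
    ref_mean = as.vector(ref_mean),
    factor = as.vector(factor_mat),
    stringsAsFactors = FALSE)
  uncalibratable <- data.frame(
    protein_id = table$protein_ids[uncal[, 1]],
    tmt_set = sets[uncal[, 2]],
    stringsAsFactors = FALSE)
  list(table = replace_values(table, values),
       report = report,
       uncalibratable = uncalibratable)
}

#' Missing-aware log2 transform
#'
#' @param table raw-scale `intensity_table` with strictly positive observed
#'   values.
#' @return The table on the log2 scale; missing entries stay missing.
#' @export
log2_missing_aware <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  if (table$scale != "raw") stop("table is already on the log2 scale")
  values <- table$values
  if (any(values <= 0, na.rm = TRUE)) {
    stop("observed nonpositive intensity; cannot log2-transform")
  }
  replace_values(table, log2(values), scale = "log2")
}

#' Per-sample median centering
#'
#' Subtracts each sample's median over observed log2 intensities, so every
#' sample's observed median becomes 0. Idempotent. Samples with no observed
#' value are left unchanged with a warning.
#'
#' @param table log2-scale `intensity_table`.
#' @return A list with `table` and `report` (data.frame `sample_id`,
#'   `median_subtracted`).
#' @export
median_center <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  if (table$scale != "log2") stop("median centering expects log2 scale")
  values <- table$values
  meds <- apply(values, 2, stats::median, na.rm = TRUE)
  empty <- !is.finite(meds)
  if (any(empty)) {
    warning("sample(s) with no observed values left unchanged: ",
            paste(table$sample_ids[empty], collapse = ", "))
    meds[empty] <- 0
  }
  values <- sweep(values, 2, meds, `-`)
  report <- data.frame(sample_id = table$sample_ids,
                       median_subtracted = unname(meds),
                       stringsAsFactors = FALSE)
  list(table = replace_values(table, values), report = report)
}

#' PCA quality-control scores
#'
#' Sample scores on the leading principal components, computed from
#' complete-case proteins (no missing value in any sample), per-protein
#' mean-centered, unscaled. Used to check that pooled reference samples
#' cluster together after normalization and that the leading component no
#' longer separates TMT sets. Deterministic up to component sign.
#'
#' @param table log2-scale `intensity_table`.
#' @param annotation `sample_annotation`.
#' @param n_components number of leading components to return.
#' @return A data.frame with `sample_id`, `timepoint`, `is_reference_pool`,
#'   `tmt_set`, and one `PC<k>` column per component; the proportion of
#'   variance explained is attached as attribute `var_explained`.
#' @export
pca_qc_scores <- function(table, annotation, n_components = 2) {
  stopifnot(inherits(table, "intensity_table"))
  if (table$scale != "log2") stop("PCA QC expects log2 scale")
  ann <- align_annotation(table, annotation)
  complete <- rowSums(is.na(table$values)) == 0
  if (!any(complete)) stop("no complete-case proteins for PCA")
  x <- t(table$values[complete, , drop = FALSE])  # samples x proteins
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- as.data.frame(pc$x[, seq_len(k), drop = FALSE])
  names(scores) <- paste0("PC", seq_len(k))
  out <- cbind(data.frame(sample_id = table$sample_ids,
                          timepoint = ann$timepoint,
                          is_reference_pool = ann$is_reference_pool,
                          tmt_set = ann$tmt_set,
                          stringsAsFactors = FALSE),
               scores)
  attr(out, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  out
}

replace_values <- function(table, values, scale = table$scale) {
  intensity_table(values,
                  protein_ids = table$protein_ids,
                  gene_symbols = table$gene_symbols,
                  sample_ids = table$sample_ids,
                  scale = scale,
                  contaminant = table$contaminant,
                  zero_as_missing = FALSE)
}
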