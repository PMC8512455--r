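#' Valid-value eligibility rules
#'
#' Per-dataset rules deciding which proteins enter the longitudinal model:
#' `serum_rule` needs at least 4 valid values per time point, `sev_rule` at
#' least 3 per time point, `csf_rule` a valid value in every collected
#' (non-reference) sample. Reference-pool channels never count as
#' observations.
#'
#' @param name `serum_rule`, `sev_rule`, or `csf_rule`.
#' @param min_valid_per_timepoint override the per-time-point minimum of the
#'   serum/sEV rules (ignored for the complete-case CSF rule).
#' @return A list of class `eligibility_rule`.
#' @export
eligibility_rule <- function(name = c("serum_rule", "sev_rule", "csf_rule"),
                             min_valid_per_timepoint = NULL) {
  name <- match.arg(name)
  defaults <- c(serum_rule = 4L, sev_rule = 3L)
  all_samples <- name == "csf_rule"
  min_valid <- if (all_samples) NA_integer_
               else if (!is.null(min_valid_per_timepoint))
                 as.integer(min_valid_per_timepoint)
               else defaults[[name]]
  structure(list(name = name,
                 min_valid_per_timepoint = min_valid,
                 all_samples_required = all_samples,
                 assay = c(serum_rule = "serum_tmt", sev_rule = "sev_lfq",
                           csf_rule = "csf_lfq")[[name]]),
            class = "eligibility_rule")
}

#' Per-protein valid-value counts by time point
#'
#' Counts observed (non-missing) values per time point for each protein,
#' over non-reference samples only. Mice missing a whole time point simply
#' contribute no count there.
#'
#' @param table `intensity_table` (any scale).
#' @param annotation `sample_annotation`.
#' @return Integer matrix, proteins x time points (baseline, T1, T2).
#' @export
valid_counts <- function(table, annotation) {
  stopifnot(inherits(table, "intensity_table"))
  ann <- align_annotation(table, annotation)
  bio <- !ann$is_reference_pool
  counts <- sapply(TIMEPOINT_LEVELS, function(tp) {
    j <- which(bio & ann$timepoint == tp)
    rowSums(!is.na(table$values[, j, drop = FALSE]))
  })
  counts <- matrix(as.integer(counts), nrow = nrow(table$values),
                   dimnames = list(table$protein_ids, TIMEPOINT_LEVELS))
  counts
}

#' Apply an eligibility rule to every protein
#'
#' @param table `intensity_table`.
#' @param annotation `sample_annotation`.
#' @param rule an [eligibility_rule()]; its assay must match the samples'.
#' @return A data.frame with one row per protein: `protein_id`, per-time-point
#'   valid counts (`n_baseline`, `n_T1`, `n_T2`), `eligible`, `reason`.
#' @export
select_eligible <- function(table, annotation, rule) {
  stopifnot(inherits(rule, "eligibility_rule"))
  ann <- align_annotation(table, annotation)
  assays <- unique(ann$assay)
  if (!identical(assays, rule$assay)) {
    stop("rule ", rule$name, " expects assay ", rule$assay,
         " but annotation has: ", paste(assays, collapse = ", "))
  }
  counts <- valid_counts(table, annotation)
  if (rule$all_samples_required) {
    bio <- !ann$is_reference_pool
    n_bio <- sum(bio)
    eligible <- rowSums(!is.na(table$values[, bio, drop = FALSE])) == n_bio
  } else {
    eligible <- apply(counts >= rule$min_valid_per_timepoint, 1, all)
  }
  data.frame(protein_id = table$protein_ids,
             n_baseline = counts[, "baseline"],
             n_T1 = counts[, "T1"],
             n_T2 = counts[, "T2"],
             eligible = unname(eligible),
             reason = ifelse(eligible, "", "insufficient valid values"),
             row.names = NULL,
             stringsAsFactors = FALSE)
}
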