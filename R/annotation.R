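TIMEPOINT_LEVELS <- c("baseline", "T1", "T2")
ASSAY_LEVELS <- c("serum_tmt", "sev_lfq", "csf_lfq")

#' Build and validate a sample-annotation table
#'
#' One row per sample. TMT samples must carry a set and channel; pooled
#' reference channels occur only within TMT sets and are flagged with
#' `is_reference_pool`. Among non-reference samples of one assay, each
#' (mouse, time point) pair may occur at most once.
#'
#' @param df data.frame with columns `sample_id`, `mouse_id`, `timepoint`
#'   (one of baseline/T1/T2), `assay` (serum_tmt/sev_lfq/csf_lfq), and
#'   optionally `tmt_set`, `tmt_channel`, `is_reference_pool`.
#' @return A validated data.frame of class `sample_annotation`.
#' @export
sample_annotation <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("sample_id", "mouse_id", "timepoint", "assay")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("annotation is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"tmt_set" %in% names(df)) df$tmt_set <- NA_integer_
  if (!"tmt_channel" %in% names(df)) df$tmt_channel <- NA_character_
  if (!"is_reference_pool" %in% names(df)) df$is_reference_pool <- FALSE
  df$sample_id <- as.character(df$sample_id)
  df$mouse_id <- as.character(df$mouse_id)
  df$timepoint <- as.character(df$timepoint)
  df$assay <- as.character(df$assay)
  df$tmt_set <- suppressWarnings(as.integer(df$tmt_set))
  df$tmt_channel <- as.character(df$tmt_channel)
  df$is_reference_pool <- parse_flag(df$is_reference_pool)

  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  bad_tp <- setdiff(unique(df$timepoint[!df$is_reference_pool]),
                    TIMEPOINT_LEVELS)
  if (length(bad_tp) > 0) {
    stop("unknown timepoint label(s): ", paste(bad_tp, collapse = ", "),
         " (expected ", paste(TIMEPOINT_LEVELS, collapse = "/"), ")")
  }
  bad_assay <- setdiff(unique(df$assay), ASSAY_LEVELS)
  if (length(bad_assay) > 0) {
    stop("unknown assay label(s): ", paste(bad_assay, collapse = ", "))
  }
  is_tmt <- df$assay == "serum_tmt"
  no_set <- is_tmt & (is.na(df$tmt_set) | is.na(df$tmt_channel) |
                        df$tmt_channel == "")
  if (any(no_set)) {
    stop("TMT sample(s) without tmt_set/tmt_channel: ",
         paste(df$sample_id[no_set], collapse = ", "))
  }
  if (any(df$is_reference_pool & !is_tmt)) {
    stop("reference-pool flag set on non-TMT sample(s): ",
         paste(df$sample_id[df$is_reference_pool & !is_tmt], collapse = ", "))
  }
  bio <- df[!df$is_reference_pool, , drop = FALSE]
  key <- paste(bio$assay, bio$mouse_id, bio$timepoint)
  if (anyDuplicated(key)) {
    stop("duplicated (mouse, timepoint) among non-reference samples: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  class(df) <- c("sample_annotation", "data.frame")
  df
}

parse_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(trimws(as.character(x)))
  x %in% c("true", "t", "1", "yes", "+")
}

#' Read a sample-annotation table from a tab-separated file
#'
#' @param path path to a TSV with header; required columns as in
#'   [sample_annotation()].
#' @return A validated `sample_annotation` data.frame.
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "#")
  sample_annotation(df)
}

#' Write a sample-annotation table as TSV
#'
#' @param annotation a `sample_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_annotation <- function(annotation, path) {
  utils::write.table(as.data.frame(annotation), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict annotation rows to those matching a table's samples, in order
#' @noRd
align_annotation <- function(table, annotation) {
  idx <- match(table$sample_ids, annotation$sample_id)
  if (anyNA(idx)) {
    stop("samples absent from annotation: ",
         paste(table$sample_ids[is.na(idx)], collapse = ", "))
  }
  annotation[idx, , drop = FALSE]
}
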