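TMT10_CHANNELS <- c("126", "127N", "127C", "128N", "128C",
                    "129N", "129C", "130N", "130C", "131")

#' Simulation configuration
#'
#' Describes a synthetic longitudinal proteomics study generated directly
#' from the screening model: per-protein log2 baseline abundance, per-mouse
#' random intercepts, categorical time effects (log2 fold changes vs
#' baseline), and Gaussian residual noise, with optional TMT plumbing
#' (10-plex sets, two pooled-reference channels per set, per-channel loading
#' factors, per-set offsets) and missingness (MCAR, intensity-dependent
#' MNAR, whole missing visits). The seed fully determines the output.
#'
#' Affected proteins receive a T2 effect drawn uniformly from
#' `effect_range_T2` in absolute value with random sign, and a T1 effect
#' equal to `effect_T1_scale` times the T2 effect — the pre-symptomatic
#' change smaller than the symptomatic one, as longitudinal disease
#' progression typically shows. Noise SDs default to 0.5 log2 units for both
#' components; these are generic placeholders for biofluid MS data, not
#' estimates from any particular study.
#'
#' @param seed integer RNG seed.
#' @param n_mice number of animals (default 6).
#' @param n_proteins number of proteins.
#' @param prop_affected proportion of proteins with a true time effect;
#'   exactly `round(prop_affected * n_proteins)` are affected.
#' @param effect_range_T2 range of |beta(T2)| for affected proteins (log2).
#' @param effect_sign `"both"` (random sign per protein) or `"positive"`.
#' @param effect_T1_scale beta(T1) = scale * beta(T2).
#' @param sigma_mouse SD of the per-mouse random intercept (log2 units).
#' @param sigma_resid residual SD (log2 units).
#' @param baseline_range range of per-protein baseline log2 abundance.
#' @param mcar_rate probability of completely-random dropout per value.
#' @param mnar_threshold log2 intensity below which intensity-dependent
#'   dropout ramps up (`NA` disables MNAR).
#' @param mnar_steepness steepness of the logistic dropout probability
#'   `plogis((threshold - x) * steepness)`.
#' @param missing_visits data.frame with columns `mouse_id`, `timepoint`:
#'   visits that never happened; their samples are dropped entirely.
#' @param design `"label_free"` or `"tmt"`.
#' @param assay assay label written into the annotation.
#' @param channels_per_set,refs_per_set TMT set geometry (10-plex, 2 pooled
#'   references by default).
#' @param loading_sd SD (log2) of per-channel loading factors.
#' @param set_offset_sd SD (log2) of per-set multiplicative offsets.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_mice = 6L,
                              n_proteins = 100L,
                              prop_affected = 0.1,
                              effect_range_T2 = c(0.5, 2),
                              effect_sign = c("both", "positive"),
                              effect_T1_scale = 0.5,
                              sigma_mouse = 0.5,
                              sigma_resid = 0.5,
                              baseline_range = c(20, 30),
                              mcar_rate = 0,
                              mnar_threshold = NA_real_,
                              mnar_steepness = 1,
                              missing_visits = NULL,
                              design = c("label_free", "tmt"),
                              assay = NULL,
                              channels_per_set = 10L,
                              refs_per_set = 2L,
                              loading_sd = 0.2,
                              set_offset_sd = 0.5) {
  design <- match.arg(design)
  effect_sign <- match.arg(effect_sign)
  if (is.null(assay)) {
    assay <- if (design == "tmt") "serum_tmt" else "sev_lfq"
  }
  stopifnot(sigma_mouse >= 0, sigma_resid >= 0,
            prop_affected >= 0, prop_affected <= 1,
            mcar_rate >= 0, mcar_rate <= 1, n_mice >= 2, n_proteins >= 1)
  if (design == "tmt") {
    if (assay != "serum_tmt") stop("TMT design requires assay serum_tmt")
    if (refs_per_set >= channels_per_set) {
      stop("inconsistent TMT config: refs_per_set must leave room for ",
           "biological channels")
    }
  }
  if (!is.null(missing_visits)) {
    missing_visits <- as.data.frame(missing_visits,
                                    stringsAsFactors = FALSE)
    stopifnot(all(c("mouse_id", "timepoint") %in% names(missing_visits)))
  }
  structure(
    list(seed = as.integer(seed), n_mice = as.integer(n_mice),
         timepoints = TIMEPOINT_LEVELS,
         n_proteins = as.integer(n_proteins),
         prop_affected = prop_affected,
         effect_range_T2 = effect_range_T2,
         effect_sign = effect_sign,
         effect_T1_scale = effect_T1_scale,
         sigma_mouse = sigma_mouse, sigma_resid = sigma_resid,
         baseline_range = baseline_range,
         mcar_rate = mcar_rate, mnar_threshold = mnar_threshold,
         mnar_steepness = mnar_steepness,
         missing_visits = missing_visits,
         design = design, assay = assay,
         channels_per_set = as.integer(channels_per_set),
         refs_per_set = as.integer(refs_per_set),
         loading_sd = loading_sd, set_offset_sd = set_offset_sd),
    class = "simulation_config")
}

#' Named study-design presets
#'
#' `serum6x3`: 6 mice x 3 time points, TMT 10-plex sets with two pooled
#' reference channels each. `sev6x3`: 6 mice, label-free, one mouse missing
#' T2 and a different mouse missing baseline. `csf5`: 5 mice, label-free,
#' three mice missing T2 and one mouse missing both baseline and T1 —
#' the visit structures of repeated serum/vesicle/CSF sampling in
#' tumor-bearing mice.
#'
#' @param name preset name.
#' @param ... overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
simulation_preset <- function(name = c("serum6x3", "sev6x3", "csf5"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    serum6x3 = list(n_mice = 6L, design = "tmt", assay = "serum_tmt"),
    sev6x3 = list(
      n_mice = 6L, design = "label_free", assay = "sev_lfq",
      missing_visits = data.frame(mouse_id = c("m1", "m2"),
                                  timepoint = c("T2", "baseline"),
                                  stringsAsFactors = FALSE)),
    csf5 = list(
      n_mice = 5L, design = "label_free", assay = "csf_lfq",
      missing_visits = data.frame(
        mouse_id = c("m1", "m2", "m3", "m4", "m4"),
        timepoint = c("T2", "T2", "T2", "baseline", "T1"),
        stringsAsFactors = FALSE)))
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_config, args)
}

#' Simulate a longitudinal proteomics dataset with ground truth
#'
#' Generates log2 intensities exactly from the screening model
#' (baseline + mouse intercept + categorical time effect + Gaussian
#' residual), exponentiates to the raw scale, and — for TMT designs —
#' distributes samples over 10-plex sets, adds pooled-reference channels
#' whose expected value is the per-set average of the protein's biological
#' intensities, and injects per-channel loading factors and per-set offsets.
#' Mouse intercepts are drawn independently per (protein, mouse), matching
#' the per-protein model.
#'
#' Missingness is not applied here; pass the result through
#' [apply_missingness()].
#'
#' @param config a [simulation_config()].
#' @return A list with `table` (raw-scale `intensity_table`), `annotation`
#'   (`sample_annotation`), and `truth` (data.frame of class
#'   `simulation_truth`: per-protein `affected`, `beta_T1`, `beta_T2`, `mu`,
#'   with the per-mouse intercepts as attribute `mouse_intercepts` and, for
#'   TMT, injected `loading_factors` / `set_offsets` attributes).
#' @export
simulate_longitudinal <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  P <- config$n_proteins
  K <- config$n_mice
  mice <- paste0("m", seq_len(K))
  protein_ids <- sprintf("SIMP%04d", seq_len(P))
  gene_symbols <- sprintf("Simg%04d", seq_len(P))

  n_aff <- round(config$prop_affected * P)
  affected <- rep(FALSE, P)
  affected[sample.int(P, n_aff)] <- TRUE
  beta_T2 <- numeric(P)
  signs <- if (config$effect_sign == "positive") rep(1, n_aff)
           else sample(c(-1, 1), n_aff, replace = TRUE)
  beta_T2[affected] <- stats::runif(n_aff, config$effect_range_T2[1],
                                    config$effect_range_T2[2]) * signs
  beta_T1 <- config$effect_T1_scale * beta_T2
  mu <- stats::runif(P, config$baseline_range[1], config$baseline_range[2])
  u <- matrix(stats::rnorm(P * K, 0, config$sigma_mouse), P, K,
              dimnames = list(protein_ids, mice))

  grid <- expand.grid(mouse_id = mice, timepoint = config$timepoints,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$mouse_id, match(grid$timepoint,
                                          config$timepoints)), ]
  n_bio <- nrow(grid)
  eff <- rbind(baseline = 0, T1 = beta_T1, T2 = beta_T2)
  y <- mu + u[, grid$mouse_id] +
    t(eff[grid$timepoint, , drop = FALSE]) +
    matrix(stats::rnorm(P * n_bio, 0, config$sigma_resid), P, n_bio)

  truth <- data.frame(protein_id = protein_ids, gene_symbol = gene_symbols,
                      affected = affected, beta_T1 = beta_T1,
                      beta_T2 = beta_T2, mu = mu,
                      stringsAsFactors = FALSE)
  attr(truth, "mouse_intercepts") <- u
  class(truth) <- c("simulation_truth", "data.frame")

  if (config$design == "label_free") {
    sample_ids <- paste(grid$mouse_id, grid$timepoint, sep = "_")
    ann <- sample_annotation(data.frame(
      sample_id = sample_ids, mouse_id = grid$mouse_id,
      timepoint = grid$timepoint, assay = config$assay,
      stringsAsFactors = FALSE))
    raw <- 2^y
    colnames(raw) <- sample_ids
    table <- intensity_table(raw, protein_ids, gene_symbols, sample_ids,
                             scale = "raw")
    return(list(table = table, annotation = ann, truth = truth))
  }

  # TMT design: randomized assignment of biological samples to sets
  per_set <- config$channels_per_set - config$refs_per_set
  n_sets <- ceiling(n_bio / per_set)
  assignment <- sample(rep(seq_len(n_sets), length.out = n_bio))
  bio_channels <- TMT10_CHANNELS[seq_len(config$channels_per_set)]
  ref_channels <- utils::tail(bio_channels, config$refs_per_set)
  bio_channels <- setdiff(bio_channels, ref_channels)

  loading <- list()
  offsets <- 2^stats::rnorm(n_sets, 0, config$set_offset_sd)
  cols <- list()
  ann_rows <- list()
  for (s in seq_len(n_sets)) {
    in_set <- which(assignment == s)
    raw_bio <- 2^y[, in_set, drop = FALSE]
    set_avg <- rowMeans(raw_bio)
    ref_noise <- matrix(2^stats::rnorm(P * config$refs_per_set, 0,
                                       config$sigma_resid),
                        P, config$refs_per_set)
    raw_ref <- set_avg * ref_noise
    chans <- c(bio_channels[seq_along(in_set)], ref_channels)
    L <- 2^stats::rnorm(length(chans), 0, config$loading_sd)
    block <- cbind(raw_bio, raw_ref) * rep(L * offsets[s],
                                           each = P)
    ids <- paste0("set", s, "_", chans)
    colnames(block) <- ids
    loading[[s]] <- stats::setNames(L, ids)
    cols[[s]] <- block
    ann_rows[[s]] <- data.frame(
      sample_id = ids,
      mouse_id = c(grid$mouse_id[in_set],
                   rep("pool", config$refs_per_set)),
      timepoint = c(grid$timepoint[in_set],
                    rep("baseline", config$refs_per_set)),
      assay = config$assay,
      tmt_set = s,
      tmt_channel = chans,
      is_reference_pool = c(rep(FALSE, length(in_set)),
                            rep(TRUE, config$refs_per_set)),
      stringsAsFactors = FALSE)
  }
  raw <- do.call(cbind, cols)
  ann <- sample_annotation(do.call(rbind, ann_rows))
  table <- intensity_table(raw, protein_ids, gene_symbols,
                           colnames(raw), scale = "raw")
  attr(truth, "loading_factors") <- unlist(unname(loading))
  attr(truth, "set_offsets") <- offsets
  list(table = table, annotation = ann, truth = truth)
}

#' Inject missing values into a simulated table
#'
#' Applies, in order: whole-visit removal (all samples of the configured
#' (mouse, time point) pairs are dropped from table and annotation — those
#' visits never happened), MCAR deletion at `mcar_rate`, and
#' intensity-dependent (MNAR) deletion with probability
#' `plogis((threshold - log2(x)) * steepness)`.
#'
#' @param table `intensity_table` from [simulate_longitudinal()].
#' @param annotation matching `sample_annotation`.
#' @param config the `simulation_config`.
#' @return A list with the thinned `table` and `annotation`.
#' @export
apply_missingness <- function(table, annotation, config) {
  stopifnot(inherits(table, "intensity_table"),
            inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  ann <- align_annotation(table, annotation)
  if (!is.null(config$missing_visits) && nrow(config$missing_visits) > 0) {
    mv <- config$missing_visits
    drop <- paste(ann$mouse_id, ann$timepoint) %in%
      paste(mv$mouse_id, mv$timepoint) & !ann$is_reference_pool
    if (any(drop)) {
      table <- subset_samples(table, !drop)
      ann <- sample_annotation(ann[!drop, , drop = FALSE])
    }
  }
  values <- table$values
  obs <- which(!is.na(values))
  if (config$mcar_rate > 0) {
    del <- obs[stats::runif(length(obs)) < config$mcar_rate]
    values[del] <- NA_real_
  }
  if (!is.na(config$mnar_threshold)) {
    obs <- which(!is.na(values))
    x_log2 <- if (table$scale == "raw") log2(values[obs]) else values[obs]
    p_drop <- stats::plogis((config$mnar_threshold - x_log2) *
                              config$mnar_steepness)
    del <- obs[stats::runif(length(obs)) < p_drop]
    values[del] <- NA_real_
  }
  list(table = replace_values(table, values), annotation = ann)
}

#' Evaluate a screen against simulation truth
#'
#' @param result a `screen_result`.
#' @param truth the matching `simulation_truth`.
#' @return A list of metrics: `n_significant`, `fdp` (false discovery
#'   proportion; 0 when nothing is declared), `sensitivity` (recall among
#'   affected proteins; 0 when nothing is declared), per-coefficient `bias`
#'   and `rmse` over proteins with estimates, and `ci_coverage` (fraction of
#'   95\% intervals covering the true coefficient, pooled over T1 and T2).
#' @export
evaluate_screen <- function(result, truth) {
  stopifnot(inherits(result, "screen_result"),
            inherits(truth, "simulation_truth"))
  if (!setequal(result$protein_id, truth$protein_id)) {
    stop("result and truth protein ids do not match")
  }
  tr <- truth[match(result$protein_id, truth$protein_id), , drop = FALSE]
  sig <- result$significant
  n_sig <- sum(sig)
  fdp <- if (n_sig == 0) 0 else sum(sig & !tr$affected) / n_sig
  n_aff <- sum(tr$affected)
  sens <- if (n_aff == 0 || n_sig == 0) 0 else
    sum(sig & tr$affected) / n_aff
  est <- !is.na(result$beta_T2)
  bias_T1 <- mean(result$beta_T1[est] - tr$beta_T1[est])
  bias_T2 <- mean(result$beta_T2[est] - tr$beta_T2[est])
  rmse_T1 <- sqrt(mean((result$beta_T1[est] - tr$beta_T1[est])^2))
  rmse_T2 <- sqrt(mean((result$beta_T2[est] - tr$beta_T2[est])^2))
  cov_T1 <- result$ci_low_T1[est] <= tr$beta_T1[est] &
    tr$beta_T1[est] <= result$ci_high_T1[est]
  cov_T2 <- result$ci_low_T2[est] <= tr$beta_T2[est] &
    tr$beta_T2[est] <= result$ci_high_T2[est]
  list(n_significant = n_sig,
       fdp = fdp,
       sensitivity = sens,
       bias_T1 = bias_T1, bias_T2 = bias_T2,
       rmse_T1 = rmse_T1, rmse_T2 = rmse_T2,
       ci_coverage = mean(c(cov_T1, cov_T2)))
}
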