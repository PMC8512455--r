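#' Shapiro-Wilk normality gate
#'
#' A fit enters significance testing only if both its within-fit residuals
#' and its predicted per-mouse random intercepts look normal: Shapiro-Wilk
#' p > alpha on each. The random effects are assessed on their predictions
#' (empirical best predictions) since the latent effects themselves are not
#' observable. If a test cannot be computed (fewer than 3 values, or zero
#' variance — including fits whose random-intercept variance collapsed to
#' (numerically) zero so all predictions coincide), the gate is
#' `indeterminate` and the protein is excluded from testing downstream.
#'
#' @param fit a converged `protein_fit`.
#' @param alpha gate level (default 0.05).
#' @return A list of class `gate_result` with `shapiro_p_residuals`,
#'   `shapiro_p_mouse_effects`, and `status` in
#'   pass / fail_residuals / fail_random_effects / indeterminate.
#' @export
normality_gate <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "protein_fit"))
  if (!fit$converged) stop("normality gate requires a converged fit")
  p_res <- shapiro_p_or_na(fit$residuals)
  u <- fit$mouse_effects
  # predictions are effectively constant when the variance ratio collapsed
  if (fit$sigma2_mouse < 1e-8 * max(fit$sigma2_resid, .Machine$double.eps)) {
    p_ranef <- NA_real_
  } else {
    p_ranef <- shapiro_p_or_na(u)
  }
  status <- if (is.na(p_res) || is.na(p_ranef)) {
    "indeterminate"
  } else if (p_res <= alpha) {
    "fail_residuals"
  } else if (p_ranef <= alpha) {
    "fail_random_effects"
  } else {
    "pass"
  }
  structure(list(shapiro_p_residuals = p_res,
                 shapiro_p_mouse_effects = p_ranef,
                 status = status),
            class = "gate_result")
}

shapiro_p_or_na <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 5000) return(NA_real_)
  if (diff(range(x)) < .Machine$double.eps^0.5 * max(1, max(abs(x)))) {
    return(NA_real_)
  }
  out <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  out
}

#' Omnibus test of the time-point effects
#'
#' Tests H0: beta(T1) = beta(T2) = 0. The default is a Wald F-test: the
#' joint Wald statistic W on the time coefficients (with the bias-adjusted
#' coefficient covariance) referred to F(q, df) with containment denominator
#' df = n - rank(X) - (n_mice - 1). At this design's sizes (6 mice, 18
#' points) the F reference is essentially exact under the null, whereas the
#' chi-square reference ("wald_chisq") is markedly anti-conservative and the
#' ML likelihood-ratio chi-square ("lrt") moderately so; both remain
#' available for sensitivity analysis.
#'
#' @param fit a converged `protein_fit` with both time coefficients
#'   estimated.
#' @param variant `"wald_f"` (default), `"wald_chisq"`, or `"lrt"`.
#' @return The p-value, or `NA` if the coefficient covariance is singular
#'   (the protein is then flagged by the caller).
#' @export
omnibus_time_test <- function(fit, variant = c("wald_f", "wald_chisq",
                                               "lrt")) {
  variant <- match.arg(variant)
  stopifnot(inherits(fit, "protein_fit"))
  if (!fit$converged) stop("omnibus test requires a converged fit")
  est <- names(fit$beta)[!is.na(fit$beta)]
  if (length(est) == 0) return(NA_real_)
  if (variant == "lrt") {
    ll_full <- if (fit$method == "ML") fit$logLik else {
      fit_random_intercept_model(fit$data$y, fit$data$mouse,
                                 fit$data$timepoint, method = "ML")$logLik
    }
    ll0 <- fit_null_model(fit$data)
    lr <- max(0, 2 * (ll_full - ll0))
    return(stats::pchisq(lr, df = length(est), lower.tail = FALSE))
  }
  b <- fit$beta[est]
  V <- fit$vcov_beta[est, est, drop = FALSE]
  W <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) NA_real_)
  if (!is.finite(W) || W < 0) return(NA_real_)
  q <- length(est)
  if (variant == "wald_chisq") {
    stats::pchisq(W, df = q, lower.tail = FALSE)
  } else {
    stats::pf(W / q, q, fit$df_containment, lower.tail = FALSE)
  }
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector of p-values in [0, 1] (NA allowed;
#'   propagated).
#' @param fdr target false discovery rate (default 0.05).
#' @return A list with `q` (BH-adjusted p-values; ties share q-values) and
#'   `rejected` (logical, `q <= fdr`).
#' @export
bh_adjust <- function(pvalues, fdr = 0.05) {
  if (length(pvalues) == 0) {
    return(list(q = numeric(0), rejected = logical(0)))
  }
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, rejected = !is.na(q) & q <= fdr)
}

#' Run the full per-protein longitudinal screen
#'
#' Pipeline order: valid-value eligibility -> random-intercept fit ->
#' Shapiro-Wilk normality gate -> omnibus time test on gate-passing proteins
#' -> Benjamini-Hochberg across the tested p-values -> significance at the
#' target FDR. Every protein appears exactly once with a disposition
#' (`ineligible`, `nonconverged`, `gate_indeterminate`, `gate_fail_residuals`,
#' `gate_fail_random_effects`, `test_undefined`, or `tested`), and q-values
#' exist only for tested proteins.
#'
#' @param table log2-scale, normalized `intensity_table`.
#' @param annotation `sample_annotation`.
#' @param rule an [eligibility_rule()] matching the assay.
#' @param fdr target FDR for the significance flag (default 0.05).
#' @param gate_alpha Shapiro-Wilk gate level (default 0.05).
#' @param method `"ML"` or `"REML"` estimation.
#' @param omnibus omnibus-test variant, see [omnibus_time_test()].
#' @param ci_df `"normal"` or `"t"` intervals, see
#'   [fit_random_intercept_model()].
#' @return An object of class `screen_result`: a data.frame with one row per
#'   protein (coefficients, CIs, gate p-values, omnibus p, q, significance,
#'   disposition) plus a `counts` attribute with the per-disposition
#'   bookkeeping.
#' @export
run_screen <- function(table, annotation, rule, fdr = 0.05,
                       gate_alpha = 0.05, method = c("ML", "REML"),
                       omnibus = c("wald_f", "wald_chisq", "lrt"),
                       ci_df = c("normal", "t")) {
  method <- match.arg(method)
  omnibus <- match.arg(omnibus)
  ci_df <- match.arg(ci_df)
  stopifnot(inherits(table, "intensity_table"))
  if (table$scale != "log2") stop("screening expects a log2-scale table")
  ann <- align_annotation(table, annotation)
  elig <- select_eligible(table, annotation, rule)

  n_prot <- nrow(table$values)
  res <- data.frame(
    protein_id = table$protein_ids,
    gene_symbol = table$gene_symbols,
    n_baseline = elig$n_baseline, n_T1 = elig$n_T1, n_T2 = elig$n_T2,
    beta_T1 = NA_real_, ci_low_T1 = NA_real_, ci_high_T1 = NA_real_,
    beta_T2 = NA_real_, ci_low_T2 = NA_real_, ci_high_T2 = NA_real_,
    shapiro_p_residuals = NA_real_, shapiro_p_ranef = NA_real_,
    p_omnibus = NA_real_, q_value = NA_real_, significant = FALSE,
    disposition = "ineligible",
    stringsAsFactors = FALSE)

  bio <- which(!ann$is_reference_pool)
  mouse <- ann$mouse_id[bio]
  tp <- ann$timepoint[bio]

  for (i in seq_len(n_prot)) {
    if (!elig$eligible[i]) next
    y <- table$values[i, bio]
    fit <- fit_random_intercept_model(y, mouse, tp, method = method,
                                      ci_df = ci_df)
    if (!fit$converged) {
      res$disposition[i] <- "nonconverged"
      next
    }
    res$beta_T1[i] <- fit$beta["T1"]
    res$ci_low_T1[i] <- fit$ci95["T1", "low"]
    res$ci_high_T1[i] <- fit$ci95["T1", "high"]
    res$beta_T2[i] <- fit$beta["T2"]
    res$ci_low_T2[i] <- fit$ci95["T2", "low"]
    res$ci_high_T2[i] <- fit$ci95["T2", "high"]
    gate <- normality_gate(fit, alpha = gate_alpha)
    res$shapiro_p_residuals[i] <- gate$shapiro_p_residuals
    res$shapiro_p_ranef[i] <- gate$shapiro_p_mouse_effects
    if (gate$status != "pass") {
      res$disposition[i] <- switch(gate$status,
                                   indeterminate = "gate_indeterminate",
                                   fail_residuals = "gate_fail_residuals",
                                   fail_random_effects =
                                     "gate_fail_random_effects")
      next
    }
    p <- omnibus_time_test(fit, variant = omnibus)
    if (is.na(p)) {
      res$disposition[i] <- "test_undefined"
      next
    }
    res$p_omnibus[i] <- p
    res$disposition[i] <- "tested"
  }

  tested <- res$disposition == "tested"
  if (any(tested)) {
    adj <- bh_adjust(res$p_omnibus[tested], fdr = fdr)
    res$q_value[tested] <- adj$q
    res$significant[tested] <- adj$rejected
  }

  counts <- table(factor(res$disposition,
                         levels = c("ineligible", "nonconverged",
                                    "gate_indeterminate",
                                    "gate_fail_residuals",
                                    "gate_fail_random_effects",
                                    "test_undefined", "tested")))
  attr(res, "counts") <- c(as.list(counts),
                           list(significant = sum(res$significant),
                                n_proteins = n_prot))
  attr(res, "params") <- list(rule = rule$name, fdr = fdr,
                              gate_alpha = gate_alpha, method = method,
                              omnibus = omnibus, ci_df = ci_df)
  class(res) <- c("screen_result", "data.frame")
  res
}

#' @export
print.screen_result <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf("longitudinal screen: %d proteins\n", cnt$n_proteins))
  cat(sprintf("  ineligible (insufficient valid values): %d\n",
              cnt$ineligible))
  cat(sprintf("  non-convergent fits: %d\n", cnt$nonconverged))
  cat(sprintf("  gate failures (residuals/ranef/indeterminate): %d/%d/%d\n",
              cnt$gate_fail_residuals, cnt$gate_fail_random_effects,
              cnt$gate_indeterminate))
  cat(sprintf("  tested: %d, significant at FDR %.2g: %d\n",
              cnt$tested, attr(x, "params")$fdr, cnt$significant))
  invisible(x)
}

#' Write screen results as TSV
#'
#' @param result a `screen_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_result <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Long-format coefficient data for forest-style plots
#'
#' One row per protein x time point with the coefficient (log2 fold change
#' vs baseline) and its 95% CI bounds, restricted by default to significant
#' proteins — the layout behind per-protein time-course effect plots.
#'
#' @param result a `screen_result`.
#' @param significant_only keep only proteins flagged significant.
#' @return A data.frame with `protein_id`, `gene_symbol`, `timepoint`,
#'   `log2fc`, `ci_low`, `ci_high`, `q_value`.
#' @export
coefficient_plot_data <- function(result, significant_only = TRUE) {
  stopifnot(inherits(result, "screen_result"))
  df <- as.data.frame(result)
  if (significant_only) df <- df[df$significant, , drop = FALSE]
  if (nrow(df) == 0) {
    return(data.frame(protein_id = character(0), gene_symbol = character(0),
                      timepoint = character(0), log2fc = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      q_value = numeric(0), stringsAsFactors = FALSE))
  }
  out <- rbind(
    data.frame(protein_id = df$protein_id, gene_symbol = df$gene_symbol,
               timepoint = "T1", log2fc = df$beta_T1,
               ci_low = df$ci_low_T1, ci_high = df$ci_high_T1,
               q_value = df$q_value, stringsAsFactors = FALSE),
    data.frame(protein_id = df$protein_id, gene_symbol = df$gene_symbol,
               timepoint = "T2", log2fc = df$beta_T2,
               ci_low = df$ci_low_T2, ci_high = df$ci_high_T2,
               q_value = df$q_value, stringsAsFactors = FALSE))
  out[order(out$protein_id, out$timepoint), , drop = FALSE]
}

#' Gene list of significant proteins
#'
#' Gene symbols of significant proteins (accession fallback when the symbol
#' is empty), one per line — the input format of external enrichment tools.
#'
#' @param result a `screen_result`.
#' @return Character vector of unique symbols/accessions.
#' @export
significant_gene_list <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  df <- as.data.frame(result)
  df <- df[df$significant, , drop = FALSE]
  sym <- ifelse(is.na(df$gene_symbol) | df$gene_symbol == "",
                df$protein_id, df$gene_symbol)
  unique(as.character(sym))
}
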