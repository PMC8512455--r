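# shared fixture builders: everything generated in code, no binary data

lfq_annotation <- function(n_mice = 6, assay = "sev_lfq",
                           timepoints = c("baseline", "T1", "T2")) {
  grid <- expand.grid(mouse_id = paste0("m", seq_len(n_mice)),
                      timepoint = timepoints,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$mouse_id), ]
  sample_annotation(data.frame(
    sample_id = paste(grid$mouse_id, grid$timepoint, sep = "_"),
    mouse_id = grid$mouse_id, timepoint = grid$timepoint, assay = assay,
    stringsAsFactors = FALSE))
}

# two TMT sets, each: 2 biological channels + n_ref reference channels
tmt_annotation_2set <- function(n_bio = 2, n_ref = 1) {
  rows <- do.call(rbind, lapply(1:2, function(s) {
    data.frame(
      sample_id = paste0("set", s, "_c", seq_len(n_bio + n_ref)),
      mouse_id = c(paste0("m", (s - 1) * n_bio + seq_len(n_bio)),
                   rep("pool", n_ref)),
      timepoint = c(rep(c("baseline", "T1", "T2"),
                        length.out = n_bio), rep("baseline", n_ref)),
      assay = "serum_tmt", tmt_set = s,
      tmt_channel = paste0("c", seq_len(n_bio + n_ref)),
      is_reference_pool = c(rep(FALSE, n_bio), rep(TRUE, n_ref)),
      stringsAsFactors = FALSE)
  }))
  sample_annotation(rows)
}

random_table <- function(n_prot = 10, annotation, seed = 1, scale = "log2",
                         na_frac = 0) {
  set.seed(seed)
  n_samp <- nrow(annotation)
  values <- matrix(rnorm(n_prot * n_samp, 24, 2), n_prot, n_samp)
  if (scale == "raw") values <- 2^(values / 4)
  if (na_frac > 0) {
    values[sample(length(values), round(na_frac * length(values)))] <- NA
  }
  colnames(values) <- annotation$sample_id
  intensity_table(values, protein_ids = sprintf("P%03d", seq_len(n_prot)),
                  gene_symbols = sprintf("G%03d", seq_len(n_prot)),
                  scale = scale, zero_as_missing = FALSE)
}

balanced_design <- function(n_mice = 6) {
  d <- expand.grid(mouse = paste0("m", seq_len(n_mice)),
                   timepoint = c("baseline", "T1", "T2"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d[order(d$mouse), ]
}

sim_protein_y <- function(design, beta_T1 = 0, beta_T2 = 0,
                          sigma_mouse = 0.5, sigma_resid = 0.5, mu = 0) {
  mice <- unique(design$mouse)
  u <- rnorm(length(mice), 0, sigma_mouse)
  names(u) <- mice
  mu + u[design$mouse] +
    ifelse(design$timepoint == "T1", beta_T1,
           ifelse(design$timepoint == "T2", beta_T2, 0)) +
    rnorm(nrow(design), 0, sigma_resid)
}

# minimal protein_fit stand-in for gate/omnibus unit tests
fake_fit <- function(residuals, mouse_effects,
                     sigma2_mouse = 1, sigma2_resid = 1,
                     beta = c(T1 = 0, T2 = 0),
                     vcov_beta = diag(2), df_containment = 10) {
  dimnames(vcov_beta) <- list(c("T1", "T2"), c("T1", "T2"))
  structure(list(beta0 = 0, beta = beta,
                 se = sqrt(diag(vcov_beta)),
                 ci95 = cbind(low = beta - 1, high = beta + 1),
                 mouse_effects = mouse_effects, residuals = residuals,
                 sigma2_mouse = sigma2_mouse, sigma2_resid = sigma2_resid,
                 lambda = sigma2_mouse / max(sigma2_resid, 1e-12),
                 vcov_beta = vcov_beta, logLik = NA_real_,
                 n_obs = length(residuals),
                 n_mice = length(mouse_effects),
                 df_containment = df_containment, rank_X = 3,
                 method = "ML", converged = TRUE, degenerate = FALSE,
                 data = NULL),
            class = "protein_fit")
}

# brute-force BH step-up: largest k with p_(k) <= k/m * alpha, reject all
# p <= that threshold
bh_brute_force <- function(p, alpha = 0.05) {
  m <- length(p)
  if (m == 0) return(logical(0))
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) / m * alpha)
  if (length(ok) == 0) return(rep(FALSE, m))
  p <= ps[max(ok)]
}
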