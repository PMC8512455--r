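test_that("the seed fully determines simulated output", {
  cfg <- simulation_preset("serum6x3", seed = 5, n_proteins = 20)
  a <- simulate_longitudinal(cfg)
  b <- simulate_longitudinal(cfg)
  expect_identical(a$table$values, b$table$values)
  expect_identical(as.data.frame(a$annotation), as.data.frame(b$annotation))
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  c_ <- simulate_longitudinal(simulation_preset("serum6x3", seed = 6,
                                                n_proteins = 20))
  expect_false(identical(a$table$values, c_$table$values))
})

test_that("affected count follows the rounding rule exactly", {
  cfg <- simulation_config(seed = 2, n_proteins = 100, prop_affected = 0.1)
  sim <- simulate_longitudinal(cfg)
  expect_equal(sum(sim$truth$affected), 10)
  expect_true(all(sim$truth$beta_T2[!sim$truth$affected] == 0))
  expect_true(all(abs(sim$truth$beta_T2[sim$truth$affected]) >= 0.5))
  expect_equal(sim$truth$beta_T1, 0.5 * sim$truth$beta_T2)
})

test_that("mouse-intercept spread matches sigma_mouse at scale", {
  cfg <- simulation_config(seed = 3, n_proteins = 2000, n_mice = 6,
                           sigma_mouse = 0.5)
  sim <- simulate_longitudinal(cfg)
  u <- attr(sim$truth, "mouse_intercepts")
  expect_equal(dim(u), c(2000, 6))
  expect_equal(sd(u), 0.5, tolerance = 0.05)
})

test_that("raw and log2 scales round-trip through the generative model", {
  cfg <- simulation_config(seed = 4, n_proteins = 10)
  sim <- simulate_longitudinal(cfg)
  logged <- log2_missing_aware(sim$table)
  expect_equal(2^logged$values, sim$table$values, tolerance = 1e-12)
})

test_that("noise-free simulation is recovered exactly by the fitter", {
  cfg <- simulation_config(seed = 6, n_proteins = 5, prop_affected = 1,
                           effect_range_T2 = c(0.5, 2), sigma_resid = 0,
                           sigma_mouse = 0.5, design = "label_free")
  sim <- simulate_longitudinal(cfg)
  logged <- log2_missing_aware(sim$table)
  ann <- sim$annotation
  for (i in seq_len(5)) {
    fit <- fit_random_intercept_model(logged$values[i, ], ann$mouse_id,
                                      ann$timepoint)
    expect_equal(fit$beta[["T1"]], sim$truth$beta_T1[i], tolerance = 1e-8)
    expect_equal(fit$beta[["T2"]], sim$truth$beta_T2[i], tolerance = 1e-8)
  }
})

test_that("TMT design has 10-plex sets with two pooled references and the
           expected biological sample count", {
  cfg <- simulation_preset("serum6x3", seed = 7, n_proteins = 8)
  sim <- simulate_longitudinal(cfg)
  ann <- sim$annotation
  expect_equal(sum(!ann$is_reference_pool), 18)
  expect_equal(sort(unique(ann$tmt_set)), 1:3)
  for (s in 1:3) {
    expect_equal(sum(ann$is_reference_pool & ann$tmt_set == s), 2)
    expect_lte(sum(ann$tmt_set == s), 10)
  }
  expect_length(attr(sim$truth, "loading_factors"), nrow(ann))
  expect_length(attr(sim$truth, "set_offsets"), 3)
})

test_that("missingness injection covers MCAR extremes, whole visits, and
           intensity-dependent dropout", {
  cfg0 <- simulation_config(seed = 8, n_proteins = 20, mcar_rate = 0,
                            design = "label_free")
  sim <- simulate_longitudinal(cfg0)
  same <- apply_missingness(sim$table, sim$annotation, cfg0)
  expect_identical(same$table$values, sim$table$values)

  cfg1 <- simulation_config(seed = 8, n_proteins = 20, mcar_rate = 1,
                            design = "label_free")
  gone <- apply_missingness(sim$table, sim$annotation, cfg1)
  expect_true(all(is.na(gone$table$values)))

  # whole visits are dropped from table and annotation alike
  cfgv <- simulation_preset("sev6x3", seed = 8, n_proteins = 20)
  simv <- simulate_longitudinal(cfgv)
  thin <- apply_missingness(simv$table, simv$annotation, cfgv)
  expect_equal(ncol(thin$table$values), 16)
  expect_equal(nrow(thin$annotation), 16)
  expect_false("m1_T2" %in% thin$annotation$sample_id)
  expect_false("m2_baseline" %in% thin$annotation$sample_id)

  # steep low-intensity dropout concentrates deletions below the median
  cfgm <- simulation_config(seed = 10, n_proteins = 200,
                            baseline_range = c(18, 30),
                            mnar_threshold = 20, mnar_steepness = 10,
                            design = "label_free")
  simm <- simulate_longitudinal(cfgm)
  thinm <- apply_missingness(simm$table, simm$annotation, cfgm)
  x <- log2(simm$table$values)
  deleted <- is.na(thinm$table$values) & !is.na(simm$table$values)
  expect_gt(sum(deleted), 0)
  expect_gte(mean(x[deleted] < median(x)), 0.8)
})

test_that("evaluate_screen reproduces a hand-computed confusion table", {
  cfg <- simulation_config(seed = 11, n_proteins = 40, prop_affected = 0.25,
                           effect_range_T2 = c(1.5, 2.5), sigma_mouse = 0.4,
                           sigma_resid = 0.4, design = "label_free")
  sim <- simulate_longitudinal(cfg)
  tab <- median_center(log2_missing_aware(sim$table))$table
  res <- run_screen(tab, sim$annotation, eligibility_rule("sev_rule"))
  m <- evaluate_screen(res, sim$truth)
  tr <- sim$truth[match(res$protein_id, sim$truth$protein_id), ]
  tp <- sum(res$significant & tr$affected)
  fp <- sum(res$significant & !tr$affected)
  expect_equal(m$n_significant, tp + fp)
  expect_equal(m$fdp, if (tp + fp == 0) 0 else fp / (tp + fp))
  expect_equal(m$sensitivity,
               if (tp + fp == 0) 0 else tp / sum(tr$affected))
  est <- !is.na(res$beta_T2)
  expect_equal(m$rmse_T2,
               sqrt(mean((res$beta_T2[est] - tr$beta_T2[est])^2)))

  # conventions: empty rejection set has FDP 0 and sensitivity 0
  res0 <- res
  res0$significant[] <- FALSE
  m0 <- evaluate_screen(res0, sim$truth)
  expect_equal(m0$fdp, 0)
  expect_equal(m0$sensitivity, 0)

  bad <- sim$truth
  bad$protein_id[1] <- "OTHER"
  expect_error(evaluate_screen(res, bad), "ids do not match")
})

test_that("manufactured 4-of-5-correct rejection set scores FDP 0.2", {
  cfg <- simulation_config(seed = 12, n_proteins = 10, prop_affected = 0.4,
                           design = "label_free")
  sim <- simulate_longitudinal(cfg)
  tab <- median_center(log2_missing_aware(sim$table))$table
  res <- run_screen(tab, sim$annotation, eligibility_rule("sev_rule"))
  aff <- match(sim$truth$protein_id[sim$truth$affected], res$protein_id)
  nul <- match(sim$truth$protein_id[!sim$truth$affected], res$protein_id)
  res$significant[] <- FALSE
  res$significant[c(aff, nul[1])] <- TRUE   # 4 true + 1 false discovery
  m <- evaluate_screen(res, sim$truth)
  expect_equal(m$fdp, 0.2)
  expect_equal(m$sensitivity, 1)
})

test_that("inconsistent TMT configuration errors", {
  expect_error(simulation_config(design = "tmt", channels_per_set = 2,
                                 refs_per_set = 2),
               "inconsistent TMT config")
  expect_error(simulation_config(design = "tmt", assay = "csf_lfq"),
               "serum_tmt")
})
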