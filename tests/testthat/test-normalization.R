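test_that("within-set loading factors equalize channel totals", {
  ann <- tmt_annotation_2set(n_bio = 2, n_ref = 0)
  ann <- ann[ann$tmt_set == 1, , drop = FALSE]
  class(ann) <- c("sample_annotation", "data.frame")
  values <- matrix(c(40, 60, 100, 200), 2, 2,
                   dimnames = list(NULL, ann$sample_id))
  tab <- intensity_table(values, c("P1", "P2"), scale = "raw")
  out <- tmt_within_set_normalize(tab, ann)
  expect_equal(out$report$factor, c(2.0, 2 / 3))
  expect_equal(unname(colSums(out$table$values)), c(200, 200))

  # equal totals -> identity; idempotence
  again <- tmt_within_set_normalize(out$table, ann)
  expect_equal(again$report$factor, c(1, 1))
  expect_equal(again$table$values, out$table$values)
})

test_that("within-set normalization undoes per-channel rescaling up to the
           set's mean total, and missing entries stay missing", {
  ann <- tmt_annotation_2set(n_bio = 3, n_ref = 2)
  for (seed in 1:3) {
    tab <- random_table(20, ann, seed = seed, scale = "raw", na_frac = 0.1)
    base <- tmt_within_set_normalize(tab, ann)$table
    scaling <- 2^runif(nrow(ann), -1, 1)
    # arbitrary rescaling: output identical up to one constant per set
    # (the set's mean total changes with the scaling)
    scaled <- intensity_table(sweep(tab$values, 2, scaling, `*`),
                              tab$protein_ids,
                              sample_ids = tab$sample_ids, scale = "raw",
                              zero_as_missing = FALSE)
    renorm <- tmt_within_set_normalize(scaled, ann)$table
    for (s in unique(ann$tmt_set)) {
      j <- ann$sample_id[ann$tmt_set == s]
      ratio <- renorm$values[, j] / base$values[, j]
      expect_lt(diff(range(ratio, na.rm = TRUE)), 1e-12)
    }
    # a rescaling that preserves each set's mean total composes to identity
    totals <- colSums(tab$values, na.rm = TRUE)
    for (s in unique(ann$tmt_set)) {
      j <- which(ann$tmt_set == s)
      scaling[j] <- scaling[j] *
        mean(totals[j]) / mean(scaling[j] * totals[j])
    }
    scaled2 <- intensity_table(sweep(tab$values, 2, scaling, `*`),
                               tab$protein_ids,
                               sample_ids = tab$sample_ids, scale = "raw",
                               zero_as_missing = FALSE)
    renorm2 <- tmt_within_set_normalize(scaled2, ann)$table
    expect_equal(renorm2$values, base$values, tolerance = 1e-12)
    expect_equal(is.na(base$values), is.na(tab$values))
  }
})

test_that("all-missing channel is a named error", {
  ann <- tmt_annotation_2set(n_bio = 2, n_ref = 1)
  tab <- random_table(5, ann, scale = "raw")
  v <- tab$values
  v[, "set2_c1"] <- NA
  tab <- intensity_table(v, tab$protein_ids, sample_ids = tab$sample_ids,
                         scale = "raw", zero_as_missing = FALSE)
  expect_error(tmt_within_set_normalize(tab, ann), "set2_c1")
})

test_that("between-set factors equalize reference averages across sets", {
  ann <- tmt_annotation_2set(n_bio = 1, n_ref = 1)
  # protein ref intensities 50 (set 1) and 200 (set 2)
  values <- matrix(c(10, 50, 20, 200), 1, 4,
                   dimnames = list(NULL, ann$sample_id))
  tab <- intensity_table(values, "P1", scale = "raw")
  out <- tmt_between_set_normalize(tab, ann)
  expect_equal(sort(out$report$factor), sort(c(2.5, 0.625)))
  ref_cols <- ann$sample_id[ann$is_reference_pool]
  expect_equal(unname(out$table$values[1, ref_cols]), c(125, 125))

  # single set -> identity
  one <- ann[ann$tmt_set == 1, , drop = FALSE]
  class(one) <- c("sample_annotation", "data.frame")
  tab1 <- subset_samples(tab, one$sample_id)
  out1 <- tmt_between_set_normalize(tab1, one)
  expect_equal(out1$table$values, tab1$values)
})

test_that("protein unobserved in a set's reference channels becomes missing
           there and is reported", {
  ann <- tmt_annotation_2set(n_bio = 2, n_ref = 2)
  tab <- random_table(4, ann, seed = 3, scale = "raw")
  v <- tab$values
  ref2 <- ann$sample_id[ann$is_reference_pool & ann$tmt_set == 2]
  v[2, ref2] <- NA
  tab <- intensity_table(v, tab$protein_ids, sample_ids = tab$sample_ids,
                         scale = "raw", zero_as_missing = FALSE)
  out <- tmt_between_set_normalize(tab, ann)
  set2 <- ann$sample_id[ann$tmt_set == 2]
  expect_true(all(is.na(out$table$values[2, set2])))
  expect_equal(out$uncalibratable,
               data.frame(protein_id = "P002", tmt_set = 2L,
                          stringsAsFactors = FALSE),
               ignore_attr = TRUE)
  # other proteins: fully calibrated, refs equal across sets
  ref1 <- ann$sample_id[ann$is_reference_pool & ann$tmt_set == 1]
  for (i in c(1, 3, 4)) {
    expect_equal(mean(out$table$values[i, ref1]),
                 mean(out$table$values[i, ref2]), tolerance = 1e-12)
  }
})

test_that("log2 transform is missing-aware and rejects nonpositive values", {
  values <- matrix(c(8, NA, 1, 4), 2, 2, dimnames = list(NULL, c("a", "b")))
  tab <- intensity_table(values, c("P1", "P2"), scale = "raw")
  out <- log2_missing_aware(tab)
  expect_equal(out$scale, "log2")
  expect_equal(unname(out$values), matrix(c(3, NA, 0, 2), 2, 2))
  neg <- intensity_table(matrix(-1), "P1", sample_ids = "a", scale = "log2")
  neg$scale <- "raw"  # forge a raw table with a negative observed value
  expect_error(log2_missing_aware(neg), "nonpositive")
})

test_that("median centering zeroes each sample's observed median and is
           idempotent", {
  values <- cbind(s1 = c(10, 12, 14), s2 = c(10, NA, 14))
  tab <- intensity_table(values, c("P1", "P2", "P3"), scale = "log2")
  out <- median_center(tab)
  expect_equal(unname(out$table$values[, "s1"]), c(-2, 0, 2))
  expect_equal(unname(out$table$values[, "s2"]), c(-2, NA, 2))
  expect_equal(out$report$median_subtracted, c(12, 12))
  twice <- median_center(out$table)
  expect_equal(twice$table$values, out$table$values)
  expect_equal(twice$report$median_subtracted, c(0, 0))

  # per-sample observed medians are 0 after centering, any missingness
  ann <- lfq_annotation(5)
  big <- random_table(40, ann, seed = 9, na_frac = 0.2)
  cent <- median_center(big)$table
  meds <- apply(cent$values, 2, median, na.rm = TRUE)
  expect_equal(unname(meds), rep(0, ncol(cent$values)), tolerance = 1e-12)
})

test_that("an all-missing sample is left unchanged with a warning", {
  values <- cbind(s1 = c(1, 2, 3), s2 = c(NA_real_, NA, NA))
  tab <- intensity_table(values, paste0("P", 1:3), scale = "log2")
  expect_warning(out <- median_center(tab), "s2")
  expect_true(all(is.na(out$table$values[, "s2"])))
})

test_that("PCA QC scores match an independent eigen-decomposition and
           duplicate samples coincide", {
  ann <- lfq_annotation(1, timepoints = c("baseline", "T1", "T2"))
  values <- rbind(c(1, 2, 6), c(3, 1, 2))
  colnames(values) <- ann$sample_id
  tab <- intensity_table(values, c("P1", "P2"), scale = "log2")
  sc <- pca_qc_scores(tab, ann, n_components = 2)
  # oracle: eigen-decomposition of the sample covariance of centered data
  xc <- scale(t(values), center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(xc) / (nrow(xc) - 1))
  oracle <- xc %*% eig$vectors
  for (k in 1:2) {
    expect_equal(abs(sc[[paste0("PC", k)]]), abs(unname(oracle[, k])),
                 tolerance = 1e-8)
  }

  ann4 <- lfq_annotation(2, timepoints = c("baseline", "T1"))
  v4 <- cbind(c(1, 5), c(2, 4), c(1, 5), c(2, 4))
  colnames(v4) <- ann4$sample_id
  t4 <- intensity_table(v4, c("P1", "P2"), scale = "log2")
  sc4 <- pca_qc_scores(t4, ann4, 1)
  expect_equal(sc4$PC1[1], sc4$PC1[3])
  expect_equal(sc4$PC1[2], sc4$PC1[4])

  empty <- intensity_table(matrix(NA_real_, 1, 4,
                                  dimnames = list("P1", ann4$sample_id)),
                           "P1", scale = "log2")
  expect_error(pca_qc_scores(empty, ann4), "complete-case")
})

test_that("between-set normalization removes a simulated batch direction
           from the leading component", {
  cfg <- simulation_preset("serum6x3", seed = 11, n_proteins = 60,
                           prop_affected = 0, set_offset_sd = 1.5,
                           loading_sd = 0.1)
  sim <- simulate_longitudinal(cfg)
  w <- tmt_within_set_normalize(sim$table, sim$annotation)$table
  b <- tmt_between_set_normalize(w, sim$annotation)$table
  r2_set <- function(tab) {
    sc <- pca_qc_scores(log2_missing_aware(tab), sim$annotation, 1)
    summary(lm(sc$PC1 ~ factor(sc$tmt_set)))$r.squared
  }
  expect_gt(r2_set(w), 0.8)   # set offsets dominate PC1 before calibration
  expect_lt(r2_set(b), 0.5)   # and are gone after
})
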