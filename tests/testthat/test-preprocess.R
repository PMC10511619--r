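test_that("intensity scaling divides present values and is linear", {
  m <- matrix(c(250000, 0, NA, 1e5), 2, 2,
              dimnames = list(c("S1", "S2"), c("F1", "F2")))
  ft <- feature_table(m)
  sc <- scale_intensities(ft, 1e5)
  expect_equal(sc$intensities["S1", "F1"], 2.5)
  expect_equal(sc$intensities["S2", "F1"], 0)
  expect_true(is.na(sc$intensities["S1", "F2"]))
  # scaling by a then b equals scaling by a*b
  expect_equal(scale_intensities(scale_intensities(ft, 10), 20)$intensities,
               scale_intensities(ft, 200)$intensities)
  expect_error(scale_intensities(ft, 0), class = "lipistage_parameter_error")
})

test_that("replicate outlier masking follows the leave-one-out z rule", {
  vals <- c(10, 10.2, 9.8, 50)
  m <- matrix(vals, 4, 1, dimnames = list(paste0("S1_r", 1:4), "F1"))
  rmap <- stats::setNames(rep("S1", 4), rownames(m))
  out <- mask_replicate_outliers(feature_table(m), rmap, k_sd = 3)
  expect_true(is.na(out$features$intensities["S1_r4", "F1"]))
  expect_equal(sum(out$outlier_mask), 1)

  # clean triplet untouched (all leave-one-out z-scores below 3)
  m2 <- matrix(c(10, 10.2, 9.8), 3, 1,
               dimnames = list(paste0("S1_r", 1:3), "F1"))
  rmap2 <- stats::setNames(rep("S1", 3), rownames(m2))
  out2 <- mask_replicate_outliers(feature_table(m2), rmap2)
  expect_equal(sum(out2$outlier_mask), 0)

  # groups of fewer than 3 present values untouched regardless of spread
  m3 <- matrix(c(1, 1000), 2, 1, dimnames = list(c("S1_r1", "S1_r2"), "F1"))
  rmap3 <- stats::setNames(rep("S1", 2), rownames(m3))
  out3 <- mask_replicate_outliers(feature_table(m3), rmap3)
  expect_equal(sum(out3$outlier_mask), 0)

  expect_error(mask_replicate_outliers(feature_table(m3),
                                       c(S1_r1 = "S1")),
               "S1_r2", class = "lipistage_mapping_error")
})

test_that("masking never adds values and ignores replicate order", {
  co <- generate_cohort(small_cohort_config(seed = 6, outlier_rate = 0.05))
  ft <- co$features
  out <- mask_replicate_outliers(ft, co$replicate_map)
  expect_lte(sum(!is.na(out$features$intensities)),
             sum(!is.na(ft$intensities)))
  perm <- sample(seq_along(ft$sample_ids))
  ftp <- feature_table(ft$intensities[perm, , drop = FALSE], ft$annotations)
  outp <- mask_replicate_outliers(ftp, co$replicate_map)
  expect_equal(outp$features$intensities[ft$sample_ids, ],
               out$features$intensities)
})

test_that("replicates collapse to means of unmasked values", {
  m <- matrix(c(10, 10.2, 9.8, NA), 4, 1,
              dimnames = list(paste0("S1_r", 1:4), "F1"))
  rmap <- stats::setNames(rep("S1", 4), rownames(m))
  cl <- collapse_replicates(feature_table(m), rmap)
  expect_equal(unname(cl$intensities["S1", "F1"]), 10.0)

  # single replicate is the identity
  one <- feature_table(matrix(5, 1, 1, dimnames = list("S1", "F1")))
  expect_equal(unname(collapse_replicates(one, c(S1 = "S1"))$intensities[1, 1]),
               5)

  # all replicates masked -> missing
  m2 <- matrix(NA_real_, 2, 1, dimnames = list(c("S1_r1", "S1_r2"), "F1"))
  cl2 <- collapse_replicates(feature_table(m2),
                             stats::setNames(rep("S1", 2), rownames(m2)))
  expect_true(is.na(cl2$intensities["S1", "F1"]))
})

test_that("feature-mean imputation fills gaps and drops empty features", {
  m <- matrix(c(1, NA, 3, 4, 5, 6, NA, NA, NA), 3, 3,
              dimnames = list(paste0("S", 1:3), c("F1", "F2", "F3")))
  expect_warning(imp <- impute_missing(feature_table(m)), "F3")
  expect_equal(unname(imp$intensities[, "F1"]), c(1, 2, 3))
  expect_equal(unname(imp$intensities[, "F2"]), c(4, 5, 6))
  expect_equal(ncol(imp$intensities), 2)
  expect_false(anyNA(imp$intensities))
})

test_that("gene status codes are +1/-1/0", {
  expect_equal(code_gene_status(c("positive", "negative", "unknown")),
               c(1L, -1L, 0L))
  expect_equal(code_gene_status(c(NA, "")), c(0L, 0L))
  expect_error(code_gene_status("wildtype"), "wildtype",
               class = "lipistage_coding_error")
})

test_that("design assembly applies the scenario class codings", {
  co <- generate_cohort(small_cohort_config(seed = 8))
  ds3 <- cohort_to_design(co, "CFI-CRC-CLM")
  cl <- co$clinical
  expect_equal(unname(ds3$y[match(cl$sample_id[cl$group == "CLM"],
                                  ds3$sample_ids)][1]), 2)
  expect_equal(sort(unique(ds3$y)), c(0, 1, 2))
  expect_false(anyNA(ds3$X))

  ds2 <- cohort_to_design(co, "CFI-mCRC")
  expect_equal(sort(unique(ds2$y)), c(0, 1))
  clm_id <- cl$sample_id[cl$group == "CLM"][1]
  expect_equal(unname(ds2$y[ds2$sample_ids == clm_id]), 1)
  # clinical covariates appended for the multi-omics scenario
  expect_true(all(c("age", "il8", "kras", "gender_f") %in% ds2$feature_names))
  expect_equal(unname(abs(mean(ds2$X[, "age"]))), 0, tolerance = 1e-10)

  ds5 <- cohort_to_design(co, "CFI-CRC")
  stage3 <- cl$sample_id[!is.na(cl$stage) & cl$stage == 3][1]
  expect_equal(unname(ds5$y[ds5$sample_ids == stage3]), 3)
  expect_false(any(cl$sample_id[cl$group == "CLM"] %in% ds5$sample_ids))
  # coding map is a bijection onto the observed code set
  expect_setequal(unname(ds5$coding_map), 0:4)
})

test_that("assembly fails when a coded class is empty", {
  co <- generate_cohort(synthetic_config(
    n_per_class = c(CFI = 6, CRC = 3), n_features = 10, n_informative = 2,
    replicate_count = 1, seed = 2))
  # only 3 CRC samples -> stages 1,2,3 present, stage 4 empty
  ft <- impute_missing(scale_intensities(co$features))
  st <- align(ft, co$clinical)
  expect_error(assemble_design(st, "CFI-CRC"),
               class = "lipistage_assembly_error")
})
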