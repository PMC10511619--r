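test_that("cohort dimensions follow the configuration", {
  cfg <- synthetic_config(seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(dim(co$features$intensities), c(66 * 3, 333))
  expect_equal(nrow(co$clinical), 66)
  expect_equal(as.vector(table(co$clinical$group)[c("CFI", "CRC", "CLM")]),
               c(16, 32, 18))
  expect_equal(nrow(co$planted_features), 9)
  expect_true(all(co$planted_features$feature_id %in% co$features$feature_ids))
  expect_setequal(unname(co$replicate_map), co$clinical$sample_id)
  # stage present exactly for CRC samples
  expect_true(all(is.na(co$clinical$stage[co$clinical$group != "CRC"])))
  expect_true(all(co$clinical$stage[co$clinical$group == "CRC"] %in% 1:4))
})

test_that("same configuration and seed give bit-identical cohorts", {
  cfg <- small_cohort_config(seed = 11)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(synthetic_config(missing_rate = 1.2), "missing_rate",
               class = "lipistage_config_error")
  expect_error(synthetic_config(n_features = -1), "n_features",
               class = "lipistage_config_error")
  expect_error(synthetic_config(outlier_magnitude = 0.5), "outlier_magnitude",
               class = "lipistage_config_error")
  expect_error(synthetic_config(gene_prevalence = list(kras = c(0.8, 0.4))),
               "kras", class = "lipistage_config_error")
  expect_error(synthetic_config(n_per_class = c(BAD = 5)), "n_per_class",
               class = "lipistage_config_error")
})

test_that("null effect size gives nominal t-test rejection rates", {
  # 1000 feature draws under the null: CFI vs CRC two-sample t-tests should
  # reject at roughly the nominal 5% level
  cfg <- synthetic_config(n_per_class = c(CFI = 20, CRC = 20),
                          n_features = 1000, n_informative = 1,
                          effect_size = 0, missing_rate = 0, outlier_rate = 0,
                          replicate_count = 1, seed = 5)
  co <- generate_cohort(cfg)
  g <- co$clinical$group[match(co$features$sample_ids, co$clinical$sample_id)]
  p <- apply(co$features$intensities, 2, function(v)
    stats::t.test(v[g == "CFI"], v[g == "CRC"])$p.value)
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
})

test_that("planted features are class-monotone at moderate effect size", {
  n_mono <- 0; n_tot <- 0
  for (seed in 1:20) {
    cfg <- synthetic_config(n_per_class = c(CFI = 16, CRC = 32, CLM = 18),
                            n_features = 40, n_informative = 9,
                            effect_size = 1, missing_rate = 0,
                            outlier_rate = 0, replicate_count = 1, seed = seed)
    co <- generate_cohort(cfg)
    g <- co$clinical$group
    for (k in seq_len(nrow(co$planted_features))) {
      f <- co$planted_features$feature_id[k]
      d <- co$planted_features$direction[k]
      mu <- tapply(co$features$intensities[, f], g, mean)[c("CFI", "CRC", "CLM")]
      ord <- if (d > 0) all(diff(mu) > 0) else all(diff(mu) < 0)
      n_mono <- n_mono + ord; n_tot <- n_tot + 1
    }
  }
  expect_gte(n_mono / n_tot, 0.95)
})

test_that("generated survival times match the configured medians", {
  cfg <- synthetic_config(n_per_class = c(CRC = 500), n_features = 4,
                          n_informative = 1, censor_rate = 0,
                          replicate_count = 1,
                          survival_median_months = c(CRC = 48), seed = 9)
  co <- generate_cohort(cfg)
  km <- km_estimate(co$clinical$dfs_months, co$clinical$dfs_event)
  expect_lt(abs(km_median(km) - 48) / 48, 0.15)
})

test_that("intensities are positive before missing/outlier injection", {
  cfg <- small_cohort_config(seed = 2, missing_rate = 0, outlier_rate = 0)
  co <- generate_cohort(cfg)
  expect_true(all(co$features$intensities > 0))
})

test_that("cohorts round-trip through CSV files", {
  cfg <- small_cohort_config(seed = 13)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  ft <- read_feature_table(file.path(dir, "features.csv"),
                           file.path(dir, "annotations.csv"))
  cl <- read_clinical_table(file.path(dir, "clinical.csv"))
  expect_equal(ft$intensities, co$features$intensities)
  expect_equal(cl$group, co$clinical$group)
  expect_equal(cl$dfs_months, co$clinical$dfs_months)
})

test_that("YAML and JSON configs reproduce the constructor", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c("n_per_class:", "  CFI: 4", "  CRC: 6", "n_features: 10",
               "n_informative: 2", "seed: 3",
               "survival_median_months:", "  CFI: 100", "  CRC: 40"), yml)
  cfg <- read_synthetic_config(yml)
  expect_s3_class(cfg, "synthetic_config")
  expect_equal(unname(cfg$n_per_class[c("CFI", "CRC")]), c(4, 6))
  jsn <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(n_per_class = list(CFI = 4, CRC = 6),
                            n_features = 10, n_informative = 2, seed = 3,
                            survival_median_months = list(CFI = 100, CRC = 40)),
                       jsn, auto_unbox = TRUE)
  cfg2 <- read_synthetic_config(jsn)
  expect_equal(cfg2$n_features, 10)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg2))
})
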