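test_that("feature CSV parses blanks as missing and validates identifiers", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "feat.csv")
  writeLines(c("sample_id,F1,F2", "S1,1.5,2", "S2,,4", "S3,5,6"), f)
  ft <- read_feature_table(f)
  expect_equal(sum(is.na(ft$intensities)), 1)
  expect_true(is.na(ft$intensities["S2", "F1"]))
  expect_equal(ft$feature_ids, c("F1", "F2"))

  writeLines(c("sample_id,F1,F1", "S1,1,2"), f)
  expect_error(read_feature_table(f), "F1", class = "lipistage_format_error")

  writeLines(c("sample_id,F1,F2", "S1,1,2", "S1,3,4"), f)
  expect_error(read_feature_table(f), "S1", class = "lipistage_format_error")

  writeLines(c("sample_id,F1,F2", "S1,-3,2"), f)
  expect_error(read_feature_table(f), "negative",
               class = "lipistage_validation_error")
})

test_that("annotation side-car is attached verbatim and window-checked", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "feat.csv"); a <- file.path(dir, "ann.csv")
  writeLines(c("sample_id,F1", "S1,1", "S2,2", "S3,3"), f)
  writeLines(c("feature_id,lipid_class,mz,rt,adduct",
               "F1,PS,855.59,14.08,"), a)
  ft <- read_feature_table(f, a)
  expect_equal(ft$annotations$mz, 855.59)
  expect_equal(ft$annotations$rt, 14.08)
  expect_equal(ft$annotations$lipid_class, "PS")

  writeLines(c("feature_id,lipid_class,mz,rt,adduct", "F1,PS,1500,2,"), a)
  expect_error(read_feature_table(f, a), "1300",
               class = "lipistage_validation_error")
})

test_that("clinical CSV honours the column contract", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "clin.csv")
  hdr <- "sample_id,group,stage,age,gender,waist_cm,il8,pf4,midkine,kras,braf,mlh1,dfs_months,dfs_event,os_months,os_event"
  writeLines(c(hdr,
               "S1,CLM,,65,F,94,12,1800,300,positive,,unknown,20,1,30,0"), f)
  cl <- read_clinical_table(f)
  expect_equal(cl$group, "CLM")
  expect_true(is.na(cl$stage))
  expect_equal(cl$braf, "unknown")   # empty cell reads as unknown
  expect_equal(cl$kras, "positive")

  writeLines(c(hdr, "S1,CRC,5,65,F,94,12,1800,300,,,,20,1,30,0"), f)
  expect_error(read_clinical_table(f), "stage",
               class = "lipistage_validation_error")
  writeLines(c(hdr, "S1,CFI,2,65,F,94,12,1800,300,,,,20,1,30,0"), f)
  expect_error(read_clinical_table(f), "non-CRC",
               class = "lipistage_validation_error")
  writeLines(c(hdr, "S1,CRC,2,sixty,F,94,12,1800,300,,,,20,1,30,0"), f)
  expect_error(read_clinical_table(f), "age",
               class = "lipistage_format_error")
})

test_that("feature tables round-trip at full precision", {
  co <- generate_cohort(small_cohort_config(seed = 4))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "f.csv")
  write_feature_table(co$features, p)
  back <- read_feature_table(p)
  expect_identical(is.na(back$intensities), is.na(co$features$intensities))
  expect_equal(back$intensities, co$features$intensities, tolerance = 0)
})

test_that("align intersects, reorders, and reports dropped samples", {
  m1 <- matrix(1:6, 3, 2, dimnames = list(c("S1", "S2", "S3"), c("F1", "F2")))
  ft <- feature_table(m1 * 1.0)
  cl <- tiny_clinical(ids = c("S2", "S3", "S4"),
                      groups = c("CRC", "CLM", "CFI"),
                      stages = c(1, NA, NA))
  st <- suppressMessages(align(ft, cl))
  expect_equal(st$features$sample_ids, c("S2", "S3"))
  expect_equal(st$clinical$sample_id, c("S2", "S3"))
  expect_setequal(st$dropped_samples, c("S1", "S4"))

  # same identifier sets in different orders align with nothing dropped
  cl2 <- tiny_clinical(ids = c("S3", "S1", "S2"),
                       groups = c("CLM", "CFI", "CRC"),
                       stages = c(NA, NA, 3))
  st2 <- align(ft, cl2)
  expect_equal(st2$dropped_samples, character(0))
  expect_equal(st2$features$sample_ids, st2$clinical$sample_id)

  # align is idempotent
  st3 <- align(st2$features, st2$clinical)
  expect_identical(st3$features, st2$features)
  expect_identical(st3$clinical, st2$clinical)

  cl3 <- tiny_clinical(ids = c("X1", "X2", "X3"))
  expect_error(align(ft, cl3), class = "lipistage_alignment_error")
})
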