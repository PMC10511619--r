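test_that("the product-limit estimate matches the hand example", {
  km <- km_estimate(c(2, 3, 3, 5), c(1, 1, 1, 0))
  expect_equal(km$curve$time, c(2, 3))
  expect_equal(km$curve$survival, c(0.75, 0.25))
  expect_equal(km_survival_at(km, c(2, 3, 5)), c(0.75, 0.25, 0.25))
  expect_equal(km$censor_times, 5)
})

test_that("no events means survival stays at one", {
  km <- km_estimate(c(4, 7, 9), c(0, 0, 0))
  expect_equal(nrow(km$curve), 0)
  expect_equal(km_survival_at(km, c(1, 10)), c(1, 1))
})

test_that("without censoring the curve is the empirical survivor function", {
  set.seed(2)
  t <- round(rexp(40, 0.1), 1)
  km <- km_estimate(t, rep(1, 40))
  at <- c(2, 5, 10, 20)
  expect_equal(km_survival_at(km, at),
               vapply(at, function(a) mean(t > a), numeric(1)))
})

test_that("km_estimate agrees exactly with a brute-force risk-set oracle", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(3:25, 1)
    t <- sample(1:12, n, replace = TRUE)  # heavy ties on purpose
    e <- rbinom(n, 1, 0.7)
    if (sum(e) == 0) e[1] <- 1
    km <- km_estimate(t, e)
    oracle <- km_oracle(t, e)
    expect_equal(km$curve$time, oracle$time)
    expect_equal(km$curve$survival, oracle$survival, tolerance = 1e-12)
    expect_equal(km$curve$n_at_risk, oracle$n_at_risk)
    expect_equal(km$curve$n_events, oracle$n_events)
  }
})

test_that("survival curves are valid non-increasing step functions", {
  set.seed(8)
  km <- km_estimate(rexp(50, 0.05), rbinom(50, 1, 0.6))
  expect_true(all(diff(km$curve$survival) <= 0))
  expect_true(all(km$curve$survival >= 0 & km$curve$survival <= 1))
  expect_true(all(diff(km$curve$n_at_risk) <= 0))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), class = "lipistage_input_error")
})

test_that("the log-rank test is symmetric and label-invariant", {
  g <- list(a = list(times = c(2, 4, 6, 8), events = c(1, 1, 0, 1)),
            b = list(times = c(2, 4, 6, 8), events = c(1, 1, 0, 1)))
  lr <- logrank_test(g)
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  set.seed(10)
  g2 <- list(a = list(times = rexp(30, 0.1), events = rbinom(30, 1, 0.8)),
             b = list(times = rexp(30, 0.05), events = rbinom(30, 1, 0.8)))
  lr1 <- logrank_test(g2)
  lr2 <- logrank_test(rev(g2))
  expect_equal(lr1$chi2, lr2$chi2, tolerance = 1e-12)
  expect_equal(lr1$df, 1)

  # degenerate: no events anywhere
  g3 <- list(a = list(times = c(1, 2), events = c(0, 0)),
             b = list(times = c(3, 4), events = c(0, 0)))
  lr3 <- logrank_test(g3)
  expect_true(lr3$degenerate)
  expect_equal(lr3$p, 1)
  expect_error(logrank_test(g3[1]), class = "lipistage_input_error")
})

test_that("group-wise survival mirrors the stage structure", {
  co <- generate_cohort(synthetic_config(seed = 21))
  sg <- survival_by_group(co$clinical, "dfs")
  expect_true(all(grepl("^stage-|^CLM$", names(sg$curves))))
  expect_false("CFI" %in% names(sg$curves))
  expect_equal(sg$horizon_months, 60)
  expect_equal(colnames(sg$at_risk)[1], "m0")
  expect_s3_class(sg$logrank, "logrank_result")
  # administrative censoring never raises the curve below the horizon
  sg_no <- survival_by_group(co$clinical, "dfs", horizon_months = Inf)
  for (g in names(sg$curves)) {
    at <- sg$curves[[g]]$curve$time
    expect_equal(km_survival_at(sg$curves[[g]], at),
                 km_survival_at(sg_no$curves[[g]], at), tolerance = 1e-12)
  }
  # single-group request yields a curve but no test
  one <- survival_by_group(co$clinical[co$clinical$group == "CLM", ], "os",
                           by = "stage")
  expect_null(one$logrank)
  # missing endpoint columns are reported
  cl2 <- co$clinical; cl2$os_months <- NULL
  expect_error(survival_by_group(cl2, "os"), "os_months",
               class = "lipistage_input_error")
})

test_that("class-dependent hazards are detected by the log-rank test", {
  # hazards separated enough that the log-rank test should be near-certain
  hits <- 0
  for (seed in 1:20) {
    co <- generate_cohort(synthetic_config(
      n_per_class = c(CFI = 20, CRC = 30, CLM = 20), n_features = 5,
      n_informative = 1, replicate_count = 1, censor_rate = 0.15,
      survival_median_months = c(CFI = 150, CRC = 30, CLM = 8),
      seed = 300 + seed))
    sg <- survival_by_group(co$clinical, "dfs", by = "group")
    if (sg$logrank$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.9)
})
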