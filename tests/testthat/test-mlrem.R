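test_that("beta = 0 reproduces ordinary least squares", {
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("x", 1:5)))
    y <- drop(X %*% rnorm(5)) + rnorm(40, sd = 0.3)
    m <- fit_mlrem(X, y, beta_sparsity = 0)
    w_raw <- coef(m, scale = "raw")[paste0("x", 1:5)]
    ols <- stats::lm(y ~ X)
    expect_equal(unname(w_raw), unname(coef(ols)[-1]), tolerance = 1e-6)
    expect_equal(unname(predict(m, X)), unname(fitted(ols)), tolerance = 1e-6)
  }
})

test_that("an exact linear relation is reproduced exactly at beta = 0", {
  X <- matrix(1:4, 4, 1, dimnames = list(NULL, "x"))
  y <- 1:4
  m <- fit_mlrem(X, y, beta_sparsity = 0)
  expect_equal(unname(predict(m, X)), as.numeric(y), tolerance = 1e-8)
  expect_equal(unname(coef(m, "raw")["x"]), 1, tolerance = 1e-8)
  expect_equal(m$train_r2, 1, tolerance = 1e-10)
})

test_that("identical columns keep identical weights", {
  set.seed(1)
  x <- rnorm(30)
  X <- cbind(a = x, b = x, c = rnorm(30))
  y <- 2 * x + rnorm(30, sd = 0.1)
  # the unpenalized refit warns that one of the twin columns is aliased
  suppressWarnings(m <- fit_mlrem(X, y, beta_sparsity = 0.3))
  if (all(c("a", "b") %in% m$selected_features)) {
    expect_equal(unname(m$coefficients["a"]), unname(m$coefficients["b"]),
                 tolerance = 1e-10)
  } else {
    # symmetric update: either both survive or both prune
    expect_false(any(c("a", "b") %in% m$selected_features))
  }
})

test_that("a single informative feature is isolated at moderate sparsity", {
  ok <- 0
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(250), 50, 5, dimnames = list(NULL, paste0("x", 1:5)))
    y <- 3 * X[, 1] + rnorm(50, sd = 0.5)
    m <- fit_mlrem(X, y, beta_sparsity = 1)
    if (identical(m$selected_features, "x1")) ok <- ok + 1
  }
  expect_gte(ok / 20, 0.95)
})

test_that("sparsity sweep panel sizes are non-increasing on the fixture seed", {
  co <- generate_cohort(small_cohort_config(seed = 1))
  ds <- cohort_to_design(co)
  sw <- sparsity_sweep(ds$X, ds$y, c(0.2, 0.4, 1.0))
  ns <- vapply(sw$entries, `[[`, numeric(1), "n_selected")
  expect_true(all(diff(ns) <= 0))
  expect_error(sparsity_sweep(ds$X, ds$y, c(0.4, 0.2)),
               class = "lipistage_parameter_error")
})

test_that("beta = 0 in a sweep keeps the full-rank design's columns", {
  set.seed(2)
  X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- drop(X %*% c(1, -1, 2, 0.5, -0.5)) + rnorm(40, sd = 0.2)
  sw <- sparsity_sweep(X, y, 0)
  expect_equal(sw$entries[[1]]$n_selected, 5)
})

test_that("over-pruning yields a flagged intercept-only model", {
  set.seed(3)
  X <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- rnorm(20)
  m <- fit_mlrem(X, y, beta_sparsity = 50)
  expect_true(m$degenerate)
  expect_length(m$selected_features, 0)
  expect_equal(unname(predict(m, X)), rep(mean(y), 20))
})

test_that("predictions are invariant to raw column rescaling", {
  set.seed(4)
  X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- drop(X %*% c(2, 1, 0, 0, -1)) + rnorm(40, sd = 0.3)
  m1 <- fit_mlrem(X, y, beta_sparsity = 0.3)
  X2 <- X; X2[, "x1"] <- X2[, "x1"] * 1000
  m2 <- fit_mlrem(X2, y, beta_sparsity = 0.3)
  expect_equal(predict(m2, X2), predict(m1, X), tolerance = 1e-8)
})

test_that("predict enforces the selected-feature contract", {
  set.seed(5)
  X <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] + rnorm(40, sd = 0.2)
  m <- fit_mlrem(X, y, beta_sparsity = 0.5)
  expect_error(predict(m, X[, "b", drop = FALSE]),
               m$selected_features[1], class = "lipistage_input_error")
  expect_error(fit_mlrem(cbind(a = c(1, NA, 3)), 1:3, 0),
               class = "lipistage_input_error")
})

test_that("constant columns are dropped with a warning", {
  set.seed(6)
  X <- cbind(a = rnorm(30), b = rep(2, 30))
  y <- X[, "a"] + rnorm(30, sd = 0.1)
  expect_warning(m <- fit_mlrem(X, y, beta_sparsity = 0.2), "b")
  expect_false("b" %in% m$selected_features)
})

test_that("post-selection t-tests match hand-computed least squares", {
  X <- matrix(1:4, 4, 1, dimnames = list(NULL, "x"))
  y <- c(2.1, 3.9, 6.2, 7.8)
  tt <- coefficient_ttests(X, y)
  # hand OLS: Sxx = 5, Sxy = 9.70 -> slope 1.94; SSE = 0.082,
  # SE = sqrt((0.082/2)/5) = 0.0906, t = 21.4
  expect_equal(unname(tt$estimate["x"]), 1.94, tolerance = 1e-10)
  expect_equal(unname(tt$se["x"]), 0.09055, tolerance = 1e-3)
  expect_equal(unname(tt$t_stats["x"]), 21.4, tolerance = 5e-3)
  expect_false(tt$exact_fit)
})

test_that("exact fits and orthogonal predictors are flagged correctly", {
  X <- matrix(1:6, 6, 1, dimnames = list(NULL, "x"))
  tt <- coefficient_ttests(X, 2 * (1:6) + 1)
  expect_true(tt$exact_fit)
  expect_equal(unname(tt$se["x"]), 0)
  expect_equal(unname(tt$p_values["x"]), .Machine$double.xmin)

  x <- c(-1, 1, -1, 1); y <- c(-1, -1, 1, 1)
  tt2 <- coefficient_ttests(matrix(x, 4, 1, dimnames = list(NULL, "x")), y)
  expect_equal(unname(tt2$t_stats["x"]), 0)
  expect_equal(unname(tt2$p_values["x"]), 1)
})

test_that("rank-deficient refits drop aliased columns with a warning", {
  set.seed(7)
  x <- rnorm(20)
  X <- cbind(a = x, b = x)
  expect_warning(tt <- coefficient_ttests(X, x + rnorm(20, sd = 0.1)),
                 "aliased")
  expect_length(tt$estimate, 1)
})

test_that("beta selection prefers the smallest beta inside the window", {
  co <- generate_cohort(synthetic_config(seed = 1))
  ds <- cohort_to_design(co)
  sw <- sparsity_sweep(ds$X, ds$y, c(0.1, 0.2, 0.3, 0.4, 0.6, 1.0))
  sel <- choose_beta(sw)
  ns <- vapply(sw$entries, `[[`, numeric(1), "n_selected")
  if (any(ns >= 9 & ns <= 12)) {
    expect_equal(sel$rule, "window")
    expect_true(sel$n_selected >= 9 && sel$n_selected <= 12)
    expect_equal(sel$beta, sw$entries[[which(ns >= 9 & ns <= 12)[1]]]$beta_sparsity)
  } else {
    expect_equal(sel$rule, "penalized_r2")
  }
})

test_that("models serialize to JSON and a coefficient CSV", {
  set.seed(8)
  X <- matrix(rnorm(150), 30, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- X[, 1] - X[, 2] + rnorm(30, sd = 0.3)
  m <- fit_mlrem(X, y, beta_sparsity = 0.3)
  dir <- withr::local_tempdir()
  write_mlrem_json(m, file.path(dir, "m.json"))
  j <- jsonlite::fromJSON(file.path(dir, "m.json"))
  expect_equal(j$beta_sparsity, 0.3)
  expect_setequal(names(j$coefficients), m$selected_features)
  write_coefficient_table(m, file.path(dir, "m.csv"))
  tab <- utils::read.csv(file.path(dir, "m.csv"))
  expect_equal(names(tab), c("feature", "coefficient", "t", "p"))
  expect_equal(nrow(tab), length(m$selected_features))
})
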