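#' Stratified train/test split of a coded dataset
#'
#' Test samples are drawn without replacement within each class:
#' `round(test_frac * n_class)`, but at least one sample per class, from the
#' seeded stream. The partition is a disjoint cover of the dataset.
#'
#' @param dataset a `coded_dataset` from [assemble_design()], or any list
#'   with matrix `X` and vector `y`.
#' @param test_frac test fraction (default 0.2).
#' @param seed integer seed.
#' @return list with `train` and `test` (both `coded_dataset`-shaped),
#'   `test_idx`, and `split_seed`.
#' @export
stratified_split <- function(dataset, test_frac = 0.2, seed = 1) {
  ls_assert(test_frac > 0 && test_frac < 1, "`test_frac` must be in (0, 1)",
            "lipistage_parameter_error")
  y <- dataset$y
  tab <- table(y)
  singletons <- names(tab)[tab < 2]
  ls_assert(length(singletons) == 0,
            sprintf("class(es) with fewer than 2 samples cannot be split: %s",
                    paste(singletons, collapse = ", ")),
            "lipistage_split_error")
  test_idx <- with_preserved_rng({
    set.seed(seed)
    unlist(lapply(sort(unique(y)), function(cl) {
      idx <- which(y == cl)
      n_test <- max(1L, round(test_frac * length(idx)))
      sort(sample(idx, n_test))
    }), use.names = FALSE)
  })
  test_idx <- sort(test_idx)
  subset_ds <- function(idx) {
    out <- dataset
    out$X <- dataset$X[idx, , drop = FALSE]
    out$y <- dataset$y[idx]
    if (!is.null(dataset$sample_ids)) out$sample_ids <- dataset$sample_ids[idx]
    out
  }
  list(train = subset_ds(setdiff(seq_along(y), test_idx)),
       test = subset_ds(test_idx),
       test_idx = test_idx, split_seed = seed)
}

#' Round continuous predictions onto ordinal class codes
#'
#' Each prediction maps to the nearest class code; exact midpoints map to the
#' lower code, and predictions outside the code range are clipped to the
#' nearest end.
#'
#' @param y_hat numeric predictions.
#' @param classes ordered vector of class codes.
#' @return vector of class codes, same length as `y_hat`.
#' @export
round_to_class <- function(y_hat, classes) {
  classes <- sort(unique(classes))
  vapply(y_hat, function(v) {
    d <- abs(classes - v)
    classes[which.min(d)]  # which.min takes the first (lower) code on ties
  }, numeric(1))
}

#' Truth table (confusion matrix) of true vs predicted class codes
#'
#' @param y_true,y_pred vectors of class codes (equal, positive length).
#' @param classes optional ordered code list; defaults to the sorted union.
#' @return a `truth_table`: list with `classes` and the `counts` matrix
#'   (rows = true, columns = predicted).
#' @export
truth_table <- function(y_true, y_pred, classes = NULL) {
  ls_assert(length(y_true) > 0 && length(y_true) == length(y_pred),
            "`y_true` and `y_pred` must be non-empty and equal length",
            "lipistage_input_error")
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  counts <- table(factor(y_true, levels = classes),
                  factor(y_pred, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(true = as.character(classes),
                                   predicted = as.character(classes)))
  structure(list(classes = classes, counts = counts), class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat("<truth_table> true (rows) x predicted (columns)\n")
  print(x$counts)
  invisible(x)
}

#' Write a truth table as CSV with labelled margins
#' @param tt a `truth_table`.
#' @param path output CSV path.
#' @export
write_truth_table <- function(tt, path) {
  df <- as.data.frame(tt$counts)
  df <- cbind(true = rownames(tt$counts), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classification accuracy with a stage tolerance
#'
#' Fraction of samples whose predicted code is within `tolerance` of the true
#' code; `tolerance = 0` is exact accuracy, `tolerance = 1` the one-stage
#' mismatch allowance.
#'
#' @param tt a `truth_table`.
#' @param tolerance non-negative integer tolerance in code units (default 0).
#' @return fraction in \[0, 1\].
#' @export
accuracy <- function(tt, tolerance = 0) {
  ls_assert(tolerance >= 0, "`tolerance` must be non-negative",
            "lipistage_parameter_error")
  codes <- tt$classes
  ok <- abs(outer(codes, codes, "-")) <= tolerance
  sum(tt$counts[ok]) / sum(tt$counts)
}

#' Regression metrics on the continuous prediction scale
#'
#' `r2` is the squared Pearson correlation between truth and prediction
#' (reported 0 with `r2_defined = FALSE` when the predictions are constant);
#' `se` is the root-mean-square prediction error. `r2_sse` additionally
#' reports the 1 - SSE/SST variant.
#'
#' @param y_true,y_hat numeric vectors of equal length.
#' @return list with `r2`, `se`, `r2_sse`, `r2_defined`.
#' @export
regression_metrics <- function(y_true, y_hat) {
  ls_assert(length(y_true) == length(y_hat) && length(y_true) > 1,
            "`y_true` and `y_hat` must be equal length (> 1)",
            "lipistage_input_error")
  se <- sqrt(mean((y_true - y_hat)^2))
  sst <- sum((y_true - mean(y_true))^2)
  r2_sse <- if (sst > 0) 1 - sum((y_true - y_hat)^2) / sst else NA_real_
  if (stats::sd(y_hat) == 0 || stats::sd(y_true) == 0) {
    return(list(r2 = 0, se = se, r2_sse = r2_sse, r2_defined = FALSE))
  }
  list(r2 = stats::cor(y_true, y_hat)^2, se = se, r2_sse = r2_sse,
       r2_defined = TRUE)
}

#' Full evaluation report for train and test partitions
#'
#' Bundles the regression metrics, truth tables and exact / tolerance-1
#' accuracies for continuous predictions on both partitions of a split.
#'
#' @param y_train,yhat_train true codes and continuous predictions, training
#'   partition.
#' @param y_test,yhat_test same for the test partition.
#' @param classes ordered class codes of the scenario.
#' @param split_seed seed used for the split (recorded verbatim).
#' @return an `evaluation_report` list: `r2_train`, `r2_test`, `se_train`,
#'   `se_test`, `truth_train`, `truth_test`, `acc_exact_train/test`,
#'   `acc_tol1_train/test`, `split_seed`.
#' @export
evaluation_report <- function(y_train, yhat_train, y_test, yhat_test,
                              classes, split_seed = NA_integer_) {
  m_tr <- regression_metrics(y_train, yhat_train)
  m_te <- regression_metrics(y_test, yhat_test)
  tt_tr <- truth_table(y_train, round_to_class(yhat_train, classes), classes)
  tt_te <- truth_table(y_test, round_to_class(yhat_test, classes), classes)
  structure(list(
    r2_train = m_tr$r2, r2_test = m_te$r2,
    se_train = m_tr$se, se_test = m_te$se,
    truth_train = tt_tr, truth_test = tt_te,
    acc_exact_train = accuracy(tt_tr, 0), acc_exact_test = accuracy(tt_te, 0),
    acc_tol1_train = accuracy(tt_tr, 1), acc_tol1_test = accuracy(tt_te, 1),
    split_seed = split_seed
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_report> train: r2 = %.3f, SE = %.3f, ",
                     "acc = %.0f%% (+/-1: %.0f%%); test: r2 = %.3f, SE = %.3f, ",
                     "acc = %.0f%% (+/-1: %.0f%%)\n"),
              x$r2_train, x$se_train, 100 * x$acc_exact_train,
              100 * x$acc_tol1_train, x$r2_test, x$se_test,
              100 * x$acc_exact_test, 100 * x$acc_tol1_test))
  invisible(x)
}
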