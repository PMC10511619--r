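#' Scale lipid peak intensities
#'
#' LC-MS peak areas arrive at magnitudes around 1e5-1e6; dividing by a fixed
#' factor (default 100,000) brings them to order unity, which keeps the
#' regularized regression and neural-network fits well conditioned.
#' Missingness is unchanged.
#'
#' @param features a [feature_table()].
#' @param factor positive scaling divisor (default 1e5).
#' @return the scaled [feature_table()].
#' @export
scale_intensities <- function(features, factor = 1e5) {
  ls_assert(is.numeric(factor) && length(factor) == 1 && is.finite(factor) &&
              factor > 0,
            "`factor` must be a positive number", "lipistage_parameter_error")
  feature_table(features$intensities / factor, features$annotations)
}

#' Mask outlying technical replicates
#'
#' For each feature and each replicate group with at least three present
#' values, a value is set missing when its leave-one-out z-score (distance
#' from the mean of the other replicates, in units of their standard
#' deviation) exceeds `k_sd`. Groups with fewer than three present values are
#' left untouched. All z-scores are computed against the original values, so
#' masking does not depend on the order replicates are visited.
#'
#' @param features replicate-level [feature_table()].
#' @param replicate_map named character vector mapping every replicate-row
#'   identifier to its biological sample.
#' @param k_sd z-score threshold (default 3).
#' @return list with `features` (masked table) and `outlier_mask` (logical
#'   matrix of newly masked cells, for audit).
#' @export
mask_replicate_outliers <- function(features, replicate_map, k_sd = 3) {
  check_positive(k_sd, "k_sd")
  unknown <- setdiff(features$sample_ids, names(replicate_map))
  ls_assert(length(unknown) == 0,
            sprintf("sample(s) missing from replicate_map: %s",
                    paste(unknown, collapse = ", ")),
            "lipistage_mapping_error")
  X <- features$intensities
  grp <- replicate_map[features$sample_ids]
  mask <- matrix(FALSE, nrow(X), ncol(X), dimnames = dimnames(X))
  for (g in unique(grp)) {
    rows <- which(grp == g)
    if (length(rows) < 3) next
    sub <- X[rows, , drop = FALSE]
    for (j in seq_len(ncol(sub))) {
      v <- sub[, j]
      present <- which(!is.na(v))
      if (length(present) < 3) next
      for (i in present) {
        others <- v[setdiff(present, i)]
        m <- mean(others)
        s <- stats::sd(others)
        z <- if (s > 0) abs(v[i] - m) / s else if (abs(v[i] - m) > 0) Inf else 0
        if (z > k_sd) mask[rows[i], j] <- TRUE
      }
    }
  }
  X[mask] <- NA_real_
  list(features = feature_table(X, features$annotations), outlier_mask = mask)
}

#' Collapse technical replicates to biological samples
#'
#' One row per biological sample, the mean of the unmasked replicate values;
#' cells whose replicates are all missing become missing.
#'
#' @inheritParams mask_replicate_outliers
#' @return a biological-sample-level [feature_table()] whose row order follows
#'   the first appearance of each biological sample.
#' @export
collapse_replicates <- function(features, replicate_map) {
  unknown <- setdiff(features$sample_ids, names(replicate_map))
  ls_assert(length(unknown) == 0,
            sprintf("sample(s) missing from replicate_map: %s",
                    paste(unknown, collapse = ", ")),
            "lipistage_mapping_error")
  grp <- replicate_map[features$sample_ids]
  bio_ids <- unique(grp)
  X <- features$intensities
  out <- matrix(NA_real_, length(bio_ids), ncol(X),
                dimnames = list(bio_ids, colnames(X)))
  for (b in bio_ids) {
    rows <- X[grp == b, , drop = FALSE]
    m <- colMeans(rows, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    out[b, ] <- m
  }
  feature_table(out, features$annotations)
}

#' Impute missing intensities
#'
#' The default `"feature-mean"` strategy replaces each missing cell with the
#' mean of the present values of that feature, computed over all samples
#' (never per class, so class labels cannot leak into the design matrix).
#' Features with no present values are dropped with a warning.
#'
#' @param features a [feature_table()].
#' @param strategy imputation strategy; only `"feature-mean"` is implemented.
#' @return a [feature_table()] with no missing entries.
#' @export
impute_missing <- function(features, strategy = "feature-mean") {
  ls_assert(identical(strategy, "feature-mean"),
            sprintf("unknown imputation strategy: %s", strategy),
            "lipistage_parameter_error")
  X <- features$intensities
  all_missing <- colSums(!is.na(X)) == 0
  if (any(all_missing)) {
    warning(sprintf("dropping %d feature(s) with no present values: %s",
                    sum(all_missing),
                    paste(colnames(X)[all_missing], collapse = ", ")))
    X <- X[, !all_missing, drop = FALSE]
  }
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[!nas, j])
  }
  ann <- features$annotations
  if (!is.null(ann)) ann <- ann[ann$feature_id %in% colnames(X), , drop = FALSE]
  feature_table(X, ann)
}

#' Code a ternary gene-mutation status numerically
#'
#' Mutation-positive samples are coded +1, mutation-negative -1 and unknown
#' status 0, so that an untested sample exerts no pull on the regression.
#'
#' @param status character vector of `positive` / `negative` / `unknown`
#'   (empty or `NA` treated as unknown).
#' @return integer vector with values -1, 0, +1.
#' @export
code_gene_status <- function(status) {
  status <- as.character(status)
  status[is.na(status) | status == ""] <- "unknown"
  bad <- setdiff(unique(status), c("positive", "negative", "unknown"))
  ls_assert(length(bad) == 0,
            sprintf("unrecognized gene status label(s): %s",
                    paste(bad, collapse = ", ")),
            "lipistage_coding_error")
  unname(c(positive = 1L, negative = -1L, unknown = 0L)[status])
}

scenario_labels <- c("CFI-CRC-CLM", "CFI-CRC", "CFI-mCRC")

#' Assemble the numeric design matrix and ordinal response for a scenario
#'
#' Three modelling scenarios are supported, each with its own ordinal class
#' coding:
#' \describe{
#'   \item{`CFI-CRC-CLM`}{three groups: cancer-free 0, staged CRC 1, liver
#'     metastasis 2.}
#'   \item{`CFI-CRC`}{cancer-free 0 and CRC stages I-IV coded 1-4 (CLM
#'     excluded). Stage-0 CRC samples are excluded by default; set
#'     `include_stage0` to code them 0 alongside the cancer-free group.}
#'   \item{`CFI-mCRC`}{cancer-free 0 versus all diseased samples (CRC of any
#'     stage plus CLM) 1.}
#' }
#' When `include_clinical` is set, age, waist, a 0/1 gender indicator, the
#' chemokine columns and the +1/-1/0 gene codes are appended to the scaled
#' lipid features; continuous clinical columns are z-scored when
#' `standardize_clinical` so they are commensurate with the lipid block.
#'
#' @param study an `aligned_study` from [align()] whose feature table is
#'   already scaled, collapsed and imputed (no missing cells).
#' @param scenario one of `"CFI-CRC-CLM"`, `"CFI-CRC"`, `"CFI-mCRC"`.
#' @param include_clinical append clinical/chemokine/gene columns
#'   (default `FALSE`; the multi-omics scenario typically sets it).
#' @param standardize_clinical z-score continuous clinical columns
#'   (default `TRUE`).
#' @param include_stage0 code stage-0 CRC samples as class 0 in the
#'   `CFI-CRC` scenario instead of excluding them (default `FALSE`).
#' @return a `coded_dataset`: list with `X` (numeric matrix), `y` (ordinal
#'   codes), `feature_names`, `scenario`, `coding_map`, `sample_ids`.
#' @export
assemble_design <- function(study, scenario, include_clinical = FALSE,
                            standardize_clinical = TRUE,
                            include_stage0 = FALSE) {
  ls_assert(scenario %in% scenario_labels,
            sprintf("`scenario` must be one of %s",
                    paste(scenario_labels, collapse = ", ")),
            "lipistage_parameter_error")
  cl <- study$clinical
  X <- study$features$intensities
  ls_assert(!anyNA(X),
            "feature table still has missing cells; impute before assembly",
            "lipistage_assembly_error")

  if (scenario == "CFI-CRC-CLM") {
    keep <- rep(TRUE, nrow(cl))
    y <- c(CFI = 0, CRC = 1, CLM = 2)[cl$group]
    coding_map <- c(CFI = 0, CRC = 1, CLM = 2)
  } else if (scenario == "CFI-CRC") {
    keep <- cl$group == "CFI" |
      (cl$group == "CRC" & !is.na(cl$stage) &
         (cl$stage >= 1 | include_stage0))
    y <- ifelse(cl$group == "CFI", 0, cl$stage)
    coding_map <- c(CFI = 0, `stage-I` = 1, `stage-II` = 2, `stage-III` = 3,
                    `stage-IV` = 4)
  } else {
    keep <- rep(TRUE, nrow(cl))
    y <- ifelse(cl$group == "CFI", 0, 1)
    coding_map <- c(CFI = 0, mCRC = 1)
  }
  y <- unname(y[keep])
  ids <- cl$sample_id[keep]
  X <- X[ids, , drop = FALSE]
  empty <- setdiff(unname(coding_map), y)
  ls_assert(length(empty) == 0,
            sprintf("scenario %s has zero samples in coded class(es): %s",
                    scenario, paste(empty, collapse = ", ")),
            "lipistage_assembly_error")

  if (include_clinical) {
    cls <- cl[keep, , drop = FALSE]
    clin <- list()
    if ("age" %in% names(cls)) clin$age <- as.numeric(cls$age)
    if ("waist_cm" %in% names(cls)) clin$waist_cm <- as.numeric(cls$waist_cm)
    if ("gender" %in% names(cls)) {
      clin$gender_f <- as.numeric(toupper(substr(cls$gender, 1, 1)) == "F")
    }
    for (ck in intersect(c("il8", "pf4", "midkine"), names(cls))) {
      clin[[ck]] <- as.numeric(cls[[ck]])
    }
    for (g in intersect(c("kras", "braf", "mlh1"), names(cls))) {
      clin[[g]] <- as.numeric(code_gene_status(cls[[g]]))
    }
    cm <- do.call(cbind, clin)
    rownames(cm) <- ids
    ls_assert(!anyNA(cm),
              "clinical covariates contain missing values; cannot assemble",
              "lipistage_assembly_error")
    if (standardize_clinical) {
      cont <- intersect(colnames(cm), c("age", "waist_cm", "il8", "pf4",
                                        "midkine"))
      for (col in cont) {
        s <- stats::sd(cm[, col])
        if (s > 0) cm[, col] <- (cm[, col] - mean(cm[, col])) / s
      }
    }
    X <- cbind(X, cm)
  }

  structure(list(X = X, y = y, feature_names = colnames(X),
                 scenario = scenario, coding_map = coding_map,
                 sample_ids = ids),
            class = "coded_dataset")
}

#' @export
print.coded_dataset <- function(x, ...) {
  cat(sprintf("<coded_dataset> scenario %s: %d samples x %d columns, classes {%s}\n",
              x$scenario, nrow(x$X), ncol(x$X),
              paste(sort(unique(x$y)), collapse = ", ")))
  invisible(x)
}
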