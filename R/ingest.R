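#' Construct and validate a lipid feature table
#'
#' A feature table holds the samples-by-features intensity matrix produced by
#' LC-MS peak picking, together with optional per-feature annotations (lipid
#' class such as PS/PE/TG/CE/SM, m/z in Daltons, retention time in minutes,
#' adduct). Intensities are non-negative; missing measurements are `NA`.
#'
#' @param intensities numeric matrix, samples in rows (rownames are sample
#'   identifiers), features in columns (colnames are feature identifiers).
#' @param annotations optional `data.frame` with a `feature_id` column and any
#'   of `lipid_class`, `mz`, `rt`, `adduct`. m/z values, when present, must
#'   lie inside the 140-1300 Da acquisition window.
#' @return an object of class `feature_table` with fields `sample_ids`,
#'   `feature_ids`, `intensities`, `annotations`.
#' @export
feature_table <- function(intensities, annotations = NULL) {
  ls_assert(is.matrix(intensities) && is.numeric(intensities),
            "`intensities` must be a numeric matrix", "lipistage_format_error")
  sample_ids <- rownames(intensities)
  feature_ids <- colnames(intensities)
  ls_assert(!is.null(sample_ids) && !is.null(feature_ids),
            "intensity matrix must carry sample rownames and feature colnames",
            "lipistage_format_error")
  dup_s <- sample_ids[duplicated(sample_ids)]
  ls_assert(length(dup_s) == 0,
            sprintf("duplicate sample identifier(s): %s",
                    paste(unique(dup_s), collapse = ", ")),
            "lipistage_format_error")
  dup_f <- feature_ids[duplicated(feature_ids)]
  ls_assert(length(dup_f) == 0,
            sprintf("duplicate feature identifier(s): %s",
                    paste(unique(dup_f), collapse = ", ")),
            "lipistage_format_error")
  neg <- which(!is.na(intensities) & intensities < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    cells <- apply(neg, 1, function(ij)
      sprintf("[%s, %s]", sample_ids[ij[1]], feature_ids[ij[2]]))
    ls_abort(sprintf("negative intensity at cell(s): %s",
                     paste(utils::head(cells, 10), collapse = ", ")),
             "lipistage_validation_error")
  }
  if (!is.null(annotations)) {
    ls_assert(is.data.frame(annotations) && "feature_id" %in% names(annotations),
              "`annotations` must be a data.frame with a `feature_id` column",
              "lipistage_format_error")
    if ("mz" %in% names(annotations)) {
      mz <- annotations$mz
      bad <- !is.na(mz) & (mz < 140 | mz > 1300)
      ls_assert(!any(bad),
                sprintf("m/z outside the 140-1300 acquisition window for: %s",
                        paste(annotations$feature_id[bad], collapse = ", ")),
                "lipistage_validation_error")
    }
  }
  structure(list(sample_ids = sample_ids, feature_ids = feature_ids,
                 intensities = intensities, annotations = annotations),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features (%d missing cells)\n",
              length(x$sample_ids), length(x$feature_ids),
              sum(is.na(x$intensities))))
  invisible(x)
}

#' Read a feature table from CSV/TSV
#'
#' Expected layout: first column `sample_id`, remaining columns one per lipid
#' feature. Blank cells and literal `NA` become missing values. An optional
#' side-car annotation file (`feature_id,lipid_class,mz,rt,adduct`) is joined
#' by feature identifier.
#'
#' @param path path to the feature CSV/TSV.
#' @param annotations_path optional path to the annotation side-car CSV.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, annotations_path = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  # header read separately so duplicated column names survive for validation
  hdr <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  feats <- hdr[-1]
  dup <- unique(feats[duplicated(feats)])
  ls_assert(length(dup) == 0,
            sprintf("duplicate feature column(s): %s", paste(dup, collapse = ", ")),
            "lipistage_format_error")
  sample_ids <- as.character(df[[1]])
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  ls_assert(length(dup_s) == 0,
            sprintf("duplicate sample identifier(s): %s", paste(dup_s, collapse = ", ")),
            "lipistage_format_error")
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(apply(mat, 2, function(col) any(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))))
    ls_assert(length(bad) == 0,
              sprintf("non-numeric intensity in column(s): %s",
                      paste(feats[bad], collapse = ", ")),
              "lipistage_format_error")
    mat <- matrix(as.numeric(mat), nrow = nrow(mat), dimnames = dimnames(mat))
  }
  rownames(mat) <- sample_ids
  colnames(mat) <- feats
  ann <- NULL
  if (!is.null(annotations_path)) {
    ann <- utils::read.csv(annotations_path, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("", "NA"))
  }
  feature_table(mat, ann)
}

#' Write a feature table (and optionally its annotations) to CSV
#'
#' Missing values are written as empty cells; values round-trip at full
#' double precision.
#'
#' @param ft a [feature_table()].
#' @param path output CSV path.
#' @param annotations_path optional output path for the annotation side-car.
#' @export
write_feature_table <- function(ft, path, annotations_path = NULL) {
  df <- data.frame(sample_id = ft$sample_ids,
                   as.data.frame(ft$intensities, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(format_full_precision(df), path, row.names = FALSE,
                   na = "", quote = FALSE)
  if (!is.null(annotations_path) && !is.null(ft$annotations)) {
    utils::write.csv(ft$annotations, annotations_path, row.names = FALSE,
                     na = "", quote = FALSE)
  }
  invisible(path)
}

# format() loses precision; keep numerics at 17 significant digits
format_full_precision <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      out <- sprintf("%.17g", df[[j]])
      out[is.na(df[[j]])] <- NA
      df[[j]] <- out
    }
  }
  df
}

clinical_columns <- c("sample_id", "group", "stage", "age", "gender",
                      "waist_cm", "il8", "pf4", "midkine", "kras", "braf",
                      "mlh1", "dfs_months", "dfs_event", "os_months",
                      "os_event")

#' Construct and validate a clinical metadata table
#'
#' One row per biological sample: disease group (`CFI` cancer-free, `CRC`
#' staged colorectal cancer, `CLM` liver metastasis), CRC stage (0-4, CRC
#' rows only), demographics, chemokine concentrations (IL-8, PF-4, midkine),
#' ternary gene-mutation statuses (KRAS, BRAF, MLH1; `positive`/`negative`/
#' `unknown`, empty cells read as unknown) and disease-free / overall
#' survival endpoints in months with binary event indicators.
#'
#' @param df data.frame with (a subset of) the documented columns; `sample_id`
#'   and `group` are required.
#' @return the validated data.frame with class `clinical_table`.
#' @export
clinical_table <- function(df) {
  ls_assert(is.data.frame(df) && all(c("sample_id", "group") %in% names(df)),
            "clinical table needs `sample_id` and `group` columns",
            "lipistage_format_error")
  df$sample_id <- as.character(df$sample_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  ls_assert(length(dup) == 0,
            sprintf("duplicate sample identifier(s): %s", paste(dup, collapse = ", ")),
            "lipistage_format_error")
  ls_assert(all(df$group %in% c("CFI", "CRC", "CLM")),
            "`group` must be one of CFI, CRC, CLM",
            "lipistage_validation_error")
  if ("stage" %in% names(df)) {
    has_stage <- !is.na(df$stage)
    bad_grp <- has_stage & df$group != "CRC"
    ls_assert(!any(bad_grp),
              sprintf("stage present for non-CRC sample(s): %s",
                      paste(df$sample_id[bad_grp], collapse = ", ")),
              "lipistage_validation_error")
    ls_assert(all(df$stage[has_stage] %in% 0:4),
              "stage must be an integer in 0..4",
              "lipistage_validation_error")
  }
  for (col in c("dfs_months", "os_months")) {
    if (col %in% names(df)) {
      ls_assert(all(is.na(df[[col]]) | df[[col]] >= 0),
                sprintf("`%s` must be non-negative", col),
                "lipistage_validation_error")
    }
  }
  for (col in c("dfs_event", "os_event")) {
    if (col %in% names(df)) {
      ls_assert(all(is.na(df[[col]]) | df[[col]] %in% c(0, 1)),
                sprintf("`%s` must be 0/1", col),
                "lipistage_validation_error")
    }
  }
  for (g in c("kras", "braf", "mlh1")) {
    if (g %in% names(df)) {
      v <- as.character(df[[g]])
      v[is.na(v) | v == ""] <- "unknown"
      ls_assert(all(v %in% c("positive", "negative", "unknown")),
                sprintf("`%s` status must be positive/negative/unknown", g),
                "lipistage_validation_error")
      df[[g]] <- v
    }
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a clinical metadata table from CSV/TSV
#'
#' @param path path to the clinical CSV/TSV (column contract documented in
#'   [clinical_table()]).
#' @return a validated [clinical_table()].
#' @export
read_clinical_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  numeric_cols <- c("stage", "age", "waist_cm", "il8", "pf4", "midkine",
                    "dfs_months", "dfs_event", "os_months", "os_event")
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v))
    ls_assert(length(bad) == 0,
              sprintf("unparseable numeric in column `%s`, row(s) %s",
                      col, paste(bad, collapse = ", ")),
              "lipistage_format_error")
    df[[col]] <- v
  }
  clinical_table(df)
}

#' Write a clinical table to CSV
#' @param ct a [clinical_table()].
#' @param path output CSV path.
#' @export
write_clinical_table <- function(ct, path) {
  utils::write.csv(format_full_precision(as.data.frame(ct)), path,
                   row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Align feature and clinical tables on their shared samples
#'
#' Both tables are restricted to the intersection of their sample
#' identifiers (case-sensitive exact match) and put in the same order;
#' samples present in only one table are reported in `dropped_samples`.
#'
#' @param features a [feature_table()].
#' @param clinical a [clinical_table()].
#' @return an `aligned_study`: list with `features`, `clinical`,
#'   `dropped_samples`.
#' @export
align <- function(features, clinical) {
  common <- intersect(features$sample_ids, clinical$sample_id)
  ls_assert(length(common) > 0,
            "no sample identifiers shared between feature and clinical tables",
            "lipistage_alignment_error")
  dropped <- union(setdiff(features$sample_ids, common),
                   setdiff(clinical$sample_id, common))
  if (length(dropped) > 0) {
    message(sprintf("align: dropping %d sample(s) present in only one table: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  ft <- feature_table(features$intensities[common, , drop = FALSE],
                      features$annotations)
  cl <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  rownames(cl) <- NULL
  structure(list(features = ft, clinical = clinical_table(as.data.frame(cl)),
                 dropped_samples = dropped),
            class = "aligned_study")
}
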