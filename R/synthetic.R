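#' Configuration for the synthetic cohort generator
#'
#' Describes a synthetic plasma-lipidomics study: per-group sample counts,
#' feature-panel size, how many lipid features carry a planted disease
#' signal, the strength of that signal, measurement noise, missingness and
#' outlier contamination, chemokine and gene-status structure, and
#' class-dependent survival hazards.
#'
#' Intensities are generated log-normally: for sample \eqn{s} and feature
#' \eqn{j}, \eqn{log I(s,j) ~ N(mu0 + e * c(s) * d(j), sigma^2)}
#' where \eqn{mu0} is `baseline_log_mean`, \eqn{e} is `effect_size`,
#' \eqn{d(j)} (one of -1, 0, +1) is the planted direction (0 for uninformative
#' features) and \eqn{c_s} is a graded disease-severity code: 0 for
#' cancer-free (CFI), stage/2 for staged CRC, 2 for liver metastasis (CLM).
#' Planted biomarkers therefore rise (or fall) monotonically with disease
#' severity, both across the three groups and across CRC stages.
#'
#' @param n_per_class named integer vector of biological sample counts, names
#'   from `CFI`, `CRC`, `CLM`. Default mirrors a 66-sample three-group study
#'   (16/32/18).
#' @param n_features number of lipid features (default 333).
#' @param n_informative number of planted discriminative features (default 9).
#' @param effect_size log-scale mean shift per unit severity code
#'   (dimensionless; default 1.0).
#' @param noise_sigma log-normal shape parameter (default 0.5, i.e. roughly a
#'   50 percent coefficient of variation).
#' @param baseline_log_mean location of the log-intensity baseline; the
#'   default `log(5e5)` puts raw peak intensities at the 1e5-1e6 magnitude
#'   typical of Orbitrap peak areas.
#' @param missing_rate fraction of replicate-level cells set missing
#'   (default 0.02).
#' @param outlier_rate fraction of replicate-level cells multiplied by
#'   `outlier_magnitude` (default 0.01).
#' @param outlier_magnitude multiplicative outlier factor > 1 (default 8).
#' @param chemokine_effects named list: per-unit-severity mean shift for each
#'   chemokine column (defaults for `il8`, `pf4`, `midkine`).
#' @param gene_prevalence named list of `c(prob_positive, prob_unknown)` per
#'   gene (defaults for `kras`, `braf`, `mlh1`); probabilities must sum to
#'   at most 1.
#' @param survival_median_months named numeric vector: median disease-free
#'   survival time per group. Overall survival uses twice the group median.
#' @param censor_rate fraction of subjects censored (default 0.3).
#' @param replicate_count technical replicates per biological sample
#'   (default 3).
#' @param seed integer root seed; sub-streams for intensities, chemokines,
#'   genes, survival, missingness and outliers are derived from it so each
#'   component is independently reproducible.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_class = c(CFI = 16, CRC = 32, CLM = 18),
                             n_features = 333,
                             n_informative = 9,
                             effect_size = 1.0,
                             noise_sigma = 0.5,
                             baseline_log_mean = log(5e5),
                             missing_rate = 0.02,
                             outlier_rate = 0.01,
                             outlier_magnitude = 8,
                             chemokine_effects = list(il8 = 8, pf4 = 400,
                                                      midkine = 60),
                             gene_prevalence = list(kras = c(0.40, 0.20),
                                                    braf = c(0.10, 0.30),
                                                    mlh1 = c(0.15, 0.40)),
                             survival_median_months = c(CFI = 120, CRC = 48,
                                                        CLM = 20),
                             censor_rate = 0.3,
                             replicate_count = 3,
                             seed = 1) {
  ls_assert(length(n_per_class) > 0 && !is.null(names(n_per_class)) &&
              all(names(n_per_class) %in% c("CFI", "CRC", "CLM")),
            "`n_per_class` must be named with labels from CFI/CRC/CLM",
            "lipistage_config_error")
  for (g in names(n_per_class)) check_count(n_per_class[[g]],
                                            paste0("n_per_class$", g))
  check_count(n_features, "n_features")
  check_count(n_informative, "n_informative")
  ls_assert(n_informative <= n_features,
            "`n_informative` must not exceed `n_features`",
            "lipistage_config_error")
  ls_assert(is.numeric(effect_size) && is.finite(effect_size) && effect_size >= 0,
            "`effect_size` must be a non-negative number",
            "lipistage_config_error")
  check_positive(noise_sigma, "noise_sigma")
  ls_assert(is.numeric(baseline_log_mean) && is.finite(baseline_log_mean),
            "`baseline_log_mean` must be a finite number",
            "lipistage_config_error")
  check_rate(missing_rate, "missing_rate")
  check_rate(outlier_rate, "outlier_rate")
  ls_assert(is.numeric(outlier_magnitude) && outlier_magnitude > 1,
            "`outlier_magnitude` must be > 1", "lipistage_config_error")
  for (g in names(gene_prevalence)) {
    p <- gene_prevalence[[g]]
    ls_assert(length(p) == 2 && all(p >= 0) && sum(p) <= 1,
              sprintf("`gene_prevalence$%s` must be c(prob_positive, prob_unknown) with sum <= 1", g),
              "lipistage_config_error")
  }
  for (g in names(n_per_class)) {
    ls_assert(g %in% names(survival_median_months) &&
                survival_median_months[[g]] > 0,
              sprintf("`survival_median_months` must give a positive median for class %s", g),
              "lipistage_config_error")
  }
  check_rate(censor_rate, "censor_rate")
  check_count(replicate_count, "replicate_count")
  ls_assert(length(seed) == 1 && is.numeric(seed) && is.finite(seed) &&
              seed == as.integer(seed),
            "`seed` must be an integer", "lipistage_config_error")
  structure(list(
    n_per_class = n_per_class, n_features = n_features,
    n_informative = n_informative, effect_size = effect_size,
    noise_sigma = noise_sigma, baseline_log_mean = baseline_log_mean,
    missing_rate = missing_rate, outlier_rate = outlier_rate,
    outlier_magnitude = outlier_magnitude,
    chemokine_effects = chemokine_effects, gene_prevalence = gene_prevalence,
    survival_median_months = survival_median_months,
    censor_rate = censor_rate, replicate_count = replicate_count,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Read a synthetic-cohort configuration from YAML or JSON
#' @param path a `.yaml`/`.yml` or `.json` file whose keys match the
#'   arguments of [synthetic_config()].
#' @return a validated `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (f in c("n_per_class", "survival_median_months")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(raw$gene_prevalence)) {
    raw$gene_prevalence <- lapply(raw$gene_prevalence, unlist)
  }
  do.call(synthetic_config, raw)
}

# severity code used for planted effects: CFI 0, CRC stage s -> s/2, CLM 2
severity_code <- function(group, stage) {
  ifelse(group == "CFI", 0, ifelse(group == "CLM", 2, stage / 2))
}

with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  expr
}

#' Generate a seeded synthetic cohort
#'
#' Produces a replicate-level lipid [feature_table()], a biological-sample
#' [clinical_table()] (demographics, chemokines, ternary gene statuses,
#' disease-free and overall survival endpoints) and the list of planted
#' discriminative features with their signed directions. Missing values and
#' multiplicative outliers are injected after technical replicates are
#' expanded, so replicate-based outlier masking downstream has something to
#' find. Two calls with the same configuration are bit-identical.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_cohort`: list with `features` (replicate-level rows,
#'   identifiers `<sample>_r<k>` when `replicate_count > 1`), `clinical`,
#'   `replicate_map` (named vector replicate-id -> biological id),
#'   `planted_features` (data.frame `feature_id`, `direction`), `config`.
#' @export
generate_cohort <- function(config) {
  ls_assert(inherits(config, "synthetic_config"),
            "`config` must come from synthetic_config()",
            "lipistage_config_error")
  with_preserved_rng({
    set.seed(config$seed)
    sub <- sample.int(.Machine$integer.max - 1L, 8L)

    ## cohort structure ----------------------------------------------------
    groups <- rep(names(config$n_per_class), times = config$n_per_class)
    n_bio <- length(groups)
    bio_ids <- sprintf("S%03d", seq_len(n_bio))
    stage <- rep(NA_real_, n_bio)
    is_crc <- groups == "CRC"
    stage[is_crc] <- rep_len(1:4, sum(is_crc))
    sev <- severity_code(groups, stage)

    set.seed(sub[1])
    planted_idx <- sort(sample.int(config$n_features, config$n_informative))
    direction <- rep_len(c(1, -1), config$n_informative)
    feature_ids <- sprintf("F%04d", seq_len(config$n_features))
    lipid_classes <- c("PS", "PE", "PC", "TG", "DG", "MG", "CE", "SM", "PA",
                       "FA", "LacCer")
    annotations <- data.frame(
      feature_id = feature_ids,
      lipid_class = sample(lipid_classes, config$n_features, replace = TRUE),
      mz = round(stats::runif(config$n_features, 140, 1300), 4),
      rt = round(stats::runif(config$n_features, 0.5, 20), 2),
      adduct = NA_character_,
      stringsAsFactors = FALSE
    )

    ## lipid intensities (replicate level) ---------------------------------
    dir_vec <- numeric(config$n_features)
    dir_vec[planted_idx] <- direction
    log_mean <- config$baseline_log_mean +
      config$effect_size * outer(sev, dir_vec)       # n_bio x p
    rep_ids <- if (config$replicate_count > 1) {
      as.vector(t(outer(bio_ids, seq_len(config$replicate_count),
                        function(s, k) paste0(s, "_r", k))))
    } else bio_ids
    replicate_map <- stats::setNames(rep(bio_ids, each = config$replicate_count),
                                     rep_ids)
    n_rep <- length(rep_ids)
    set.seed(sub[2])
    log_mean_rep <- log_mean[rep(seq_len(n_bio), each = config$replicate_count), ,
                             drop = FALSE]
    intensities <- exp(log_mean_rep +
                         matrix(stats::rnorm(n_rep * config$n_features,
                                             sd = config$noise_sigma),
                                n_rep, config$n_features))
    dimnames(intensities) <- list(rep_ids, feature_ids)

    ## outliers then missingness, both replicate-level ----------------------
    set.seed(sub[3])
    out_mask <- matrix(stats::runif(n_rep * config$n_features) <
                         config$outlier_rate, n_rep, config$n_features)
    intensities[out_mask] <- intensities[out_mask] * config$outlier_magnitude
    set.seed(sub[4])
    na_mask <- matrix(stats::runif(n_rep * config$n_features) <
                        config$missing_rate, n_rep, config$n_features)
    intensities[na_mask] <- NA_real_

    ## demographics ---------------------------------------------------------
    set.seed(sub[5])
    age_rng <- list(CFI = c(34, 82), CRC = c(38, 89), CLM = c(42, 81))
    p_female <- c(CFI = 0.63, CRC = 0.41, CLM = 0.50)
    waist_med <- c(CFI = 108, CRC = 111, CLM = 94)
    age <- vapply(groups, function(g)
      round(stats::runif(1, age_rng[[g]][1], age_rng[[g]][2])), numeric(1))
    gender <- vapply(groups, function(g)
      if (stats::runif(1) < p_female[[g]]) "F" else "M", character(1))
    waist <- round(pmin(141, pmax(70, stats::rnorm(n_bio, waist_med[groups], 10))))

    ## chemokines -----------------------------------------------------------
    set.seed(sub[6])
    chem_base <- c(il8 = 15, pf4 = 2000, midkine = 300)
    chem_sd <- c(il8 = 5, pf4 = 500, midkine = 100)
    chem <- lapply(names(config$chemokine_effects), function(nm) {
      base <- if (nm %in% names(chem_base)) chem_base[[nm]] else 100
      sdv <- if (nm %in% names(chem_sd)) chem_sd[[nm]] else 20
      pmax(0, base + config$chemokine_effects[[nm]] * sev +
             stats::rnorm(n_bio, sd = sdv))
    })
    names(chem) <- names(config$chemokine_effects)

    ## gene statuses --------------------------------------------------------
    set.seed(sub[7])
    genes <- lapply(names(config$gene_prevalence), function(g) {
      p <- config$gene_prevalence[[g]]
      sample(c("positive", "unknown", "negative"), n_bio, replace = TRUE,
             prob = c(p[1], p[2], 1 - p[1] - p[2]))
    })
    names(genes) <- names(config$gene_prevalence)

    ## survival endpoints ---------------------------------------------------
    # exponential event times anchored at the group median, graded within
    # CRC by stage severity (stage IV shorter than stage I) so stage-wise
    # curves separate; the group-level median stays at its anchor
    set.seed(sub[8])
    mean_sev <- c(CFI = 0, CRC = 1.25, CLM = 2)
    med <- config$survival_median_months[groups] *
      2^(mean_sev[groups] - sev)
    dfs_t <- stats::rexp(n_bio, rate = log(2) / med)
    os_t <- stats::rexp(n_bio, rate = log(2) / (2 * med))
    dfs_e <- stats::rbinom(n_bio, 1, 1 - config$censor_rate)
    os_e <- stats::rbinom(n_bio, 1, 1 - config$censor_rate)
    cens_frac <- stats::runif(n_bio)
    dfs_t <- ifelse(dfs_e == 1, dfs_t, dfs_t * cens_frac)
    os_t <- ifelse(os_e == 1, os_t, os_t * cens_frac)

    clinical <- clinical_table(data.frame(
      sample_id = bio_ids, group = groups, stage = stage, age = age,
      gender = gender, waist_cm = waist,
      il8 = chem$il8 %||% NA_real_, pf4 = chem$pf4 %||% NA_real_,
      midkine = chem$midkine %||% NA_real_,
      kras = genes$kras %||% "unknown", braf = genes$braf %||% "unknown",
      mlh1 = genes$mlh1 %||% "unknown",
      dfs_months = round(dfs_t, 2), dfs_event = dfs_e,
      os_months = round(os_t, 2), os_event = os_e,
      stringsAsFactors = FALSE
    ))

    structure(list(
      features = feature_table(intensities, annotations),
      clinical = clinical,
      replicate_map = replicate_map,
      planted_features = data.frame(feature_id = feature_ids[planted_idx],
                                    direction = direction,
                                    stringsAsFactors = FALSE),
      config = config
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d biological samples (%s), %d features, %d planted\n",
              nrow(x$clinical),
              paste(sprintf("%s=%d", names(x$config$n_per_class),
                            x$config$n_per_class), collapse = ", "),
              length(x$features$feature_ids), nrow(x$planted_features)))
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Emits `features.csv`, `annotations.csv`, `clinical.csv`,
#' `replicate_map.csv` and `planted_features.csv` in `dir`, in the column
#' layouts read back by [read_feature_table()] and [read_clinical_table()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(cohort$features, file.path(dir, "features.csv"),
                      file.path(dir, "annotations.csv"))
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.csv"))
  utils::write.csv(data.frame(replicate_id = names(cohort$replicate_map),
                              sample_id = unname(cohort$replicate_map)),
                   file.path(dir, "replicate_map.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(cohort$planted_features,
                   file.path(dir, "planted_features.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
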