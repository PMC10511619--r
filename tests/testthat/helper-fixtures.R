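# Shared fixtures and independent oracles used across test files.

# small three-group cohort configuration that keeps generation cheap
small_cohort_config <- function(seed = 1, ...) {
  synthetic_config(n_per_class = c(CFI = 8, CRC = 12, CLM = 8),
                   n_features = 40, n_informative = 5, seed = seed, ...)
}

# feature table built in code: 3 samples x 2 features with one missing cell
tiny_feature_table <- function() {
  m <- matrix(c(1, 2, 3, 4, NA, 6), nrow = 3,
              dimnames = list(c("S1", "S2", "S3"), c("FA", "FB")))
  feature_table(m)
}

tiny_clinical <- function(ids = c("S1", "S2", "S3"),
                          groups = c("CFI", "CRC", "CLM"),
                          stages = c(NA, 2, NA)) {
  clinical_table(data.frame(sample_id = ids, group = groups, stage = stages,
                            dfs_months = c(10, 20, 30), dfs_event = c(1, 1, 0),
                            os_months = c(12, 25, 35), os_event = c(1, 0, 0),
                            stringsAsFactors = FALSE))
}

# Independent product-limit oracle: explicit risk-set loop, events before
# censorings at tied times.
km_oracle <- function(times, events) {
  ev_times <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = ev_times, survival = NA_real_,
                    n_at_risk = NA_real_, n_events = NA_real_)
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_i <- sum(times >= t)          # censored at t still at risk for event at t
    d_i <- sum(times == t & events == 1)
    s <- s * (1 - d_i / n_i)
    out$survival[i] <- s
    out$n_at_risk[i] <- n_i
    out$n_events[i] <- d_i
  }
  out
}

# preprocess a synthetic cohort with package defaults up to the design matrix
cohort_to_design <- function(cohort, scenario = "CFI-CRC-CLM",
                             include_clinical = identical(scenario, "CFI-mCRC")) {
  ft <- scale_intensities(cohort$features)
  ft <- mask_replicate_outliers(ft, cohort$replicate_map)$features
  ft <- collapse_replicates(ft, cohort$replicate_map)
  ft <- impute_missing(ft)
  assemble_design(align(ft, cohort$clinical), scenario,
                  include_clinical = include_clinical)
}
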