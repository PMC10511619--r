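#' Kaplan-Meier product-limit estimate
#'
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over the distinct event
#' times \eqn{t_i}, with censored observations reducing the risk sets only.
#' Ties between events and censorings at the same time are resolved events
#' first (the standard convention). Greenwood standard errors accompany the
#' curve.
#'
#' @param times non-negative follow-up times (months).
#' @param events 0/1 event indicators (1 = event, 0 = censored).
#' @return a `km_curve`: data.frame `curve` with columns `time`, `n_at_risk`,
#'   `n_events`, `survival`, `std_err` (event times only), plus
#'   `censor_times` and `n`.
#' @export
km_estimate <- function(times, events) {
  ls_assert(length(times) == length(events) && length(times) > 0,
            "`times` and `events` must be non-empty and equal length",
            "lipistage_input_error")
  ls_assert(all(times >= 0), "negative follow-up time",
            "lipistage_input_error")
  ls_assert(all(events %in% c(0, 1)), "`events` must be 0/1",
            "lipistage_input_error")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  curve <- data.frame(time = fit$time[keep],
                      n_at_risk = fit$n.risk[keep],
                      n_events = fit$n.event[keep],
                      survival = fit$surv[keep],
                      std_err = fit$surv[keep] * fit$std.err[keep])
  structure(list(curve = curve,
                 censor_times = sort(times[events == 0]),
                 n = length(times)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#' @param km a `km_curve`.
#' @param at numeric times.
#' @return survival probabilities (1 before the first event).
#' @export
km_survival_at <- function(km, at) {
  vapply(at, function(t) {
    i <- which(km$curve$time <= t)
    if (length(i) == 0) 1 else km$curve$survival[max(i)]
  }, numeric(1))
}

#' KM median survival time
#' @param km a `km_curve`.
#' @return the smallest event time with survival <= 0.5, or `NA` if the curve
#'   never falls that far.
#' @export
km_median <- function(km) {
  i <- which(km$curve$survival <= 0.5)
  if (length(i) == 0) NA_real_ else km$curve$time[min(i)]
}

#' Log-rank test across two or more groups
#'
#' Observed-minus-expected events over the shared risk sets; the statistic is
#' chi-squared with groups - 1 degrees of freedom. A degenerate input (no
#' events anywhere) is flagged and reported as chi2 = 0, p = 1.
#'
#' @param groups named list; each element a list/data.frame with `times` and
#'   `events`.
#' @return a `logrank_result`: `chi2`, `df`, `p`, `degenerate`.
#' @export
logrank_test <- function(groups) {
  ls_assert(length(groups) >= 2, "need at least two groups",
            "lipistage_input_error")
  ns <- vapply(groups, function(g) length(g$times), numeric(1))
  ls_assert(all(ns >= 1), "every group needs at least one subject",
            "lipistage_input_error")
  times <- unlist(lapply(groups, `[[`, "times"), use.names = FALSE)
  events <- unlist(lapply(groups, `[[`, "events"), use.names = FALSE)
  labels <- rep(names(groups) %||% seq_along(groups), times = ns)
  if (sum(events) == 0) {
    return(structure(list(chi2 = 0, df = length(groups) - 1L, p = 1,
                          degenerate = TRUE), class = "logrank_result"))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ labels)
  df <- length(groups) - 1L
  chi2 <- unname(sd$chisq)
  structure(list(chi2 = chi2, df = df,
                 p = max(stats::pchisq(chi2, df, lower.tail = FALSE),
                         .Machine$double.xmin),
                 degenerate = FALSE),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chi2 = %.3f on %d df, p = %.4g%s\n",
              x$chi2, x$df, x$p,
              if (x$degenerate) " [degenerate: no events]" else ""))
  invisible(x)
}

#' Survival curves and log-rank test by disease group
#'
#' One Kaplan-Meier curve per disease group — CRC samples split by stage
#' (`stage-0` ... `stage-IV`) and liver-metastasis samples as their own
#' `CLM` group; cancer-free samples are excluded since recurrence endpoints
#' are not defined for them. Disease-free survival is administratively
#' censored at 60 months and overall survival at 96 months by default, and a
#' patients-at-risk table is reported at 12-month ticks.
#'
#' @param clinical a [clinical_table()] with the endpoint columns.
#' @param endpoint `"dfs"` or `"os"`.
#' @param horizon_months administrative censoring horizon; default 60 for
#'   DFS, 96 for OS. `Inf` disables it.
#' @param by `"stage"` (default, stages + CLM) or `"group"` (CFI/CRC/CLM).
#' @return a `survival_by_group` list: `curves` (named `km_curve`s),
#'   `logrank` (`logrank_result`, `NULL` for a single group), `at_risk`
#'   (groups x yearly ticks matrix), `endpoint`, `horizon_months`.
#' @export
survival_by_group <- function(clinical, endpoint = c("dfs", "os"),
                              horizon_months = NULL, by = c("stage", "group")) {
  endpoint <- match.arg(endpoint)
  by <- match.arg(by)
  tcol <- paste0(endpoint, "_months")
  ecol <- paste0(endpoint, "_event")
  missing_cols <- setdiff(c(tcol, ecol), names(clinical))
  ls_assert(length(missing_cols) == 0,
            sprintf("clinical table lacks endpoint column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "lipistage_input_error")
  horizon <- horizon_months %||% if (endpoint == "dfs") 60 else 96

  cl <- as.data.frame(clinical)
  if (by == "stage") {
    cl <- cl[cl$group != "CFI", , drop = FALSE]
    roman <- c("0", "I", "II", "III", "IV")
    lab <- ifelse(cl$group == "CLM", "CLM",
                  paste0("stage-", roman[cl$stage + 1]))
  } else {
    lab <- cl$group
  }
  keep <- !is.na(cl[[tcol]]) & !is.na(cl[[ecol]])
  cl <- cl[keep, , drop = FALSE]
  lab <- lab[keep]
  ls_assert(nrow(cl) > 0, "no samples with the requested endpoint",
            "lipistage_input_error")

  t_obs <- pmin(cl[[tcol]], horizon)
  e_obs <- ifelse(cl[[tcol]] > horizon, 0, cl[[ecol]])

  labels <- unique(lab)
  labels <- labels[order(match(labels, c(paste0("stage-", c("0", "I", "II",
                                                            "III", "IV")),
                                         "CLM", "CFI", "CRC")))]
  curves <- lapply(labels, function(g)
    km_estimate(t_obs[lab == g], e_obs[lab == g]))
  names(curves) <- labels

  ticks <- seq(0, if (is.finite(horizon)) horizon else max(t_obs), by = 12)
  at_risk <- t(vapply(labels, function(g) {
    tg <- t_obs[lab == g]
    vapply(ticks, function(tk) sum(tg >= tk), numeric(1))
  }, numeric(length(ticks))))
  dimnames(at_risk) <- list(labels, paste0("m", ticks))

  lr <- if (length(labels) >= 2) {
    logrank_test(stats::setNames(lapply(labels, function(g)
      list(times = t_obs[lab == g], events = e_obs[lab == g])), labels))
  } else NULL

  structure(list(curves = curves, logrank = lr, at_risk = at_risk,
                 endpoint = endpoint, horizon_months = horizon),
            class = "survival_by_group")
}

#' Write a KM curve as CSV
#' @param km a `km_curve`.
#' @param path output CSV path.
#' @export
write_km_curve <- function(km, path) {
  utils::write.csv(km$curve, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
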