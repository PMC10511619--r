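#' Sparse multiple linear regression with EM feature pruning (MLR-EM)
#'
#' Fits a linear model of the ordinal class code on the feature columns under
#' a Laplacian (double-exponential) prior on the weights, solved by the EM /
#' majorize-minimize scheme that makes the prior tractable: at iteration
#' \eqn{t} the weights solve the reweighted ridge system
#' \deqn{(X^T X / n + \beta D^{(t)})\, w = X^T y / n, \qquad
#'       D^{(t)} = \mathrm{diag}\big(1 / \max(|w_i^{(t)}|, \epsilon)\big),}
#' so small weights feel an ever-stiffer penalty and collapse to zero.
#' The penalty is applied per sample (the \eqn{1/n} normalization), which
#' makes \eqn{\beta} comparable across sample sizes and puts its useful range
#' at order 0.1-1 for cohorts of this kind. Features whose weight magnitude
#' falls below `prune_tol` are removed from the active set permanently; the
#' sparsity coefficient `beta_sparsity` (the method's \eqn{\beta}) controls
#' how aggressively the panel shrinks — larger \eqn{\beta}, fewer surviving
#' features. With \eqn{\beta = 0} the fixed point is ordinary least squares
#' on the full active set.
#'
#' Iteration stops when the weights converge (`conv_tol`) or when the active
#' set has been stable for `stable_iters` consecutive iterations. The second
#' rule matters: this is a feature-selection method, and once the panel has
#' stabilized, further reweighting only erodes groups of correlated
#' informative features in favour of a single representative (the usual
#' winner-take-all endpoint of an L1 penalty). Stopping on panel stability
#' keeps correlated biomarkers together while noise features — which collapse
#' within a few iterations — are still eliminated.
#'
#' Columns are z-scored and the response centred internally; reported
#' coefficients live on the standardized scale (use
#' `coef(model, scale = "raw")` for the raw-scale back-transform). Constant
#' columns are dropped with a warning. The fitter is fully deterministic.
#' Per-coefficient t and p values come from an unpenalized least-squares
#' refit on the final selected set (see [coefficient_ttests()]); they are
#' nominal, not selection-adjusted.
#'
#' @param X numeric matrix (samples x features) with column names.
#' @param y numeric response (ordinal class codes).
#' @param beta_sparsity non-negative sparsity coefficient (default 0.4).
#' @param prune_tol weight magnitude below which a feature is pruned, on the
#'   standardized scale (default 1e-6).
#' @param conv_tol convergence threshold on the maximum weight change
#'   (default 1e-8).
#' @param max_iter iteration cap (default 500).
#' @param stable_iters stop after this many consecutive iterations without a
#'   pruning event (default 10).
#' @return an object of class `sparse_linear_model`: intercept, named
#'   `coefficients` (standardized scale, selected features only),
#'   `beta_sparsity`, `n_iterations`, `converged`, `selected_features`,
#'   `t_stats`, `p_values`, `train_r2`, `train_se`, standardization constants
#'   `column_means` / `column_sds`, and a `degenerate` flag for the
#'   intercept-only fallback when every feature prunes away.
#' @export
fit_mlrem <- function(X, y, beta_sparsity = 0.4, prune_tol = 1e-6,
                      conv_tol = 1e-8, max_iter = 500, stable_iters = 10) {
  ls_assert(is.matrix(X) && is.numeric(X), "`X` must be a numeric matrix",
            "lipistage_input_error")
  ls_assert(all(is.finite(X)), "non-finite values in `X`",
            "lipistage_input_error")
  ls_assert(all(is.finite(y)) && length(y) == nrow(X),
            "`y` must be finite and match nrow(X)", "lipistage_input_error")
  ls_assert(nrow(X) >= 3, "need at least 3 samples", "lipistage_input_error")
  ls_assert(is.numeric(beta_sparsity) && beta_sparsity >= 0,
            "`beta_sparsity` must be non-negative", "lipistage_parameter_error")
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))

  std <- standardize_columns(X)
  if (any(std$constant)) {
    warning(sprintf("dropping %d constant column(s): %s", sum(std$constant),
                    paste(colnames(X)[std$constant], collapse = ", ")))
  }
  keep0 <- !std$constant
  Z <- std$Z[, keep0, drop = FALSE]
  ybar <- mean(y)
  yc <- y - ybar
  eps <- 1e-9
  n <- nrow(Z)

  solve_system <- function(Zk, w_abs, beta) {
    # (Z'Z/n + beta D) w = Z'y/n with D = diag(1/max(|w|, eps)); equivalent
    # to the unnormalized system with penalty n * beta. Woodbury identity
    # when the active set is wider than the sample count.
    p <- ncol(Zk)
    if (beta == 0) {
      return(qr.coef(qr(Zk, LAPACK = TRUE), yc))
    }
    d <- 1 / pmax(w_abs, eps)
    beta_n <- n * beta
    if (p <= n) {
      A <- crossprod(Zk)
      diag(A) <- diag(A) + beta_n * d
      drop(solve(A, crossprod(Zk, yc)))
    } else {
      b <- 1 / (beta_n * d)                   # diagonal of D^{-1} / (n beta)
      ZB <- sweep(Zk, 2, b, "*")
      M <- diag(n) + tcrossprod(ZB, Zk)       # I + Z B Z'
      drop(b * crossprod(Zk, solve(M, yc)))
    }
  }

  degenerate <- FALSE
  active <- colnames(Z)
  if (length(active) == 0) {
    degenerate <- TRUE
    w <- numeric(0)
    iter <- 0L
    converged <- TRUE
  } else {
    # deterministic ridge initialization, penalty beta * I (per sample)
    w <- if (beta_sparsity == 0) {
      solve_system(Z, NULL, 0)
    } else {
      A <- crossprod(Z)
      diag(A) <- diag(A) + n * beta_sparsity
      drop(solve(A, crossprod(Z, yc)))
    }
    names(w) <- active
    converged <- FALSE
    iter <- 0L
    since_prune <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      Zk <- Z[, active, drop = FALSE]
      w_new <- solve_system(Zk, abs(w[active]), beta_sparsity)
      names(w_new) <- active
      if (anyNA(w_new)) {
        ls_abort("singular system in MLR-EM update (rank-deficient design at beta = 0)",
                 "lipistage_input_error")
      }
      delta <- max(abs(w_new - w[active]))
      keep <- abs(w_new) >= prune_tol
      pruned_now <- any(!keep)
      w <- w_new[keep]
      active <- active[keep]
      if (length(active) == 0) {
        degenerate <- TRUE
        converged <- TRUE
        break
      }
      since_prune <- if (pruned_now) 0L else since_prune + 1L
      if (!pruned_now && delta < conv_tol) {
        converged <- TRUE
        break
      }
      if (since_prune >= stable_iters) {
        converged <- TRUE
        break
      }
    }
  }

  if (degenerate) {
    model <- structure(list(
      intercept = ybar, coefficients = stats::setNames(numeric(0), character(0)),
      beta_sparsity = beta_sparsity, n_iterations = iter, converged = converged,
      selected_features = character(0),
      t_stats = stats::setNames(numeric(0), character(0)),
      p_values = stats::setNames(numeric(0), character(0)),
      train_r2 = 0, train_se = sqrt(mean(yc^2)),
      column_means = std$mean, column_sds = std$sd,
      degenerate = TRUE, exact_fit = FALSE
    ), class = "sparse_linear_model")
    return(model)
  }

  Zsel <- Z[, active, drop = FALSE]
  fitted <- ybar + drop(Zsel %*% w)
  tt <- if (nrow(Zsel) > length(active) + 1) {
    coefficient_ttests(Zsel, y)
  } else {
    list(t_stats = stats::setNames(rep(NA_real_, length(active)), active),
         p_values = stats::setNames(rep(NA_real_, length(active)), active),
         exact_fit = FALSE)
  }
  r2 <- if (stats::sd(fitted) > 0) stats::cor(y, fitted)^2 else 0

  structure(list(
    intercept = ybar, coefficients = w, beta_sparsity = beta_sparsity,
    n_iterations = iter, converged = converged, selected_features = active,
    t_stats = tt$t_stats[active], p_values = tt$p_values[active],
    train_r2 = r2, train_se = sqrt(mean((y - fitted)^2)),
    column_means = std$mean, column_sds = std$sd,
    degenerate = FALSE, exact_fit = isTRUE(tt$exact_fit)
  ), class = "sparse_linear_model")
}

#' @export
print.sparse_linear_model <- function(x, ...) {
  cat(sprintf("<sparse_linear_model> beta = %g, %d feature(s) selected%s, train r2 = %.3f, SE = %.3f\n",
              x$beta_sparsity, length(x$selected_features),
              if (x$degenerate) " (degenerate: intercept only)" else "",
              x$train_r2, x$train_se))
  invisible(x)
}

#' Coefficients of a sparse linear model
#' @param object a `sparse_linear_model`.
#' @param scale `"standardized"` (as fitted) or `"raw"` to back-transform to
#'   the original column units.
#' @param ... unused.
#' @export
coef.sparse_linear_model <- function(object, scale = c("standardized", "raw"),
                                     ...) {
  scale <- match.arg(scale)
  w <- object$coefficients
  if (scale == "standardized" || length(w) == 0) return(w)
  sds <- object$column_sds[names(w)]
  w / sds
}

#' Predict from a sparse linear model
#'
#' Applies the stored standardization and linear form. Predictions are
#' continuous; rounding onto class codes is the evaluation module's job
#' ([round_to_class()]).
#'
#' @param object a `sparse_linear_model`.
#' @param X_new numeric matrix containing (at least) the selected feature
#'   columns, matched by name.
#' @param ... unused.
#' @return numeric prediction vector.
#' @export
predict.sparse_linear_model <- function(object, X_new, ...) {
  ls_assert(is.matrix(X_new) && is.numeric(X_new),
            "`X_new` must be a numeric matrix", "lipistage_input_error")
  if (length(object$selected_features) == 0) {
    return(rep(object$intercept, nrow(X_new)))
  }
  if (is.null(colnames(X_new))) colnames(X_new) <- sprintf("V%d", seq_len(ncol(X_new)))
  missing_cols <- setdiff(object$selected_features, colnames(X_new))
  ls_assert(length(missing_cols) == 0,
            sprintf("X_new is missing selected feature column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "lipistage_input_error")
  sel <- object$selected_features
  Z <- sweep(X_new[, sel, drop = FALSE], 2, object$column_means[sel], "-")
  Z <- sweep(Z, 2, object$column_sds[sel], "/")
  object$intercept + drop(Z %*% object$coefficients)
}

#' Sweep the sparsity coefficient over a grid
#'
#' One [fit_mlrem()] per value of \eqn{\beta}; because standardization is a
#' deterministic function of `X`, all fits share the same standardized
#' design. Surviving-feature counts typically fall as \eqn{\beta} rises.
#'
#' @inheritParams fit_mlrem
#' @param betas strictly increasing vector of non-negative sparsity values.
#' @return a `sparsity_sweep_result`: list of entries
#'   `(beta_sparsity, n_selected, model)`.
#' @export
sparsity_sweep <- function(X, y, betas, prune_tol = 1e-6, conv_tol = 1e-8,
                           max_iter = 500, stable_iters = 10) {
  ls_assert(length(betas) > 0 && all(betas >= 0) &&
              (length(betas) == 1 || all(diff(betas) > 0)),
            "`betas` must be non-empty, non-negative and strictly increasing",
            "lipistage_parameter_error")
  entries <- lapply(betas, function(b) {
    m <- fit_mlrem(X, y, beta_sparsity = b, prune_tol = prune_tol,
                   conv_tol = conv_tol, max_iter = max_iter,
                   stable_iters = stable_iters)
    list(beta_sparsity = b, n_selected = length(m$selected_features), model = m)
  })
  structure(list(entries = entries), class = "sparsity_sweep_result")
}

#' @export
print.sparsity_sweep_result <- function(x, ...) {
  for (e in x$entries) {
    cat(sprintf("  beta = %-6g -> %d feature(s)%s\n", e$beta_sparsity,
                e$n_selected, if (e$model$degenerate) " [degenerate]" else ""))
  }
  invisible(x)
}

#' Choose a sparsity value from a sweep
#'
#' Default rule: the smallest \eqn{\beta} whose selected-panel size falls
#' inside `window` (biomarker panels of roughly 9-12 readouts are the
#' practical sweet spot for this class of study); if no \eqn{\beta}
#' qualifies, fall back to the entry maximizing training r-squared minus
#' `size_penalty` per selected feature.
#'
#' @param sweep a `sparsity_sweep_result`.
#' @param window advisory `c(min, max)` panel size (default `c(9, 12)`).
#' @param size_penalty r-squared penalty per selected feature used by the
#'   fallback (default 0.005).
#' @return list with `beta`, `model`, `n_selected`, `rule` (`"window"` or
#'   `"penalized_r2"`).
#' @export
choose_beta <- function(sweep, window = c(9, 12), size_penalty = 0.005) {
  ns <- vapply(sweep$entries, function(e) e$n_selected, numeric(1))
  in_win <- which(ns >= window[1] & ns <= window[2])
  if (length(in_win) > 0) {
    e <- sweep$entries[[in_win[1]]]
    return(list(beta = e$beta_sparsity, model = e$model,
                n_selected = e$n_selected, rule = "window"))
  }
  score <- vapply(sweep$entries, function(e)
    e$model$train_r2 - size_penalty * e$n_selected, numeric(1))
  e <- sweep$entries[[which.max(score)]]
  list(beta = e$beta_sparsity, model = e$model, n_selected = e$n_selected,
       rule = "penalized_r2")
}

#' Post-selection t-tests for a set of predictors
#'
#' Unpenalized least-squares refit with intercept; standard errors from the
#' residual variance times the diagonal of the inverse normal-equations
#' matrix, t = estimate / SE, two-sided p from Student's t with n - k - 1
#' degrees of freedom. An exact fit (zero residual variance) reports SE 0
#' and the smallest representable p, flagged `exact_fit`. Rank-deficient
#' designs drop the aliased columns with a warning.
#'
#' @param X_selected numeric matrix of the selected predictor columns.
#' @param y numeric response.
#' @return list with named `estimate`, `se`, `t_stats`, `p_values`,
#'   `df`, and flag `exact_fit`.
#' @export
coefficient_ttests <- function(X_selected, y) {
  ls_assert(is.matrix(X_selected) && is.numeric(X_selected),
            "`X_selected` must be a numeric matrix", "lipistage_input_error")
  k <- ncol(X_selected)
  n <- nrow(X_selected)
  ls_assert(n > k + 1, "need n_samples > n_selected + 1 for t-tests",
            "lipistage_input_error")
  if (is.null(colnames(X_selected)))
    colnames(X_selected) <- sprintf("V%d", seq_len(k))
  Xd <- cbind(`(Intercept)` = 1, X_selected)
  q <- qr(Xd)
  if (q$rank < ncol(Xd)) {
    aliased <- colnames(Xd)[q$pivot[(q$rank + 1):ncol(Xd)]]
    warning(sprintf("dropping aliased column(s): %s",
                    paste(aliased, collapse = ", ")))
    X_selected <- X_selected[, setdiff(colnames(X_selected), aliased),
                             drop = FALSE]
    Xd <- cbind(`(Intercept)` = 1, X_selected)
    q <- qr(Xd)
    k <- ncol(X_selected)
  }
  beta_hat <- qr.coef(q, y)
  res <- y - drop(Xd %*% beta_hat)
  df <- n - k - 1
  sse <- sum(res^2)
  xtx_inv <- chol2inv(qr.R(q))
  dimnames(xtx_inv) <- list(colnames(Xd), colnames(Xd))
  exact <- sse < max(1e-20, 1e-12 * sum((y - mean(y))^2))
  if (exact) {
    se <- stats::setNames(rep(0, k), colnames(X_selected))
    est <- beta_hat[colnames(X_selected)]
    t_stats <- ifelse(est == 0, 0, sign(est) * Inf)
    p_values <- ifelse(est == 0, 1, .Machine$double.xmin)
    names(t_stats) <- names(p_values) <- colnames(X_selected)
  } else {
    sigma2 <- sse / df
    se_all <- sqrt(sigma2 * diag(xtx_inv))
    est <- beta_hat[colnames(X_selected)]
    se <- se_all[colnames(X_selected)]
    t_stats <- est / se
    t_stats[se == 0] <- 0
    p_values <- 2 * stats::pt(-abs(t_stats), df)
    p_values <- pmin(pmax(p_values, .Machine$double.xmin), 1)
  }
  list(estimate = est, se = se, t_stats = t_stats, p_values = p_values,
       df = df, exact_fit = exact)
}

#' Serialize a sparse linear model to JSON
#' @param model a `sparse_linear_model`.
#' @param path output path.
#' @export
write_mlrem_json <- function(model, path) {
  jsonlite::write_json(list(
    type = "sparse_linear_model",
    beta_sparsity = model$beta_sparsity,
    intercept = model$intercept,
    selected_features = model$selected_features,
    coefficients = as.list(model$coefficients),
    t_stats = as.list(model$t_stats),
    p_values = as.list(model$p_values),
    train_r2 = model$train_r2, train_se = model$train_se,
    column_means = as.list(model$column_means[model$selected_features]),
    column_sds = as.list(model$column_sds[model$selected_features]),
    degenerate = model$degenerate, converged = model$converged,
    n_iterations = model$n_iterations
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export the selected-feature coefficient table as CSV
#'
#' Columns `feature, coefficient, t, p` — the tabular companion to the
#' coefficient histogram a modelling report shows per panel.
#'
#' @param model a `sparse_linear_model`.
#' @param path output CSV path.
#' @export
write_coefficient_table <- function(model, path) {
  df <- data.frame(feature = model$selected_features,
                   coefficient = unname(model$coefficients),
                   t = unname(model$t_stats),
                   p = unname(model$p_values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
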