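#' Bayesian-regularized neural network regression (BRANN)
#'
#' Single-hidden-layer network (tanh hidden units, linear output) regressing
#' the ordinal class code on a feature subset, with weight decay set by the
#' Bayesian evidence framework rather than a validation set. The training
#' objective is
#' \deqn{F(w) = \beta_n E_D + \alpha E_W, \quad E_D = \sum_i (y_i - f(x_i; w))^2,
#'       \quad E_W = \tfrac{1}{2} \sum_k w_k^2,}
#' minimized by damped Gauss-Newton (Levenberg-Marquardt) steps. After each
#' accepted step the hyperparameters are re-estimated:
#' \deqn{\gamma = N_w - \alpha\, \mathrm{tr}(H^{-1}), \quad
#'       \alpha = \gamma / (2 E_W), \quad \beta_n = (n - \gamma) / (2 E_D),}
#' with \eqn{H = 2\beta_n J^T J + \alpha I} the Gauss-Newton approximation of
#' the Hessian of \eqn{F}. \eqn{\gamma} is the effective number of
#' parameters: how many of the \eqn{N_w} weights the data actually pin down.
#' Because regularization is set from the evidence there is no early
#' stopping.
#'
#' Inputs are z-scored internally (constant columns dropped with a warning).
#' Training is deterministic given `seed`: initial weights are drawn from a
#' seeded stream, scaled by `1/sqrt(fan-in)`, and the optimizer itself is
#' deterministic. `max_iter = 0` returns the untrained network
#' (\eqn{\gamma = 0}).
#'
#' @param X numeric matrix (samples x features) with column names.
#' @param y numeric response.
#' @param n_hidden number of tanh hidden units (default 3).
#' @param seed integer seed for weight initialization.
#' @param max_iter total cap on Levenberg-Marquardt weight updates across all
#'   outer rounds (default 1000; each outer round re-estimates the
#'   hyperparameters after at most 25 updates).
#' @param conv_tol relative change of F below which training stops
#'   (default 1e-8).
#' @return an object of class `brann_model`: `n_input`, `n_hidden`, flat
#'   `weights` vector, `alpha`, `beta_noise`, `gamma_effective`, `seed`,
#'   `converged`, `objective_trace`, standardization constants, and a
#'   `flags` character vector recording clamped hyperparameter updates.
#' @export
fit_brann <- function(X, y, n_hidden = 3, seed = 1, max_iter = 1000,
                      conv_tol = 1e-8) {
  ls_assert(is.matrix(X) && is.numeric(X) && all(is.finite(X)),
            "`X` must be a finite numeric matrix", "lipistage_input_error")
  ls_assert(length(y) == nrow(X) && all(is.finite(y)),
            "`y` must be finite and match nrow(X)", "lipistage_input_error")
  check_count(n_hidden, "n_hidden")
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))

  std <- standardize_columns(X)
  if (any(std$constant)) {
    warning(sprintf("dropping %d constant column(s): %s", sum(std$constant),
                    paste(colnames(X)[std$constant], collapse = ", ")))
  }
  Z <- std$Z[, !std$constant, drop = FALSE]
  p <- ncol(Z)
  h <- n_hidden
  n <- nrow(Z)
  n_w <- h * (p + 2) + 1  # input weights + hidden biases + output weights + bias

  w <- with_preserved_rng({
    set.seed(seed)
    c(stats::rnorm(h * p, sd = 1 / sqrt(max(p, 1))),  # W1
      stats::rnorm(h, sd = 1 / sqrt(max(p, 1))),      # b1
      stats::rnorm(h, sd = 1 / sqrt(h)),              # W2
      0)                                              # b2
  })

  # flat layout: W1 row-major per hidden unit, then b1, W2, b2
  unpack <- function(w) {
    list(W1 = matrix(w[seq_len(h * p)], h, p, byrow = TRUE),
         b1 = w[h * p + seq_len(h)],
         W2 = w[h * (p + 1) + seq_len(h)],
         b2 = w[n_w])
  }
  forward <- function(w, Zm) {
    pr <- unpack(w)
    A <- tcrossprod(Zm, pr$W1)                 # n x h pre-activations
    A <- sweep(A, 2, pr$b1, "+")
    Zh <- tanh(A)
    list(f = drop(Zh %*% pr$W2) + pr$b2, Zh = Zh)
  }
  jacobian <- function(w, Zm, Zh) {
    pr <- unpack(w)
    n_r <- nrow(Zm)
    J <- matrix(0, n_r, n_w)
    G <- (1 - Zh^2) * matrix(pr$W2, n_r, h, byrow = TRUE)  # d f / d a_k
    for (k in seq_len(h)) {
      J[, (k - 1) * p + seq_len(p)] <- G[, k] * Zm         # W1 rows stored per unit
    }
    J[, h * p + seq_len(h)] <- G
    J[, h * (p + 1) + seq_len(h)] <- Zh
    J[, n_w] <- 1
    J
  }
  alpha <- 0.01
  beta_noise <- 1
  gamma <- 0
  flags <- character(0)
  trace <- numeric(0)
  converged <- FALSE

  objective <- function(w, alpha, beta_noise) {
    f <- forward(w, Z)$f
    e <- f - y
    list(F = beta_noise * sum(e^2) + alpha * 0.5 * sum(w^2),
         E_D = sum(e^2), E_W = 0.5 * sum(w^2), e = e)
  }

  # One outer iteration = damped Gauss-Newton minimization of F at fixed
  # (alpha, beta_noise), then evidence re-estimation of the hyperparameters.
  # Re-estimating only at an (approximate) minimum of F avoids locking the
  # noise precision onto the large residuals of a half-trained network.
  steps_left <- max_iter
  if (max_iter > 0) {
    outer_max <- 40L
    for (outer in seq_len(outer_max)) {
      mu <- 1e-3
      ob <- objective(w, alpha, beta_noise)
      if (outer == 1) trace <- ob$F
      inner_done <- FALSE
      inner_steps <- 0L
      inner_cap <- 25L  # keep re-estimation frequent within the step budget
      while (!inner_done && steps_left > 0 && inner_steps < inner_cap) {
        steps_left <- steps_left - 1L
        inner_steps <- inner_steps + 1L
        fw <- forward(w, Z)
        e <- fw$f - y
        J <- jacobian(w, Z, fw$Zh)
        if (!all(is.finite(J)) || !all(is.finite(e))) {
          ls_abort("non-finite loss during BRANN training (see objective_trace)",
                   "lipistage_training_error")
        }
        g <- 2 * beta_noise * drop(crossprod(J, e)) + alpha * w
        H <- 2 * beta_noise * crossprod(J)
        diag(H) <- diag(H) + alpha
        accepted <- FALSE
        for (try in 1:25) {
          Hd <- H
          diag(Hd) <- diag(Hd) + mu
          step <- tryCatch(solve(Hd, -g), error = function(e) NULL)
          if (!is.null(step)) {
            w_try <- w + step
            ob_try <- objective(w_try, alpha, beta_noise)
            if (is.finite(ob_try$F) && ob_try$F <= ob$F) {
              rel <- (ob$F - ob_try$F) / max(ob$F, 1e-12)
              w <- w_try
              ob <- ob_try
              mu <- max(mu / 3, 1e-12)
              accepted <- TRUE
              if (rel < 1e-10) inner_done <- TRUE
              break
            }
          }
          mu <- mu * 3
        }
        if (!accepted || mu > 1e10) inner_done <- TRUE  # no descent left
      }
      # evidence-framework re-estimation on the Gauss-Newton Hessian
      fw <- forward(w, Z)
      e <- fw$f - y
      J <- jacobian(w, Z, fw$Zh)
      H <- 2 * beta_noise * crossprod(J)
      diag(H) <- diag(H) + alpha
      tr_Hinv <- tryCatch(sum(diag(solve(H))), error = function(e) NA_real_)
      if (is.finite(tr_Hinv)) {
        gamma <- min(max(n_w - alpha * tr_Hinv, 0), n_w)
      }
      E_W <- 0.5 * sum(w^2)
      E_D <- sum(e^2)
      alpha_old <- alpha
      beta_old <- beta_noise
      if (E_W > 1e-12) {
        alpha <- min(max(gamma / (2 * E_W), 1e-8), 1e8)
      }
      if (n > gamma && E_D > 1e-10 * max(sum(y^2), 1)) {
        beta_noise <- min(max((n - gamma) / (2 * E_D), 1e-8), 1e12)
      } else {
        flags <- unique(c(flags, "beta_noise_clamped"))
        beta_noise <- min(max(beta_noise, 1), 1e12)
      }
      ob <- objective(w, alpha, beta_noise)
      trace <- c(trace, ob$F)
      hyper_rel <- max(abs(alpha - alpha_old) / max(alpha_old, 1e-12),
                       abs(beta_noise - beta_old) / max(beta_old, 1e-12))
      len <- length(trace)
      if (len > 1 && hyper_rel < 1e-4 &&
          abs(trace[len] - trace[len - 1]) /
            max(abs(trace[len - 1]), 1e-12) < conv_tol) {
        converged <- TRUE
        break
      }
      if (steps_left <= 0) break
    }
  }

  structure(list(
    n_input = p, n_hidden = h, weights = w, alpha = alpha,
    beta_noise = beta_noise, gamma_effective = gamma, n_weights = n_w,
    seed = seed, converged = converged, objective_trace = trace,
    column_means = std$mean[!std$constant], column_sds = std$sd[!std$constant],
    feature_names = colnames(Z), flags = flags
  ), class = "brann_model")
}

#' @export
print.brann_model <- function(x, ...) {
  cat(sprintf("<brann_model> %d-%d-1 tanh network, alpha = %.3g, beta_noise = %.3g, gamma = %.2f / %d weights\n",
              x$n_input, x$n_hidden, x$alpha, x$beta_noise,
              x$gamma_effective, x$n_weights))
  invisible(x)
}

#' Predict from a fitted BRANN
#'
#' Deterministic forward pass using the stored standardization constants.
#'
#' @param object a `brann_model`.
#' @param X_new numeric matrix with the model's input columns (matched by
#'   name when named, otherwise by position; the column count must match).
#' @param ... unused.
#' @return numeric prediction vector.
#' @export
predict.brann_model <- function(object, X_new, ...) {
  ls_assert(is.matrix(X_new) && is.numeric(X_new),
            "`X_new` must be a numeric matrix", "lipistage_input_error")
  if (!is.null(colnames(X_new)) &&
      all(object$feature_names %in% colnames(X_new))) {
    X_new <- X_new[, object$feature_names, drop = FALSE]
  }
  ls_assert(ncol(X_new) == object$n_input,
            sprintf("X_new has %d column(s); model expects %d",
                    ncol(X_new), object$n_input),
            "lipistage_input_error")
  Z <- sweep(X_new, 2, object$column_means, "-")
  Z <- sweep(Z, 2, object$column_sds, "/")
  p <- object$n_input
  h <- object$n_hidden
  w <- object$weights
  W1 <- matrix(w[seq_len(h * p)], h, p, byrow = TRUE)
  b1 <- w[h * p + seq_len(h)]
  W2 <- w[h * (p + 1) + seq_len(h)]
  b2 <- w[length(w)]
  A <- sweep(tcrossprod(Z, W1), 2, b1, "+")
  drop(tanh(A) %*% W2) + b2
}

#' Effective number of parameters of a BRANN
#'
#' Returns \eqn{\gamma = N_w - \alpha\,\mathrm{tr}(H^{-1})}: the number of
#' network weights the data effectively determine. On noisy data
#' \eqn{\gamma} sits strictly below the total weight count — the signature
#' of active Bayesian regularization.
#'
#' @param model a `brann_model`.
#' @return scalar \eqn{\gamma} in `[0, n_weights]`.
#' @export
effective_parameters <- function(model) {
  ls_assert(inherits(model, "brann_model"), "`model` must be a brann_model",
            "lipistage_input_error")
  model$gamma_effective
}

#' Serialize a BRANN model to JSON
#' @param model a `brann_model`.
#' @param path output path.
#' @export
write_brann_json <- function(model, path) {
  jsonlite::write_json(list(
    type = "brann_model", n_input = model$n_input, n_hidden = model$n_hidden,
    feature_names = model$feature_names, weights = model$weights,
    alpha = model$alpha, beta_noise = model$beta_noise,
    gamma_effective = model$gamma_effective, seed = model$seed,
    converged = model$converged,
    column_means = as.list(model$column_means),
    column_sds = as.list(model$column_sds)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
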