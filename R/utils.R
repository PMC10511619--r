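# Internal helpers shared across modules.

# Classed error so callers/tests can distinguish failure modes without
# matching message text.
ls_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "lipistage_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ls_assert <- function(ok, msg, class) {
  if (!isTRUE(ok)) ls_abort(msg, class)
}

# Scalar checks used by configuration validators; `field` names the offending
# entry in the error message.
check_count <- function(x, field) {
  ls_assert(length(x) == 1 && is.numeric(x) && is.finite(x) &&
              x == as.integer(x) && x > 0,
            sprintf("`%s` must be a positive integer", field),
            "lipistage_config_error")
}

check_rate <- function(x, field) {
  ls_assert(length(x) == 1 && is.numeric(x) && is.finite(x) &&
              x >= 0 && x < 1,
            sprintf("`%s` must be a fraction in [0, 1)", field),
            "lipistage_config_error")
}

check_positive <- function(x, field) {
  ls_assert(length(x) == 1 && is.numeric(x) && is.finite(x) && x > 0,
            sprintf("`%s` must be a positive number", field),
            "lipistage_config_error")
}

# Column-wise z-scoring that tolerates (and reports) constant columns.
standardize_columns <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  constant <- sdv <= .Machine$double.eps^0.5
  Z <- sweep(X, 2, mu, "-")
  Z[, !constant] <- sweep(Z[, !constant, drop = FALSE], 2, sdv[!constant], "/")
  list(Z = Z, mean = mu, sd = sdv, constant = constant)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
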