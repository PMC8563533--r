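# Internal helpers: canonical names, numerics, classed conditions.

sdq_default_scales <- function() {
  c("emotional", "conduct", "hyperactivity", "social", "prosocial")
}

sdq_default_informants <- function() c("self", "parent")

# difficulties scales = everything except prosocial-type strengths scales
sdq_difficulties <- function(scales) setdiff(scales, "prosocial")

`%||%` <- function(a, b) if (is.null(a)) b else a

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise log-sum-exp of a matrix, stable
row_logsumexp <- function(mat) {
  m <- mat[cbind(seq_len(nrow(mat)), max.col(mat, ties.method = "first"))]
  ok <- is.finite(m)
  out <- m
  if (any(ok)) {
    out[ok] <- m[ok] + log(rowSums(exp(mat[ok, , drop = FALSE] - m[ok])))
  }
  out
}

# classed conditions so callers (and the pipeline manifest) can distinguish
# validation, configuration and numerical failures
sdq_abort <- function(message, class) {
  stop(structure(
    class = c(class, "sdqmix_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

sdq_validation_error <- function(message) sdq_abort(message, "sdqmix_validation_error")
sdq_config_error <- function(message) sdq_abort(message, "sdqmix_config_error")
sdq_numerical_error <- function(message) sdq_abort(message, "sdqmix_numerical_error")

assert_prob_vector <- function(p, what, tol = 1e-8) {
  if (any(!is.finite(p)) || any(p < -1e-12) || abs(sum(p) - 1) > tol) {
    sdq_config_error(sprintf("%s must be a probability vector summing to 1 (got sum %.10g)",
                             what, sum(p)))
  }
  invisible(TRUE)
}

# deterministic sub-seed derivation; keeps results inside 32-bit integer range
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 1009 + offset) %% 2147483647
}
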