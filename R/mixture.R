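#' Construct mixture model parameters
#'
#' Parameter container for the two-level finite mixture: subject-level mixing
#' proportions `pi` over K latent profiles, and an ordinal response model per
#' (profile, informant, scale). The default response model is the
#' adjacent-category (linear-by-linear) logit with equidistant category scores
#' `k = 0 .. m-1`:
#' \deqn{P(X = k \mid c, j, s) \propto \exp(\alpha_{jsk} + \beta_{cjs} k)}
#' with category intercepts `alpha` shared across profiles
#' (`alpha[j, s, 1] == 0`) and one location parameter `beta` per
#' (profile, informant, scale). A saturated per-category multinomial
#' parameterization is available via `parameterization = "multinomial"`, in
#' which case `logp` holds the log category probabilities directly.
#'
#' Because adding `d * k` to `alpha[j, s, ]` while subtracting `d` from every
#' `beta[, j, s]` leaves the probabilities unchanged, parameters are stored in
#' the gauge where each `alpha[j, s, ]` is orthogonal to the centred category
#' scores; [em_fit()] normalizes into this gauge.
#'
#' @param pi numeric vector of K mixing proportions (sums to 1).
#' @param beta numeric K x J x S array of location parameters.
#' @param alpha numeric J x S x m array of category intercepts with
#'   `alpha[, , 1] == 0`; defaults to all zeros.
#' @param scales,informants,n_categories model frame (names and score range).
#' @param parameterization `"adjacent"` (default) or `"multinomial"`.
#' @param logp for `"multinomial"`: K x J x S x m array of log category
#'   probabilities (each cell normalized).
#' @param fit optional list of fit metadata (log-likelihood, iterations, seed,
#'   start count), filled by [em_fit()].
#' @return An object of class `sdqmix_params`.
#' @export
mixture_params <- function(pi, beta, alpha = NULL,
                           scales = sdq_default_scales(),
                           informants = sdq_default_informants(),
                           n_categories = 11L,
                           parameterization = c("adjacent", "multinomial"),
                           logp = NULL, fit = NULL) {
  parameterization <- match.arg(parameterization)
  K <- length(pi)
  J <- length(informants)
  S <- length(scales)
  m <- as.integer(n_categories)
  if (m < 2L) sdq_config_error("n_categories must be >= 2")
  assert_prob_vector(pi, "pi")
  if (any(pi <= 0)) sdq_config_error("all mixing proportions must be > 0")
  # renormalize only when needed so save/load round-trips are bit-exact
  if (abs(sum(pi) - 1) > 1e-12) pi <- pi / sum(pi)

  if (parameterization == "adjacent") {
    beta <- array(beta, dim = c(K, J, S),
                  dimnames = list(NULL, informants, scales))
    if (is.null(alpha)) alpha <- array(0, dim = c(J, S, m))
    alpha <- array(alpha, dim = c(J, S, m),
                   dimnames = list(informants, scales, NULL))
    if (any(alpha[, , 1L] != 0)) {
      sdq_config_error("alpha[, , 1] must be exactly 0 (first category is the reference)")
    }
    logp <- NULL
  } else {
    if (is.null(logp)) sdq_config_error("multinomial parameterization needs logp")
    logp <- array(logp, dim = c(K, J, S, m),
                  dimnames = list(NULL, informants, scales, NULL))
    sums <- apply(exp(logp), 1:3, sum)
    if (any(abs(sums - 1) > 1e-8)) {
      sdq_config_error("multinomial logp cells must each normalize to 1")
    }
    beta <- NULL
    alpha <- NULL
  }

  structure(list(K = K, pi = pi, beta = beta, alpha = alpha, logp = logp,
                 parameterization = parameterization,
                 meta = list(scales = scales, informants = informants,
                             n_categories = m,
                             difficulties = sdq_difficulties(scales),
                             fit = fit)),
            class = "sdqmix_params")
}

#' @export
print.sdqmix_params <- function(x, ...) {
  cat(sprintf("<sdqmix_params> K=%d profiles, %s response model\n",
              x$K, x$parameterization))
  cat("  pi:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  cat(sprintf("  frame: %d informants x %d scales, %d categories\n",
              length(x$meta$informants), length(x$meta$scales),
              x$meta$n_categories))
  if (!is.null(x$meta$fit)) {
    cat(sprintf("  fit: loglik=%.4f, %d iterations, %d starts, seed=%s\n",
                x$meta$fit$loglik %||% NA_real_, x$meta$fit$iterations %||% NA_integer_,
                x$meta$fit$n_starts %||% NA_integer_, format(x$meta$fit$seed %||% NA)))
  }
  invisible(x)
}

# K x (J*S) x m array of log category probabilities, informant-major columns
logp_array <- function(params) {
  m <- params$meta$n_categories
  J <- length(params$meta$informants)
  S <- length(params$meta$scales)
  K <- params$K
  out <- array(NA_real_, dim = c(K, J * S, m))
  if (params$parameterization == "multinomial") {
    for (j in seq_len(J)) for (s in seq_len(S)) {
      out[, (j - 1L) * S + s, ] <- params$logp[, j, s, ]
    }
    return(out)
  }
  kvec <- 0:(m - 1L)
  for (j in seq_len(J)) for (s in seq_len(S)) {
    a <- params$alpha[j, s, ]
    for (c in seq_len(K)) {
      eta <- a + params$beta[c, j, s] * kvec
      out[c, (j - 1L) * S + s, ] <- eta - logsumexp(eta)
    }
  }
  out
}

#' Category probabilities of the ordinal response model
#'
#' Returns `P(score = k | profile, informant, scale)` for
#' `k = 0 .. n_categories - 1`.
#'
#' @param params an `sdqmix_params` object.
#' @param class profile index (1-based).
#' @param informant informant name or index.
#' @param scale scale name or index.
#' @return Numeric probability vector of length `n_categories` (sums to 1).
#' @examples
#' p <- mixture_params(pi = 1, beta = array(0, c(1, 2, 5)))
#' category_probs(p, 1, "self", "emotional")  # uniform: all logits equal
#' @export
category_probs <- function(params, class, informant, scale) {
  stopifnot(inherits(params, "sdqmix_params"))
  j <- resolve_index(informant, params$meta$informants, "informant")
  s <- resolve_index(scale, params$meta$scales, "scale")
  if (!(is.numeric(class) && length(class) == 1 && class >= 1 && class <= params$K)) {
    sdq_config_error(sprintf("class must be in 1..%d", params$K))
  }
  m <- params$meta$n_categories
  if (params$parameterization == "multinomial") {
    return(exp(params$logp[class, j, s, ]))
  }
  kvec <- 0:(m - 1L)
  eta <- params$alpha[j, s, ] + params$beta[class, j, s] * kvec
  p <- exp(eta - logsumexp(eta))
  p / sum(p)
}

resolve_index <- function(x, names, what) {
  if (is.character(x)) {
    i <- match(x, names)
    if (is.na(i)) sdq_config_error(sprintf("unknown %s '%s'", what, x))
    return(i)
  }
  if (!(is.numeric(x) && x >= 1 && x <= length(names))) {
    sdq_config_error(sprintf("%s index out of range", what))
  }
  as.integer(x)
}

# n x K matrix of per-subject conditional log-likelihoods log f(x_i | class c).
# Subjects contribute one factor per observed (informant, scale) score; absent
# records/scores contribute nothing (MAR marginalization at the informant level).
subject_loglik_matrix <- function(scores, params) {
  lp <- logp_array(params)
  n <- nrow(scores)
  K <- params$K
  out <- matrix(0, n, K)
  if (n == 0) return(out)
  for (c in seq_len(K)) {
    acc <- numeric(n)
    for (js in seq_len(ncol(scores))) {
      x <- scores[, js]
      ok <- which(!is.na(x))
      if (length(ok)) acc[ok] <- acc[ok] + lp[c, js, x[ok] + 1L]
    }
    out[, c] <- acc
  }
  out
}

check_scores_in_range <- function(scores, m) {
  bad <- which(!is.na(scores) & (scores < 0L | scores >= m))
  if (length(bad)) {
    sdq_validation_error(sprintf("scores outside 0..%d at %d position(s)", m - 1L, length(bad)))
  }
}

#' Observed-data log-likelihood
#'
#' Sum over subjects of `log sum_c pi[c] * prod_(observed scores) P(score | c)`.
#' A subject with no observed informant records contributes
#' `log(sum(pi)) = 0`.
#'
#' @param data an `sdqmix_data` object (or an integer score matrix as produced
#'   internally, one row per subject, one column per informant x scale).
#' @param params an `sdqmix_params` object.
#' @return The log-likelihood (scalar).
#' @export
loglikelihood <- function(data, params) {
  stopifnot(inherits(params, "sdqmix_params"))
  scores <- if (inherits(data, "sdqmix_data")) score_matrix(data) else data
  check_scores_in_range(scores, params$meta$n_categories)
  if (nrow(scores) == 0) return(0)
  L <- subject_loglik_matrix(scores, params)
  A <- sweep(L, 2, log(params$pi), "+")
  sum(row_logsumexp(A))
}

# n x K posterior probability matrix, plus per-subject entropy
posterior_matrix <- function(scores, params) {
  L <- subject_loglik_matrix(scores, params)
  A <- sweep(L, 2, log(params$pi), "+")
  ll <- row_logsumexp(A)
  W <- exp(A - ll)
  W / rowSums(W)
}

posterior_entropy <- function(W) {
  Wp <- pmax(W, 1e-300)
  -rowSums(ifelse(W > 0, W * log(Wp), 0))
}

#' Posterior profile-membership probabilities for one subject
#'
#' Scores a subject by Bayes' rule from any combination of observed informant
#' records and subscale scores; with nothing observed the prior mixing
#' proportions are returned.
#'
#' @param params an `sdqmix_params` object.
#' @param records data.frame for one subject with columns `informant` and one
#'   column per scale (NA = unobserved); may have zero rows.
#' @return List with `probabilities` (length K, sums to 1), `modal_class`
#'   (argmax index, ties to the lowest index) and `entropy_contribution`.
#' @examples
#' p <- mixture_params(pi = c(0.5, 0.5), beta = array(c(-0.5, 0.5), c(2, 2, 5)))
#' posterior(p, data.frame(informant = "self", emotional = 9L, conduct = NA,
#'                         hyperactivity = NA, social = NA, prosocial = NA))
#' @export
posterior <- function(params, records) {
  stopifnot(inherits(params, "sdqmix_params"))
  scales <- params$meta$scales
  informants <- params$meta$informants
  S <- length(scales)
  scores <- matrix(NA_integer_, 1, length(informants) * S)
  if (!is.null(records) && nrow(records) > 0) {
    if (anyDuplicated(records$informant)) {
      sdq_validation_error("at most one record per informant")
    }
    for (r in seq_len(nrow(records))) {
      j <- resolve_index(records$informant[r], informants, "informant")
      for (s in seq_len(S)) {
        v <- records[[scales[s]]][r]
        if (!is.null(v) && !is.na(v)) scores[1, (j - 1L) * S + s] <- as.integer(v)
      }
    }
  }
  check_scores_in_range(scores, params$meta$n_categories)
  W <- posterior_matrix(scores, params)
  probs <- as.numeric(W[1, ])
  list(probabilities = probs,
       modal_class = which.max(probs),
       entropy_contribution = posterior_entropy(W)[1])
}

#' Entropy-based class-separation diagnostic
#'
#' Entropy R-squared: `1 - sum_i H(posterior_i) / (n * log K)`, where `H` is
#' Shannon entropy. 1 means perfectly separated profiles (all posteriors
#' degenerate), 0 means no separation (all posteriors uniform).
#'
#' @param x an `sdqmix_fit` object or an n x K posterior probability matrix.
#' @return Scalar in `[0, 1]`.
#' @export
entropy_r2 <- function(x) {
  W <- if (inherits(x, "sdqmix_fit")) x$posteriors else as.matrix(x)
  K <- ncol(W)
  if (K < 2) sdq_config_error("entropy_r2 is undefined for K = 1")
  n <- nrow(W)
  if (n == 0) sdq_config_error("entropy_r2 needs at least one subject")
  1 - sum(posterior_entropy(W)) / (n * log(K))
}

# Relabel classes: permute pi/beta (or logp) rows by perm (new order of old
# indices). Used for deterministic reporting order and in tests.
permute_params <- function(params, perm) {
  stopifnot(length(perm) == params$K, sort(perm) == seq_len(params$K))
  params$pi <- params$pi[perm]
  if (params$parameterization == "adjacent") {
    params$beta <- params$beta[perm, , , drop = FALSE]
  } else {
    params$logp <- params$logp[perm, , , , drop = FALSE]
  }
  params
}
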