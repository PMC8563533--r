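# EM estimation of the two-level ordinal mixture, multi-start, and BIC
# selection over a range of profile counts.

#' Fit the K-profile mixture by EM
#'
#' Maximum-likelihood estimation via EM with random multi-start. The E-step
#' computes subject posteriors by Bayes' rule; the M-step updates the mixing
#' proportions in closed form and the adjacent-category response parameters by
#' blockwise Newton steps with step-halving (each block update cannot decrease
#' the expected complete-data log-likelihood, so the observed log-likelihood
#' is non-decreasing across iterations). All starts are run for a short burn-in
#' (`short_iter` iterations), then the `n_keep` best are continued to
#' convergence and the best final log-likelihood wins; ties break to the lowest
#' start index. Deterministic given `seed`.
#'
#' Profiles in the returned fit are ordered by ascending expected total
#' difficulties (sum of expected scores over the difficulties scales, averaged
#' over informants), so profile 1 is always the least-severe profile.
#'
#' @param data an `sdqmix_data` object with at least one subject.
#' @param K number of latent profiles (>= 1).
#' @param n_starts number of random initializations (Dirichlet(1) mixing,
#'   N(0,1) locations, zero intercepts).
#' @param seed integer seed governing all initializations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per retained start.
#' @param short_iter burn-in iterations given to every start.
#' @param n_keep number of starts continued to convergence.
#' @param parameterization `"adjacent"` (default) or `"multinomial"` (saturated
#'   per-category probabilities, closed-form M-step).
#' @return An object of class `sdqmix_fit`: list with `params`
#'   (`sdqmix_params`), `loglik`, `bic`, `n_free_params`, `n_subjects`,
#'   `posteriors` (n x K), `modal` (modal assignments), and `meta`
#'   (per-start log-likelihood trajectories, best start index, convergence
#'   flag, seed).
#' @details BIC is `-2 loglik + n_free_params * log(n_subjects)`; the sample
#'   size is the number of level-2 units (subjects), since the latent classes
#'   live at the subject level. Free-parameter counts: adjacent-category,
#'   `(K-1) + J*S*(m - 2 + K)` (the shared-intercept/location gauge degeneracy
#'   is removed); multinomial, `(K-1) + K*J*S*(m-1)`.
#' @export
em_fit <- function(data, K, n_starts = 20L, seed = 1L, tol = 1e-8,
                   max_iter = 500L, short_iter = 30L, n_keep = 3L,
                   parameterization = c("adjacent", "multinomial")) {
  parameterization <- match.arg(parameterization)
  stopifnot(inherits(data, "sdqmix_data"))
  if (!(is.numeric(K) && length(K) == 1 && K >= 1)) {
    sdq_config_error("K must be a single integer >= 1")
  }
  K <- as.integer(K)
  scores <- score_matrix(data)
  n <- nrow(scores)
  if (n == 0) sdq_config_error("em_fit needs a non-empty dataset")
  check_scores_in_range(scores, data$n_categories)

  J <- length(data$informants)
  S <- length(data$scales)
  m <- data$n_categories
  if (K == 1L) n_starts <- 1L
  n_keep <- min(n_keep, n_starts)

  set.seed(as.integer(derive_seed(seed, 0)))
  inits <- lapply(seq_len(n_starts), function(i) {
    g <- stats::rgamma(K, 1)
    list(pi = g / sum(g),
         beta = array(stats::rnorm(K * J * S), dim = c(K, J, S)),
         alpha = array(0, dim = c(J, S, m)))
  })
  if (K == 1L) inits[[1]]$beta[] <- 0
  if (parameterization == "multinomial") {
    # same random starts, expressed as category probabilities
    kvec <- 0:(m - 1L)
    inits <- lapply(inits, function(init) {
      logp <- array(NA_real_, dim = c(K, J, S, m))
      for (c in seq_len(K)) for (j in seq_len(J)) for (s in seq_len(S)) {
        eta <- init$alpha[j, s, ] + init$beta[c, j, s] * kvec
        logp[c, j, s, ] <- eta - logsumexp(eta)
      }
      list(pi = init$pi, logp = logp)
    })
  }

  runs <- lapply(inits, function(init) {
    em_run(scores, init, K, J, S, m, parameterization,
           max_iter = short_iter, tol = tol)
  })
  short_ll <- vapply(runs, function(r) r$loglik, numeric(1))
  keep <- order(short_ll, decreasing = TRUE)[seq_len(n_keep)]
  keep <- sort(keep)  # process in start order so ties break to lowest index
  for (i in keep) {
    if (!runs[[i]]$converged) {
      runs[[i]] <- em_run(scores, runs[[i]]$state, K, J, S, m, parameterization,
                          max_iter = max_iter, tol = tol,
                          traj0 = runs[[i]]$trajectory)
    }
  }
  final_ll <- rep(-Inf, n_starts)
  final_ll[keep] <- vapply(runs[keep], function(r) r$loglik, numeric(1))
  best <- which.max(final_ll)  # first max -> lowest start index on ties
  run <- runs[[best]]
  if (!is.finite(run$loglik)) {
    sdq_numerical_error(sprintf(
      "EM produced a non-finite log-likelihood (K=%d, best start %d)", K, best))
  }

  params <- state_to_params(run$state, data, parameterization,
                            fit = list(loglik = run$loglik,
                                       iterations = length(run$trajectory),
                                       seed = seed, n_starts = n_starts,
                                       converged = run$converged))
  params <- normalize_gauge(params)
  params <- order_classes(params)

  W <- posterior_matrix(scores, params)
  modal <- max.col(W, ties.method = "first")
  n_free <- n_free_params(K, J, S, m, parameterization)
  ll <- loglikelihood(scores, params)
  structure(list(params = params, loglik = ll,
                 bic = -2 * ll + n_free * log(n),
                 n_free_params = n_free, n_subjects = n,
                 posteriors = W, modal = modal,
                 meta = list(trajectory = run$trajectory,
                             trajectories = lapply(runs, `[[`, "trajectory"),
                             best_start = best, converged = run$converged,
                             seed = seed, n_starts = n_starts, K = K)),
            class = "sdqmix_fit")
}

#' @export
print.sdqmix_fit <- function(x, ...) {
  cat(sprintf("<sdqmix_fit> K=%d, n=%d subjects\n", x$params$K, x$n_subjects))
  cat(sprintf("  loglik=%.4f  BIC=%.4f  free params=%d  converged=%s\n",
              x$loglik, x$bic, x$n_free_params, x$meta$converged))
  cat("  pi:", paste(sprintf("%.3f", x$params$pi), collapse = " "), "\n")
  if (x$params$K >= 2) cat(sprintf("  entropy R2: %.3f\n", entropy_r2(x)))
  invisible(x)
}

n_free_params <- function(K, J, S, m, parameterization) {
  if (parameterization == "multinomial") {
    (K - 1L) + K * J * S * (m - 1L)
  } else {
    (K - 1L) + J * S * (m - 2L + K)
  }
}

state_to_params <- function(state, data, parameterization, fit) {
  if (parameterization == "multinomial") {
    mixture_params(state$pi, beta = NULL, scales = data$scales,
                   informants = data$informants, n_categories = data$n_categories,
                   parameterization = "multinomial", logp = state$logp, fit = fit)
  } else {
    mixture_params(state$pi, state$beta, state$alpha, scales = data$scales,
                   informants = data$informants, n_categories = data$n_categories,
                   fit = fit)
  }
}

# project the linear-in-k component out of each alpha block into the betas
# (fixes the adjacent-category gauge; probabilities unchanged)
normalize_gauge <- function(params) {
  if (params$parameterization != "adjacent") return(params)
  m <- params$meta$n_categories
  kvec <- 0:(m - 1L)
  kc <- kvec - mean(kvec)
  denom <- sum(kc^2)
  J <- dim(params$alpha)[1]; S <- dim(params$alpha)[2]
  for (j in seq_len(J)) for (s in seq_len(S)) {
    a <- params$alpha[j, s, ]
    d <- sum(a * kc) / denom
    a <- a - d * kvec
    a <- a - a[1L]  # keep the reference-category zero exactly
    params$alpha[j, s, ] <- a
    params$beta[, j, s] <- params$beta[, j, s] + d
  }
  params
}

# deterministic reporting order: ascending expected total difficulties
order_classes <- function(params) {
  sev <- class_severity(params)
  perm <- order(sev)
  permute_params(params, perm)
}

class_severity <- function(params) {
  diffs <- params$meta$difficulties
  if (!length(diffs)) diffs <- params$meta$scales
  informants <- params$meta$informants
  kvec <- 0:(params$meta$n_categories - 1L)
  vapply(seq_len(params$K), function(c) {
    mean(vapply(informants, function(j) {
      sum(vapply(diffs, function(s) sum(kvec * category_probs(params, c, j, s)),
                 numeric(1)))
    }, numeric(1)))
  }, numeric(1))
}

# ---- EM internals ---------------------------------------------------------

em_run <- function(scores, state, K, J, S, m, parameterization,
                   max_iter, tol, traj0 = numeric(0)) {
  n <- nrow(scores)
  kvec <- 0:(m - 1L)
  obs <- lapply(seq_len(ncol(scores)), function(js) which(!is.na(scores[, js])))
  xval <- lapply(seq_len(ncol(scores)), function(js) scores[obs[[js]], js] + 1L)

  trajectory <- traj0
  ll_prev <- if (length(traj0)) traj0[length(traj0)] else -Inf
  converged <- FALSE
  ll <- ll_prev

  for (iter in seq_len(max_iter)) {
    prm <- state_to_params_raw(state, K, J, S, m, parameterization)
    L <- subject_loglik_matrix_raw(scores, prm, K)
    A <- sweep(L, 2, log(state$pi), "+")
    lli <- row_logsumexp(A)
    ll <- sum(lli)
    if (!is.finite(ll)) {
      sdq_numerical_error("non-finite log-likelihood during EM")
    }
    W <- exp(A - lli)
    trajectory <- c(trajectory, ll)
    if (is.finite(ll_prev) &&
        (ll - ll_prev) < tol * (abs(ll_prev) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll

    # M-step: closed-form pi, then response-parameter blocks
    pi_new <- colSums(W) / n
    pi_new <- pmax(pi_new, 1e-10)
    state$pi <- pi_new / sum(pi_new)

    for (j in seq_len(J)) for (s in seq_len(S)) {
      js <- (j - 1L) * S + s
      idx <- obs[[js]]
      if (!length(idx)) next
      Ncnt <- matrix(0, m, K)
      tmp <- rowsum(W[idx, , drop = FALSE], group = xval[[js]])
      Ncnt[as.integer(rownames(tmp)), ] <- tmp
      if (parameterization == "multinomial") {
        p <- sweep(pmax(Ncnt, 1e-10), 2, colSums(pmax(Ncnt, 1e-10)), "/")
        state$logp[, j, s, ] <- t(log(p))
      } else {
        upd <- update_block(state$alpha[j, s, ], state$beta[, j, s], Ncnt, kvec)
        state$alpha[j, s, ] <- upd$a
        state$beta[, j, s] <- upd$b
      }
    }
  }
  state$pi <- state$pi  # final state carries last M-step parameters
  list(state = state, loglik = ll, trajectory = trajectory, converged = converged)
}

state_to_params_raw <- function(state, K, J, S, m, parameterization) {
  # minimal params-like list for the inner loop (avoids repeated validation)
  if (parameterization == "multinomial") {
    list(K = K, logp = state$logp, parameterization = "multinomial",
         meta = list(n_categories = m, informants = seq_len(J), scales = seq_len(S)))
  } else {
    list(K = K, beta = state$beta, alpha = state$alpha, parameterization = "adjacent",
         meta = list(n_categories = m, informants = seq_len(J), scales = seq_len(S)))
  }
}

subject_loglik_matrix_raw <- function(scores, prm, K) {
  lp <- logp_array_raw(prm)
  n <- nrow(scores)
  out <- matrix(0, n, K)
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

logp_array_raw <- function(prm) {
  m <- prm$meta$n_categories
  J <- length(prm$meta$informants)
  S <- length(prm$meta$scales)
  K <- prm$K
  out <- array(NA_real_, dim = c(K, J * S, m))
  if (prm$parameterization == "multinomial") {
    for (j in seq_len(J)) for (s in seq_len(S)) {
      out[, (j - 1L) * S + s, ] <- prm$logp[, j, s, ]
    }
    return(out)
  }
  kvec <- 0:(m - 1L)
  for (j in seq_len(J)) for (s in seq_len(S)) {
    a <- prm$alpha[j, s, ]
    for (c in seq_len(K)) {
      eta <- a + prm$beta[c, j, s] * kvec
      out[c, (j - 1L) * S + s, ] <- eta - logsumexp(eta)
    }
  }
  out
}

# One (informant, scale) block of the M-step: expected counts Ncnt (m x K),
# shared intercepts a (length m, a[1] = 0) and per-class locations b.
# Coordinate Newton with step-halving on the block objective
#   Q(a, b) = sum_c sum_k N[k,c] (a_k + b_c k) - sum_c N_c log Z_c(a, b_c);
# every accepted step does not decrease Q, which preserves EM monotonicity.
update_block <- function(a, b, Ncnt, kvec, sweeps = 2L) {
  m <- length(kvec)
  K <- length(b)
  Nc <- colSums(Ncnt)
  for (sw in seq_len(sweeps)) {
    for (c in seq_len(K)) {
      if (Nc[c] < 1e-12) next
      b[c] <- newton_beta(b[c], a, Ncnt[, c], Nc[c], kvec)
    }
    if (m > 1L) a <- newton_alpha(a, b, Ncnt, Nc, kvec)
  }
  list(a = a, b = b)
}

newton_beta <- function(b, a, Nk, Nc, kvec, n_iter = 3L) {
  f_at <- function(bb) sum(Nk * (a + bb * kvec)) - Nc * logsumexp(a + bb * kvec)
  Sk <- sum(Nk * kvec)
  for (it in seq_len(n_iter)) {
    eta <- a + b * kvec
    lz <- logsumexp(eta)
    p <- exp(eta - lz)
    mu <- sum(p * kvec)
    v <- sum(p * kvec^2) - mu^2
    g <- Sk - Nc * mu
    if (abs(g) < 1e-10 * (1 + Nc)) break
    step <- g / (Nc * max(v, 1e-8))
    f0 <- sum(Nk * eta) - Nc * lz
    t <- 1
    accepted <- FALSE
    while (t > 1e-6) {
      bn <- b + t * step
      if (f_at(bn) >= f0 - 1e-12 * (1 + abs(f0))) {
        b <- bn
        accepted <- TRUE
        break
      }
      t <- t / 2
    }
    if (!accepted) break
  }
  b
}

newton_alpha <- function(a, b, Ncnt, Nc, kvec, n_iter = 2L) {
  m <- length(kvec)
  K <- length(b)
  free <- 2:m
  q_at <- function(aa) {
    tot <- 0
    for (c in seq_len(K)) {
      eta <- aa + b[c] * kvec
      tot <- tot + sum(Ncnt[, c] * eta) - Nc[c] * logsumexp(eta)
    }
    tot
  }
  for (it in seq_len(n_iter)) {
    g <- rowSums(Ncnt)[free]
    H <- matrix(0, m - 1L, m - 1L)
    for (c in seq_len(K)) {
      eta <- a + b[c] * kvec
      p <- exp(eta - logsumexp(eta))
      g <- g - Nc[c] * p[free]
      pf <- p[free]
      H <- H + Nc[c] * (diag(pf, nrow = m - 1L) - tcrossprod(pf))
    }
    if (max(abs(g)) < 1e-10 * (1 + sum(Nc))) break
    step <- tryCatch(solve(H + diag(1e-8, m - 1L), g),
                     error = function(e) g / (diag(H) + 1e-6))
    q0 <- q_at(a)
    t <- 1
    accepted <- FALSE
    while (t > 1e-6) {
      an <- a
      an[free] <- a[free] + t * step
      if (q_at(an) >= q0 - 1e-12 * (1 + abs(q0))) {
        a <- an
        accepted <- TRUE
        break
      }
      t <- t / 2
    }
    if (!accepted) break
  }
  a
}

#' Fit a range of profile counts and select by BIC
#'
#' Fits [em_fit()] for each K in `K_range`, tabulates log-likelihood, free
#' parameters and BIC, and returns the fit with the smallest BIC (ties break
#' to the smallest K). A failing fit is recorded in the table and excluded
#' from selection.
#'
#' @inheritParams em_fit
#' @param K_range integer vector of candidate profile counts (default 1-8).
#' @param ... further arguments passed to [em_fit()].
#' @return An object of class `sdqmix_selection`: list with `best_fit`, `best_K`
#'   and `table` (data.frame: K, loglik, n_free_params, bic, converged, error).
#' @export
select_model <- function(data, K_range = 1:8, n_starts = 20L, seed = 1L, ...) {
  if (!length(K_range)) sdq_config_error("K_range must be non-empty")
  K_range <- sort(unique(as.integer(K_range)))
  fits <- vector("list", length(K_range))
  tab <- data.frame(K = K_range, loglik = NA_real_, n_free_params = NA_integer_,
                    bic = NA_real_, converged = NA, error = NA_character_)
  for (i in seq_along(K_range)) {
    res <- tryCatch(
      em_fit(data, K_range[i], n_starts = n_starts,
             seed = derive_seed(seed, K_range[i]), ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      tab$error[i] <- conditionMessage(res)
    } else {
      fits[[i]] <- res
      tab$loglik[i] <- res$loglik
      tab$n_free_params[i] <- res$n_free_params
      tab$bic[i] <- res$bic
      tab$converged[i] <- res$meta$converged
    }
  }
  ok <- which(!is.na(tab$bic))
  if (!length(ok)) sdq_numerical_error("all candidate fits failed")
  best <- ok[which.min(tab$bic[ok])]  # which.min takes the first (smallest K) on ties
  structure(list(best_fit = fits[[best]], best_K = K_range[best], table = tab),
            class = "sdqmix_selection")
}

#' @export
print.sdqmix_selection <- function(x, ...) {
  cat(sprintf("<sdqmix_selection> best K = %d by BIC\n", x$best_K))
  print(x$table, row.names = FALSE)
  invisible(x)
}
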