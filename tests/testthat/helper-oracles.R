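# Independent oracles and small fixture builders shared across test files.

# Naive log-likelihood by explicit enumeration over class assignments:
# triple loop over subjects, classes and observed (informant, scale) cells,
# no log-sum-exp tricks. Stays independent of the vectorized implementation.
naive_loglik <- function(scores, params) {
  S <- length(params$meta$scales)
  total <- 0
  for (i in seq_len(nrow(scores))) {
    lik <- 0
    for (c in seq_len(params$K)) {
      term <- params$pi[c]
      for (js in seq_len(ncol(scores))) {
        x <- scores[i, js]
        if (is.na(x)) next
        j <- (js - 1) %/% S + 1
        s <- (js - 1) %% S + 1
        term <- term * category_probs(params, c, j, s)[x + 1]
      }
      lik <- lik + term
    }
    total <- total + log(lik)
  }
  total
}

# Random small model + score matrix for property-style checks.
random_instance <- function(seed) {
  set.seed(seed)
  K <- sample(1:3, 1)
  n <- sample(0:4, 1)
  J <- sample(1:2, 1)
  S <- sample(1:2, 1)
  m <- sample(2:3, 1)
  g <- rgamma(K, 1) + 0.1
  params <- mixture_params(
    pi = g / sum(g),
    beta = array(rnorm(K * J * S), c(K, J, S)),
    alpha = array(c(rep(0, J * S), rnorm(J * S * (m - 1), sd = 0.5)), c(J, S, m)),
    scales = paste0("sc", seq_len(S)),
    informants = c("self", "parent")[seq_len(J)],
    n_categories = m)
  scores <- matrix(sample(c(NA, 0:(m - 1)), n * J * S, replace = TRUE), n, J * S)
  list(params = params, scores = scores)
}

# Best class-permutation match of fitted to true parameters (K small).
match_classes <- function(fit_params, true_params) {
  K <- fit_params$K
  perms <- rbind(expand.grid(rep(list(seq_len(K)), K)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == K), , drop = FALSE]
  best <- NULL
  best_err <- Inf
  for (r in seq_len(nrow(perms))) {
    p <- as.integer(perms[r, ])
    err <- sum(abs(fit_params$beta[p, , , drop = FALSE] - true_params$beta))
    if (err < best_err) {
      best_err <- err
      best <- p
    }
  }
  best  # fitted class best[c] corresponds to true class c
}

# 1-D grid-search oracle for the K = 2 corrected group distribution.
grid_theta_k2 <- function(assignments, D, step = 0.001) {
  cnt <- tabulate(assignments, nbins = 2)
  grid <- seq(0, 1, by = step)
  ll <- vapply(grid, function(t1) {
    theta <- c(t1, 1 - t1)
    pw <- as.numeric(theta %*% D)
    sum(cnt * log(pmax(pw, 1e-300)))
  }, numeric(1))
  grid[which.max(ll)]
}

# Small complete two-informant dataset with hand-set scores.
tiny_data <- function() {
  subj <- data.frame(id = c("a", "b", "c"),
                     gender = c("male", "female", "male"),
                     setting = c("community", "CAMH", "CAMH"),
                     diagnoses = c("", "ADHD", "ADHD;CD/ODD"))
  rec <- expand.grid(id = subj$id, informant = c("self", "parent"),
                     stringsAsFactors = FALSE)
  set.seed(42)
  for (s in c("emotional", "conduct", "hyperactivity", "social", "prosocial")) {
    rec[[s]] <- sample(0:10, nrow(rec), replace = TRUE)
  }
  sdq_data(subj, rec)
}
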