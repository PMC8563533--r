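# Step 3 of the analysis: modal assignment, classification-error
# quantification, and bias-adjusted estimation of profile prevalence per
# group, with the reporting rules (gender differences >= 20 percentage
# points; minimum group size).

#' Modal class assignment
#'
#' Assigns each subject the class with the highest posterior probability;
#' ties break to the lowest class index.
#'
#' @param posteriors n x K posterior probability matrix (or an `sdqmix_fit`).
#' @return Integer vector of assigned classes.
#' @export
modal_assign <- function(posteriors) {
  W <- if (inherits(posteriors, "sdqmix_fit")) posteriors$posteriors else as.matrix(posteriors)
  if (nrow(W) == 0) return(integer(0))
  max.col(W, ties.method = "first")
}

#' Classification error matrix of modal assignment
#'
#' `D[c, w] = P(assigned class w | true class c)`, estimated as the
#' posterior-weighted cross-classification
#' `sum_i p_i(c) 1[w_i = w] / sum_i p_i(c)`. Rows sum to 1. A class with zero
#' total posterior mass yields an undefined (NaN) row and a warning.
#'
#' @param posteriors n x K posterior probability matrix.
#' @param assignments integer vector of modal assignments (same length).
#' @return K x K matrix `D`.
#' @export
error_matrix <- function(posteriors, assignments) {
  W <- as.matrix(posteriors)
  K <- ncol(W)
  if (K < 2) sdq_config_error("error_matrix needs K >= 2")
  if (length(assignments) != nrow(W)) {
    sdq_config_error("posteriors and assignments must have equal length")
  }
  D <- matrix(NA_real_, K, K)
  mass <- colSums(W)
  for (w in seq_len(K)) {
    D[, w] <- colSums(W[assignments == w, , drop = FALSE])
  }
  zero <- mass <= 0
  if (any(zero)) {
    warning(sprintf("class(es) %s carry zero posterior mass; error-matrix row undefined",
                    paste(which(zero), collapse = ", ")))
  }
  D <- D / ifelse(mass > 0, mass, NA_real_)
  D
}

# ML estimate of theta on the simplex for one group: maximize
#   sum_i log sum_c theta[c] D[c, w_i]
# by EM over the latent true class; with D = identity this reduces exactly to
# the empirical assigned-class proportions.
fit_theta <- function(assignments, D, tol = 1e-12, max_iter = 5000L) {
  K <- nrow(D)
  cnt <- tabulate(assignments, nbins = K)
  ntot <- sum(cnt)
  theta <- rep(1 / K, K)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    M <- theta * D                      # K x K: theta_c * D[c, w]
    pw <- pmax(colSums(M), 1e-300)      # P(assigned = w)
    ll <- sum(cnt * log(pw))
    Z <- sweep(M, 2, pw, "/")           # P(true = c | assigned = w)
    theta <- as.numeric(Z %*% cnt) / ntot
    if (ll - ll_old < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(theta = theta, loglik = ll, iterations = it)
}

#' Classification-error-corrected profile distribution per group
#'
#' For each group g, maximizes the marginal likelihood of the modal
#' assignments `sum_{i in g} log sum_c theta[g, c] D[c, w_i]` over the
#' probability simplex (EM over the latent true class), with the
#' classification error matrix `D` estimated on the full sample and held
#' fixed. With `D` equal to the identity this coincides exactly with the
#' empirical assigned-class proportions.
#'
#' @param assignments integer vector of modal assignments.
#' @param D K x K row-stochastic classification error matrix.
#' @param groups per-subject group labels; subjects with `NA` group are
#'   excluded (count reported in the result).
#' @param boot number of nonparametric bootstrap replicates for standard
#'   errors (0 = none).
#' @param seed seed for the bootstrap.
#' @return An object of class `sdqmix_groupdist`: list with `theta` (G x K
#'   matrix, rows on the simplex, rownames = groups), `n_g` group sizes,
#'   `se` (or NULL), `excluded` (number of NA-group subjects).
#' @export
adjusted_distribution <- function(assignments, D, groups, boot = 0L, seed = 1L) {
  D <- as.matrix(D)
  K <- nrow(D)
  if (any(!is.finite(D)) || any(D < -1e-12) ||
      any(abs(rowSums(D) - 1) > 1e-8)) {
    sdq_config_error("D must be row-stochastic")
  }
  if (length(groups) != length(assignments)) {
    sdq_config_error("groups and assignments must have equal length")
  }
  keep <- !is.na(groups)
  excluded <- sum(!keep)
  assignments <- assignments[keep]
  groups <- as.character(groups[keep])
  levs <- sort(unique(groups))
  theta <- matrix(NA_real_, length(levs), K,
                  dimnames = list(levs, paste0("class", seq_len(K))))
  n_g <- setNames(integer(length(levs)), levs)
  for (g in levs) {
    idx <- which(groups == g)
    n_g[g] <- length(idx)
    if (!length(idx)) next
    theta[g, ] <- fit_theta(assignments[idx], D)$theta
  }
  se <- NULL
  if (boot > 0) {
    set.seed(as.integer(derive_seed(seed, 97)))
    se <- matrix(NA_real_, length(levs), K, dimnames = dimnames(theta))
    for (g in levs) {
      idx <- which(groups == g)
      if (length(idx) < 2) next
      reps <- vapply(seq_len(boot), function(b) {
        fit_theta(assignments[sample(idx, length(idx), replace = TRUE)], D)$theta
      }, numeric(K))
      se[g, ] <- apply(reps, 1, stats::sd)
    }
  }
  structure(list(theta = theta, n_g = n_g, se = se, excluded = excluded),
            class = "sdqmix_groupdist")
}

#' @export
print.sdqmix_groupdist <- function(x, digits = 3, ...) {
  cat("<sdqmix_groupdist> corrected profile distribution per group\n")
  tab <- cbind(n = x$n_g, round(x$theta, digits))
  print(tab)
  if (x$excluded > 0) cat(sprintf("  (%d subjects excluded: missing group)\n", x$excluded))
  invisible(x)
}

#' Gender-specific corrected distributions and difference table
#'
#' Applies [adjusted_distribution()] within each group x gender cell and
#' tabulates per-profile male/female prevalences and absolute differences.
#' Cells smaller than `min_cell` are flagged unstable; empty cells get no
#' estimate.
#'
#' @inheritParams adjusted_distribution
#' @param gender per-subject gender labels (`NA` excluded).
#' @param min_cell minimum cell size below which an estimate is flagged.
#' @return List with `cells` (data.frame: group, gender, n, unstable, one
#'   column per class) and `differences` (data.frame: group, class, male,
#'   female, abs_diff).
#' @export
gender_interaction <- function(assignments, D, groups, gender, min_cell = 10L) {
  if (length(gender) != length(assignments)) {
    sdq_config_error("gender and assignments must have equal length")
  }
  keep <- !is.na(groups) & !is.na(gender)
  assignments <- assignments[keep]
  groups <- as.character(groups[keep])
  gender <- as.character(gender[keep])
  K <- nrow(as.matrix(D))
  levs_g <- sort(unique(groups))
  levs_x <- sort(unique(gender))
  cells <- list()
  for (g in levs_g) for (x in levs_x) {
    idx <- which(groups == g & gender == x)
    row <- data.frame(group = g, gender = x, n = length(idx),
                      unstable = length(idx) < min_cell,
                      stringsAsFactors = FALSE)
    th <- rep(NA_real_, K)
    if (length(idx) > 0) th <- fit_theta(assignments[idx], as.matrix(D))$theta
    for (c in seq_len(K)) row[[paste0("class", c)]] <- th[c]
    cells[[length(cells) + 1L]] <- row
  }
  cells <- do.call(rbind, cells)
  diffs <- list()
  if (all(c("male", "female") %in% levs_x)) {
    for (g in levs_g) {
      mrow <- cells[cells$group == g & cells$gender == "male", ]
      frow <- cells[cells$group == g & cells$gender == "female", ]
      for (c in seq_len(K)) {
        mv <- mrow[[paste0("class", c)]]
        fv <- frow[[paste0("class", c)]]
        diffs[[length(diffs) + 1L]] <- data.frame(
          group = g, class = c, male = mv, female = fv,
          abs_diff = abs(mv - fv), stringsAsFactors = FALSE)
      }
    }
  }
  differences <- if (length(diffs)) do.call(rbind, diffs) else
    data.frame(group = character(0), class = integer(0), male = numeric(0),
               female = numeric(0), abs_diff = numeric(0))
  list(cells = cells, differences = differences)
}

#' Prevalence report with the gender and minimum-count rules
#'
#' Formats corrected prevalences as percentages, one row per group, one
#' column per profile. Per-gender breakdowns (`"all (male/female)"`) are shown
#' only for profiles whose absolute male-female difference is at least
#' `threshold_pct` percentage points; groups with fewer than `min_n` subjects
#' are suppressed.
#'
#' @param dist an `sdqmix_groupdist` (overall estimates).
#' @param gender_cells optional result of [gender_interaction()] for the same
#'   groups, used for the per-gender breakdowns.
#' @param threshold_pct gender-difference reporting threshold in percentage
#'   points (default 20).
#' @param min_n minimum group size for a row to be reported (default 100).
#' @param labels optional profile labels used as column names.
#' @return data.frame of formatted percent strings, with attributes `tidy`
#'   (long-format numeric data.frame: group, class, n, prevalence_pct, male_pct,
#'   female_pct, reported_gender) and `suppressed` (suppressed group names).
#' @export
report_prevalence <- function(dist, gender_cells = NULL, threshold_pct = 20,
                              min_n = 100L, labels = NULL) {
  stopifnot(inherits(dist, "sdqmix_groupdist"))
  if (threshold_pct < 0 || min_n < 0) sdq_config_error("thresholds must be >= 0")
  K <- ncol(dist$theta)
  grp <- rownames(dist$theta)
  if (is.null(labels)) labels <- paste0("class", seq_len(K))
  suppressed <- grp[dist$n_g[grp] < min_n]
  shown <- setdiff(grp, suppressed)
  out <- data.frame(group = shown, n = as.integer(dist$n_g[shown]),
                    stringsAsFactors = FALSE)
  tidy <- list()
  for (c in seq_len(K)) {
    col <- character(length(shown))
    for (i in seq_along(shown)) {
      g <- shown[i]
      all_pct <- 100 * dist$theta[g, c]
      m_pct <- f_pct <- NA_real_
      show_gender <- FALSE
      if (!is.null(gender_cells)) {
        d <- gender_cells$differences
        row <- d[d$group == g & d$class == c, ]
        if (nrow(row) == 1 && is.finite(row$abs_diff)) {
          m_pct <- 100 * row$male
          f_pct <- 100 * row$female
          show_gender <- 100 * row$abs_diff >= threshold_pct
        }
      }
      col[i] <- if (show_gender) {
        sprintf("%.0f (%.0f/%.0f)", all_pct, m_pct, f_pct)
      } else {
        sprintf("%.0f", all_pct)
      }
      tidy[[length(tidy) + 1L]] <- data.frame(
        group = g, class = c, label = labels[c], n = as.integer(dist$n_g[g]),
        prevalence_pct = all_pct, male_pct = m_pct, female_pct = f_pct,
        reported_gender = show_gender, stringsAsFactors = FALSE)
    }
    out[[labels[c]]] <- col
  }
  tidy <- if (length(tidy)) do.call(rbind, tidy) else data.frame()
  attr(out, "tidy") <- tidy
  attr(out, "suppressed") <- suppressed
  out
}

#' Map diagnosis label sets to nominal diagnosis groups
#'
#' Implements the reporting scheme for diagnosis categories: a single known
#' disorder keeps its label; two known disorders form a combination label
#' (canonical order, joined by `" and "`); three or more become
#' `"Multi-problem"`; label sets containing only unknown disorders become
#' `"Other"`; an empty set becomes `"No diagnosis"`. Subjects outside the
#' CAMH setting (when `setting` is supplied) and subjects with unknown
#' diagnosis status map to `NA`.
#'
#' @param diagnoses character vector of semicolon-joined diagnosis labels
#'   (`""` = empty set, `NA` = unknown).
#' @param setting optional per-subject setting; when given, only `"CAMH"`
#'   subjects are grouped.
#' @param known ordered vector of recognized diagnosis categories.
#' @param mapping optional named character vector overriding the rule for
#'   specific raw label strings.
#' @return Character vector of group labels.
#' @export
diagnosis_group <- function(diagnoses, setting = NULL,
                            known = c("Anxiety/Mood", "CD/ODD", "ADHD", "ASD"),
                            mapping = NULL) {
  out <- rep(NA_character_, length(diagnoses))
  for (i in seq_along(diagnoses)) {
    if (!is.null(setting) && (is.na(setting[i]) || setting[i] != "CAMH")) next
    d <- diagnoses[i]
    if (is.na(d)) next
    if (!is.null(mapping) && d %in% names(mapping)) {
      out[i] <- mapping[[d]]
      next
    }
    labs <- setdiff(trimws(strsplit(d, ";", fixed = TRUE)[[1]]), "")
    if (!length(labs)) {
      out[i] <- "No diagnosis"
      next
    }
    kn <- known[known %in% labs]
    out[i] <- if (length(kn) >= 3) "Multi-problem"
      else if (length(kn) == 2) paste(kn, collapse = " and ")
      else if (length(kn) == 1) kn
      else "Other"
  }
  out
}
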