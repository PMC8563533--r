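# Profile interpretation: class-specific mean scores, cutoff-band
# classification, automatic profile labels, per-cluster informant tests, and
# the comparison analyses (total-difficulties banding; single-informant refit).

#' Build a cutoff configuration
#'
#' Per (informant, scale) — and per (informant, `"total_difficulties"`) — two
#' ordered boundaries partition the score scale into bands. For
#' `direction = "high_worse"` (difficulties scales) the boundaries are the
#' upper bounds of the normal and borderline bands: `score <= b1` is normal,
#' `b1 < score <= b2` borderline, higher abnormal. For
#' `direction = "low_worse"` (prosocial-type strengths scales) the boundaries
#' are the upper bounds of the abnormal and borderline bands: `score <= b1`
#' is abnormal, `b1 < score <= b2` borderline, higher normal. In both cases a
#' score exactly on a boundary falls in the band to its left
#' (boundary-inclusive-left rule).
#'
#' @param values nested named list: `values[[informant]][[scale]]` is either a
#'   numeric vector `c(b1, b2)` (direction inferred: `"low_worse"` for
#'   `"prosocial"`, `"high_worse"` otherwise) or a list with elements
#'   `boundaries` and `direction`.
#' @return An object of class `sdqmix_cutoffs`.
#' @seealso [read_cutoffs()], [example_cutoffs()]
#' @export
cutoff_config <- function(values) {
  for (inf in names(values)) {
    for (sc in names(values[[inf]])) {
      v <- values[[inf]][[sc]]
      if (is.numeric(v)) {
        v <- list(boundaries = v,
                  direction = if (sc == "prosocial") "low_worse" else "high_worse")
      }
      if (length(v$boundaries) != 2 || v$boundaries[1] > v$boundaries[2]) {
        sdq_config_error(sprintf("cutoffs for (%s, %s) need two ordered boundaries", inf, sc))
      }
      if (!v$direction %in% c("high_worse", "low_worse")) {
        sdq_config_error("direction must be 'high_worse' or 'low_worse'")
      }
      values[[inf]][[sc]] <- v
    }
  }
  structure(values, class = "sdqmix_cutoffs")
}

#' Read a cutoff configuration from YAML
#'
#' Expected layout: top-level keys are informants; under each, per-scale
#' entries with `boundaries: [b1, b2]` and optionally
#' `direction: high_worse|low_worse`.
#'
#' @param path YAML file path.
#' @return An `sdqmix_cutoffs` object.
#' @export
read_cutoffs <- function(path) {
  if (!file.exists(path)) sdq_config_error(sprintf("cutoff file not found: %s", path))
  raw <- yaml::read_yaml(path)
  raw <- lapply(raw, function(inf) {
    lapply(inf, function(v) {
      if (is.list(v) && !is.null(v$boundaries)) {
        list(boundaries = as.numeric(v$boundaries),
             direction = v$direction %||% "high_worse")
      } else {
        as.numeric(unlist(v))
      }
    })
  })
  cutoff_config(raw)
}

#' Illustrative cutoff configuration
#'
#' A complete cutoff set for the default five-subscale, two-informant frame,
#' including total-difficulties bands. The values are illustrative defaults
#' for demonstrations and tests; they are not the published British (or any
#' national) norm cutoffs, which must be supplied by the user via
#' [read_cutoffs()] for substantive use.
#'
#' @return An `sdqmix_cutoffs` object.
#' @export
example_cutoffs <- function() {
  one <- list(
    emotional = c(5, 6),
    conduct = c(3, 4),
    hyperactivity = c(5, 6),
    social = c(5, 6),
    prosocial = c(3, 4),          # low_worse inferred
    total_difficulties = c(15, 19))
  cutoff_config(list(self = one, parent = one))
}

#' Write a cutoff configuration to YAML
#'
#' @param cutoffs an `sdqmix_cutoffs` object.
#' @param path output file path.
#' @export
write_cutoffs <- function(cutoffs, path) {
  stopifnot(inherits(cutoffs, "sdqmix_cutoffs"))
  yaml::write_yaml(unclass(cutoffs), path)
  invisible(path)
}

#' Classify a score into a cutoff band
#'
#' @param score numeric score(s).
#' @param informant,scale which cutoff entry to use.
#' @param cutoffs an `sdqmix_cutoffs` object.
#' @return Character vector: `"normal"`, `"borderline"` or `"abnormal"`.
#' @export
classify_band <- function(score, informant, scale, cutoffs) {
  stopifnot(inherits(cutoffs, "sdqmix_cutoffs"))
  entry <- cutoffs[[informant]][[scale]]
  if (is.null(entry)) {
    sdq_config_error(sprintf("no cutoff entry for (%s, %s)", informant, scale))
  }
  b <- entry$boundaries
  low <- if (entry$direction == "high_worse") "normal" else "abnormal"
  high <- if (entry$direction == "high_worse") "abnormal" else "normal"
  ifelse(is.na(score), NA_character_,
         ifelse(score <= b[1], low, ifelse(score <= b[2], "borderline", high)))
}

#' Expected mean scores per (profile, informant, scale)
#'
#' `sum_k k * P(k | profile, informant, scale)`, plus the total-difficulties
#' mean (sum of the four difficulties-subscale means) per
#' (profile, informant) as the extra scale `"total_difficulties"`.
#'
#' @param params an `sdqmix_params` object (or an `sdqmix_fit`).
#' @return data.frame: class, informant, scale, mean.
#' @export
class_means <- function(params) {
  if (inherits(params, "sdqmix_fit")) params <- params$params
  stopifnot(inherits(params, "sdqmix_params"))
  kvec <- 0:(params$meta$n_categories - 1L)
  rows <- list()
  for (c in seq_len(params$K)) {
    for (j in params$meta$informants) {
      for (s in params$meta$scales) {
        rows[[length(rows) + 1L]] <- data.frame(
          class = c, informant = j, scale = s,
          mean = sum(kvec * category_probs(params, c, j, s)),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  diffs <- params$meta$difficulties
  tot <- aggregate(mean ~ class + informant, data = out[out$scale %in% diffs, ], FUN = sum)
  tot$scale <- "total_difficulties"
  rbind(out, tot[, c("class", "informant", "scale", "mean")])
}

#' Band classification of profile mean scores
#'
#' @param means data.frame from [class_means()].
#' @param cutoffs an `sdqmix_cutoffs` object.
#' @return `means` with an added `band` column.
#' @export
profile_bands <- function(means, cutoffs) {
  means$band <- NA_character_
  for (r in seq_len(nrow(means))) {
    means$band[r] <- classify_band(means$mean[r], means$informant[r],
                                   means$scale[r], cutoffs)
  }
  means
}

#' Automatic profile labels from band classifications
#'
#' A domain counts as affected when either informant's profile mean falls in
#' the borderline or abnormal band. A profile with no affected domain is
#' `"no difficulties"`; one whose worst band is borderline is
#' `"borderline <domains> difficulties"`; one with any abnormal band is
#' `"<domains> difficulties"`, or `"overall difficulties"` when four or more
#' domains are affected. Domains are listed in canonical scale order.
#'
#' @param bands data.frame from [profile_bands()] (subscale rows only are
#'   used; `"total_difficulties"` rows are ignored).
#' @param scales canonical scale order for listing domains.
#' @return Named character vector of labels, one per class.
#' @export
label_profiles <- function(bands, scales = NULL) {
  sub <- bands[bands$scale != "total_difficulties", ]
  if (is.null(scales)) scales <- unique(sub$scale)
  classes <- sort(unique(sub$class))
  out <- setNames(character(length(classes)), classes)
  for (i in seq_along(classes)) {
    ci <- sub[sub$class == classes[i], ]
    worst <- vapply(scales, function(s) {
      b <- ci$band[ci$scale == s]
      if (any(b == "abnormal", na.rm = TRUE)) "abnormal"
      else if (any(b == "borderline", na.rm = TRUE)) "borderline"
      else "normal"
    }, character(1))
    affected <- scales[worst != "normal"]
    out[i] <- if (!length(affected)) {
      "no difficulties"
    } else if (!any(worst == "abnormal")) {
      paste("borderline", domain_list(affected), "difficulties")
    } else if (length(affected) >= 4) {
      "overall difficulties"
    } else {
      paste(domain_list(affected), "difficulties")
    }
  }
  out
}

domain_list <- function(x) {
  n <- length(x)
  if (n == 1) x
  else if (n == 2) paste(x, collapse = " and ")
  else paste0(paste(x[-n], collapse = ", "), " and ", x[n])
}

#' Profile summary: means, bands, labels, prevalence
#'
#' @param fit an `sdqmix_fit`.
#' @param cutoffs an `sdqmix_cutoffs` object.
#' @return An object of class `sdqmix_profiles`: list with `means` (with
#'   bands), `labels`, `prevalence` (mixing proportions).
#' @export
profile_summary <- function(fit, cutoffs) {
  stopifnot(inherits(fit, "sdqmix_fit"))
  means <- profile_bands(class_means(fit$params), cutoffs)
  labels <- label_profiles(means, scales = fit$params$meta$scales)
  structure(list(means = means, labels = labels, prevalence = fit$params$pi),
            class = "sdqmix_profiles")
}

#' @export
print.sdqmix_profiles <- function(x, ...) {
  cat("<sdqmix_profiles>\n")
  for (c in seq_along(x$labels)) {
    cat(sprintf("  %d. %-45s pi=%.3f\n", c, shQuote(x$labels[c]), x$prevalence[c]))
  }
  invisible(x)
}

#' Paired informant tests per cluster and scale
#'
#' Within each cluster (by modal assignment), tests self vs parent mean score
#' differences per scale with paired t tests over subjects with both
#' informants observed, applying a Bonferroni correction whose multiplier is
#' the number of scales actually tested in that cluster. Significance is
#' flagged at `alpha` on the adjusted p value. Cells with fewer than two
#' complete pairs are skipped and flagged.
#'
#' @param data an `sdqmix_data` object (two-informant frame).
#' @param assignments per-subject modal assignments (same order as
#'   `data$subjects`).
#' @param alpha significance level (default 0.01).
#' @return data.frame: cluster, scale, n_pairs, mean_diff (self - parent), t,
#'   df, p, p_adj, significant, skipped.
#' @export
informant_tests <- function(data, assignments, alpha = 0.01) {
  stopifnot(inherits(data, "sdqmix_data"))
  if (length(data$informants) != 2) {
    sdq_config_error("informant_tests needs exactly two informants")
  }
  scores <- score_matrix(data)
  S <- length(data$scales)
  rows <- list()
  for (cl in sort(unique(assignments))) {
    members <- which(assignments == cl)
    cl_rows <- list()
    for (s in seq_len(S)) {
      a <- scores[members, s]                 # informant 1 (self)
      b <- scores[members, S + s]             # informant 2 (parent)
      ok <- !is.na(a) & !is.na(b)
      d <- a[ok] - b[ok]
      n <- length(d)
      if (n < 2) {
        cl_rows[[s]] <- data.frame(cluster = cl, scale = data$scales[s],
                                   n_pairs = n, mean_diff = NA_real_,
                                   t = NA_real_, df = NA_real_, p = NA_real_,
                                   skipped = TRUE, stringsAsFactors = FALSE)
        next
      }
      md <- mean(d)
      sdd <- stats::sd(d)
      if (sdd == 0) {
        tval <- if (md == 0) 0 else sign(md) * Inf
        p <- if (md == 0) 1 else 0
      } else {
        tval <- md / (sdd / sqrt(n))
        p <- 2 * stats::pt(-abs(tval), df = n - 1)
      }
      cl_rows[[s]] <- data.frame(cluster = cl, scale = data$scales[s],
                                 n_pairs = n, mean_diff = md, t = tval,
                                 df = n - 1, p = p, skipped = FALSE,
                                 stringsAsFactors = FALSE)
    }
    cl_tab <- do.call(rbind, cl_rows)
    n_tested <- sum(!cl_tab$skipped)
    cl_tab$p_adj <- pmin(1, cl_tab$p * n_tested)
    cl_tab$significant <- !cl_tab$skipped & cl_tab$p_adj < alpha
    rows[[length(rows) + 1L]] <- cl_tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("cluster", "scale", "n_pairs", "mean_diff", "t", "df", "p",
          "p_adj", "significant", "skipped")]
}

#' Profile prevalence per total-difficulties band
#'
#' Bands each subject's total difficulties score (sum of the four
#' difficulties subscales from the chosen informant's record; subjects with
#' any of the four unobserved are excluded) into `"normal"` versus the merged
#' `"borderline/abnormal"`, then estimates the corrected profile distribution
#' within each setting x band cell via [adjusted_distribution()], with the
#' error matrix `D` from the full sample held fixed.
#'
#' @param data an `sdqmix_data` object.
#' @param assignments per-subject modal assignments.
#' @param D classification error matrix from the full sample.
#' @param cutoffs an `sdqmix_cutoffs` with a `total_difficulties` entry for
#'   the chosen informant.
#' @param informant which informant's record to band on.
#' @return data.frame: setting, band, n, pct_within_setting, then one
#'   prevalence column per profile (proportions).
#' @export
crosstab_total_band <- function(data, assignments, D, cutoffs, informant) {
  stopifnot(inherits(data, "sdqmix_data"))
  scores <- score_matrix(data)
  S <- length(data$scales)
  j <- resolve_index(informant, data$informants, "informant")
  diffs <- match(sdq_difficulties(data$scales), data$scales)
  block <- scores[, (j - 1L) * S + diffs, drop = FALSE]
  total <- rowSums(block)                      # NA when any subscale unobserved
  band <- classify_band(total, informant, "total_difficulties", cutoffs)
  band[band %in% c("borderline", "abnormal")] <- "borderline/abnormal"
  setting <- data$subjects$setting
  keep <- !is.na(band) & !is.na(setting)
  cell <- ifelse(keep, paste(setting, band, sep = "|"), NA)
  dist <- adjusted_distribution(assignments, D, cell)
  n_setting <- table(setting[keep])
  parts <- strsplit(rownames(dist$theta), "|", fixed = TRUE)
  out <- data.frame(setting = vapply(parts, `[`, "", 1),
                    band = vapply(parts, `[`, "", 2),
                    n = as.integer(dist$n_g),
                    stringsAsFactors = FALSE)
  out$pct_within_setting <- 100 * out$n / as.numeric(n_setting[out$setting])
  th <- as.data.frame(dist$theta)
  rownames(th) <- NULL
  cbind(out, th)
}

#' Compare the multi-informant solution with a single-informant refit
#'
#' Refits the model-selection pipeline on the data restricted to one
#' informant's records and cross-classifies the modal assignments of the two
#' solutions. Full-solution profiles are mapped to the single-informant
#' profile that captures most of their members; profiles of the full solution
#' that map onto a common single-informant profile are reported as merged.
#'
#' @param data an `sdqmix_data` object with both informants.
#' @param full_fit the fit on the full (multi-informant) data.
#' @param informant which informant to retain.
#' @param K_range candidate profile counts for the refit.
#' @param ... further arguments passed to [select_model()].
#' @return An object of class `sdqmix_si_comparison`: list with `K_full`,
#'   `K_single`, `selection` (single-informant selection table), `crosstab`
#'   (full x single modal cross-classification), `mapping` (full class ->
#'   single class), `merged` (list of full-class groups sharing a single
#'   class), `prevalence_full`, `prevalence_single`.
#' @export
single_informant_comparison <- function(data, full_fit, informant = "self",
                                        K_range = 1:8, ...) {
  stopifnot(inherits(data, "sdqmix_data"), inherits(full_fit, "sdqmix_fit"))
  keep <- data$records$informant == informant
  if (!any(keep)) {
    sdq_validation_error(sprintf("no records for informant '%s'", informant))
  }
  sub <- sdq_data(data$subjects, data$records[keep, , drop = FALSE],
                  scales = data$scales, informants = informant,
                  n_categories = data$n_categories)
  sel <- select_model(sub, K_range = K_range, ...)
  single_fit <- sel$best_fit
  full_modal <- full_fit$modal
  single_modal <- single_fit$modal
  crosstab <- table(full = full_modal, single = single_modal)
  mapping <- apply(crosstab, 1, which.max)
  merged <- split(as.integer(rownames(crosstab)), mapping)
  merged <- merged[vapply(merged, length, 1L) >= 2]
  structure(list(K_full = full_fit$params$K, K_single = single_fit$params$K,
                 selection = sel$table, crosstab = crosstab,
                 mapping = mapping, merged = unname(merged),
                 prevalence_full = full_fit$params$pi,
                 prevalence_single = single_fit$params$pi,
                 single_fit = single_fit),
            class = "sdqmix_si_comparison")
}

#' @export
print.sdqmix_si_comparison <- function(x, ...) {
  cat(sprintf("<sdqmix_si_comparison> K full=%d, single=%d\n", x$K_full, x$K_single))
  print(x$crosstab)
  if (length(x$merged)) {
    for (g in x$merged) {
      cat(sprintf("  full profiles {%s} map to one single-informant profile\n",
                  paste(g, collapse = ", ")))
    }
  } else {
    cat("  no merged profiles\n")
  }
  invisible(x)
}
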