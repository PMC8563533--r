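# End-to-end pipeline: fit/select -> profile -> three-step -> comparison
# reports, with a manifest, a structured run log, and deterministic outputs
# given a seed.

#' Pipeline run configuration
#'
#' @param K_range candidate profile counts (default 1-8).
#' @param n_starts,tol,max_iter EM settings (see [em_fit()]).
#' @param seed top-level seed; every stage derives its randomness from it.
#' @param cutoffs an `sdqmix_cutoffs` object, or the path to a cutoff YAML;
#'   `NULL` makes the profiling stage fail with a configuration error.
#' @param gender_threshold_pct gender-difference reporting threshold
#'   (percentage points, default 20).
#' @param min_group_n minimum group size for prevalence reporting
#'   (default 100).
#' @param min_cell minimum gender-cell size before flagging (default 10).
#' @param compare_single_informant refit on self-report only and compare
#'   (adds one model-selection run per call).
#' @param parameterization response model passed to [em_fit()].
#' @param diagnosis_known recognized diagnosis categories for grouping.
#' @return An object of class `sdqmix_run_config`.
#' @export
run_config <- function(K_range = 1:8, n_starts = 20L, tol = 1e-8,
                       max_iter = 500L, seed = 1L, cutoffs = NULL,
                       gender_threshold_pct = 20, min_group_n = 100L,
                       min_cell = 10L, compare_single_informant = TRUE,
                       parameterization = "adjacent",
                       diagnosis_known = c("Anxiety/Mood", "CD/ODD", "ADHD", "ASD")) {
  if (!length(K_range)) sdq_config_error("K_range must be non-empty")
  if (gender_threshold_pct < 0 || min_group_n < 0) {
    sdq_config_error("reporting thresholds must be >= 0")
  }
  structure(list(K_range = K_range, n_starts = n_starts, tol = tol,
                 max_iter = max_iter, seed = seed, cutoffs = cutoffs,
                 gender_threshold_pct = gender_threshold_pct,
                 min_group_n = min_group_n, min_cell = min_cell,
                 compare_single_informant = compare_single_informant,
                 parameterization = parameterization,
                 diagnosis_known = diagnosis_known),
            class = "sdqmix_run_config")
}

#' Run the full three-step analysis pipeline
#'
#' Stages: (1) fit and select the mixture over `config$K_range` by BIC;
#' (2) write posteriors and the fitted model; (3) profile interpretation
#' (means, bands, labels, informant tests); (4) three-step corrected
#' prevalence by setting and by diagnosis group, each with the gender
#' interaction and reporting rules; (5) comparisons (total-difficulties-band
#' crosstabs per informant; optional single-informant refit). Each stage's
#' outputs are written as CSV/JSON under `out_dir` as soon as they are
#' available; `manifest.json` records per-stage status, so a later stage
#' failing leaves earlier outputs intact (the error is re-signalled after the
#' manifest is written). All numeric outputs are deterministic given
#' `config$seed`; only `run_log.json` (timings, timestamps) varies between
#' identical runs.
#'
#' @param data an `sdqmix_data` object.
#' @param config an `sdqmix_run_config`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the fitted objects (`selection`, `fit`,
#'   `profiles`, `threestep`, `comparisons`) and `out_dir`.
#' @export
run_pipeline <- function(data, config, out_dir) {
  stopifnot(inherits(data, "sdqmix_data"), inherits(config, "sdqmix_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(stages = list())
  timings <- list()
  t_all <- proc.time()[["elapsed"]]
  results <- list(out_dir = out_dir)
  failed <- NULL

  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  finish_log <- function() {
    log <- list(seed = config$seed,
                package_version = as.character(utils::packageVersion("sdqmix")),
                r_version = R.version.string,
                timestamp = format(Sys.time(), tz = "UTC"),
                n_subjects = nrow(data$subjects),
                n_records = nrow(data$records),
                timings_sec = timings)
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  stage <- function(name, expr) {
    if (!is.null(failed)) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) e)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res),
                                       class = class(res)[1])
      failed <<- res
      invisible(NULL)
    } else {
      manifest$stages[[name]] <<- list(status = "ok")
      res
    }
  }
  num_csv <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE, na = "")
  }

  # -- stage: select ---------------------------------------------------------
  sel <- stage("select", {
    select_model(data, K_range = config$K_range, n_starts = config$n_starts,
                 seed = config$seed, tol = config$tol,
                 max_iter = config$max_iter,
                 parameterization = config$parameterization)
  })
  if (!is.null(sel)) {
    results$selection <- sel
    fit <- sel$best_fit
    results$fit <- fit
    num_csv(sel$table, "selection.csv")
    save_model(fit$params, file.path(out_dir, "model.json"))
    post <- data.frame(id = data$subjects$id, stringsAsFactors = FALSE)
    for (c in seq_len(fit$params$K)) post[[paste0("prob_", c)]] <- fit$posteriors[, c]
    post$modal <- fit$modal
    num_csv(post, "posteriors.csv")
  }

  # -- stage: profile --------------------------------------------------------
  prof <- stage("profile", {
    cutoffs <- config$cutoffs
    if (is.null(cutoffs)) sdq_config_error("no cutoff configuration supplied")
    if (is.character(cutoffs)) cutoffs <- read_cutoffs(cutoffs)
    summary <- profile_summary(results$fit, cutoffs)
    tests <- informant_tests(data, results$fit$modal)
    list(summary = summary, tests = tests, cutoffs = cutoffs)
  })
  if (!is.null(prof)) {
    results$profiles <- prof
    num_csv(prof$summary$means, "profile_means.csv")
    num_csv(data.frame(class = seq_along(prof$summary$labels),
                       label = prof$summary$labels,
                       prevalence = prof$summary$prevalence),
            "profile_labels.csv")
    num_csv(prof$tests, "informant_tests.csv")
  }

  # -- stage: threestep ------------------------------------------------------
  ts <- stage("threestep", {
    fit <- results$fit
    K <- fit$params$K
    labels <- if (!is.null(results$profiles)) results$profiles$summary$labels
      else paste0("class", seq_len(K))
    if (K < 2) {
      list(trivial = TRUE, labels = labels)
    } else {
      D <- error_matrix(fit$posteriors, fit$modal)
      subj <- data$subjects
      by_setting <- adjusted_distribution(fit$modal, D, subj$setting)
      gi_setting <- gender_interaction(fit$modal, D, subj$setting, subj$gender,
                                       min_cell = config$min_cell)
      dgroup <- diagnosis_group(subj$diagnoses, subj$setting,
                                known = config$diagnosis_known)
      by_diag <- adjusted_distribution(fit$modal, D, dgroup)
      gi_diag <- gender_interaction(fit$modal, D, dgroup, subj$gender,
                                    min_cell = config$min_cell)
      list(trivial = FALSE, D = D, labels = labels,
           by_setting = by_setting, gi_setting = gi_setting,
           report_setting = report_prevalence(by_setting, gi_setting,
                                              config$gender_threshold_pct,
                                              min_n = 0L, labels = labels),
           by_diagnosis = by_diag, gi_diagnosis = gi_diag,
           report_diagnosis = report_prevalence(by_diag, gi_diag,
                                                config$gender_threshold_pct,
                                                min_n = config$min_group_n,
                                                labels = labels))
    }
  })
  if (!is.null(ts)) {
    results$threestep <- ts
    if (isTRUE(ts$trivial)) {
      num_csv(data.frame(note = "single-profile solution: all prevalences are 1"),
              "threestep_setting.csv")
    } else {
      num_csv(as.data.frame(ts$D), "error_matrix.csv")
      num_csv(ts$report_setting, "threestep_setting.csv")
      num_csv(attr(ts$report_setting, "tidy"), "threestep_setting_tidy.csv")
      num_csv(ts$report_diagnosis, "threestep_diagnosis.csv")
      num_csv(attr(ts$report_diagnosis, "tidy"), "threestep_diagnosis_tidy.csv")
      num_csv(ts$gi_setting$differences, "gender_differences_setting.csv")
      num_csv(ts$gi_diagnosis$differences, "gender_differences_diagnosis.csv")
    }
  }

  # -- stage: compare --------------------------------------------------------
  cmp <- stage("compare", {
    out <- list()
    if (!is.null(results$threestep) && !isTRUE(results$threestep$trivial) &&
        !is.null(results$profiles)) {
      for (inf in data$informants) {
        out[[paste0("crosstab_", inf)]] <- crosstab_total_band(
          data, results$fit$modal, results$threestep$D,
          results$profiles$cutoffs, inf)
      }
    }
    if (config$compare_single_informant && length(data$informants) > 1) {
      out$single_informant <- single_informant_comparison(
        data, results$fit, informant = data$informants[1],
        K_range = config$K_range, n_starts = config$n_starts,
        seed = derive_seed(config$seed, 31), tol = config$tol,
        max_iter = config$max_iter,
        parameterization = config$parameterization)
    }
    out
  })
  if (!is.null(cmp)) {
    results$comparisons <- cmp
    for (nm in names(cmp)) {
      if (startsWith(nm, "crosstab_")) num_csv(cmp[[nm]], paste0(nm, ".csv"))
    }
    if (!is.null(cmp$single_informant)) {
      si <- cmp$single_informant
      num_csv(as.data.frame.matrix(si$crosstab), "single_informant_crosstab.csv")
      num_csv(data.frame(full_class = seq_along(si$mapping),
                         single_class = as.integer(si$mapping),
                         prevalence_full = si$prevalence_full),
              "single_informant_mapping.csv")
    }
  }

  timings$total <- round(proc.time()[["elapsed"]] - t_all, 3)
  write_manifest()
  finish_log()
  if (!is.null(failed)) stop(failed)
  invisible(results)
}
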