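#' Assemble a multi-informant SDQ dataset
#'
#' Bundles a subject table and an informant-record table into the container
#' used by all model-fitting and reporting functions, after validating both
#' against the configured scales, informants and score range.
#'
#' @param subjects data.frame with columns `id`, and optionally `gender`
#'   (`"male"`/`"female"` or `NA`), `setting` (`"community"`, `"CASC"`,
#'   `"CAMH"` or `NA`) and `diagnoses` (semicolon-joined label set; `""` means
#'   an empty set, `NA` means unknown).
#' @param records data.frame with columns `id`, `informant`, and one integer
#'   column per scale in `scales`. Scores must lie in
#'   `0 .. n_categories - 1`; `NA` marks an unobserved scale.
#' @param scales character vector of subscale names; the default is the five
#'   SDQ subscales.
#' @param informants character vector of informant names.
#' @param n_categories number of ordinal score categories per scale
#'   (default 11: subscale totals 0-10).
#' @return An object of class `sdqmix_data`: a list with elements `subjects`,
#'   `records`, `scales`, `informants`, `n_categories`.
#' @examples
#' subj <- data.frame(id = c("a", "b"), gender = c("male", "female"),
#'                    setting = c("community", "CAMH"), diagnoses = c("", "ADHD"))
#' rec <- data.frame(id = c("a", "a", "b"), informant = c("self", "parent", "self"),
#'                   emotional = c(2L, 3L, 8L), conduct = c(1L, 1L, 6L),
#'                   hyperactivity = c(4L, 3L, 9L), social = c(0L, 2L, 7L),
#'                   prosocial = c(9L, 8L, 3L))
#' d <- sdq_data(subj, rec)
#' d
#' @export
sdq_data <- function(subjects, records,
                     scales = sdq_default_scales(),
                     informants = sdq_default_informants(),
                     n_categories = 11L) {
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"id" %in% names(subjects)) sdq_validation_error("subjects table needs an 'id' column")
  for (col in c("gender", "setting", "diagnoses")) {
    if (!col %in% names(subjects)) subjects[[col]] <- NA_character_
  }
  subjects$id <- as.character(subjects$id)
  if (anyDuplicated(subjects$id)) {
    sdq_validation_error(sprintf("duplicate subject ids: %s",
                                 paste(unique(subjects$id[duplicated(subjects$id)]), collapse = ", ")))
  }

  need <- c("id", "informant", scales)
  missing_cols <- setdiff(need, names(records))
  if (nrow(records) == 0 && length(missing_cols)) {
    records <- as.data.frame(setNames(rep(list(logical(0)), length(need)), need))
    missing_cols <- character(0)
  }
  if (length(missing_cols)) {
    sdq_validation_error(sprintf("records table lacks columns: %s",
                                 paste(missing_cols, collapse = ", ")))
  }
  records <- records[, need, drop = FALSE]
  records$id <- as.character(records$id)
  records$informant <- as.character(records$informant)

  problems <- character(0)
  bad_inf <- which(!records$informant %in% informants)
  if (length(bad_inf)) {
    problems <- c(problems, sprintf("row %d: unknown informant '%s'",
                                    bad_inf, records$informant[bad_inf]))
  }
  orphan <- which(!records$id %in% subjects$id)
  if (length(orphan)) {
    problems <- c(problems, sprintf("row %d: record id '%s' has no subject row",
                                    orphan, records$id[orphan]))
  }
  key <- paste(records$id, records$informant)
  dup <- which(duplicated(key))
  if (length(dup)) {
    problems <- c(problems, sprintf("row %d: duplicate record for (%s)", dup, key[dup]))
  }
  for (s in scales) {
    v <- records[[s]]
    if (is.character(v)) v[v == ""] <- NA
    v_num <- suppressWarnings(as.numeric(v))
    bad_parse <- which(!is.na(v) & is.na(v_num))
    v_int <- suppressWarnings(as.integer(round(v_num)))
    not_int <- which(!is.na(v_num) & abs(v_num - round(v_num)) > 1e-9)
    out_rng <- which(!is.na(v_int) & (v_int < 0L | v_int >= n_categories))
    for (i in bad_parse) {
      problems <- c(problems, sprintf("row %d: %s score '%s' is not a number", i, s, v[i]))
    }
    for (i in not_int) {
      problems <- c(problems, sprintf("row %d: %s score %s is not an integer", i, s, v[i]))
    }
    for (i in out_rng) {
      problems <- c(problems, sprintf("row %d: %s score %d outside 0..%d",
                                      i, s, v_int[i], n_categories - 1L))
    }
    records[[s]] <- v_int
  }
  if (length(problems)) {
    sdq_validation_error(paste0("invalid records:\n  ",
                                paste(utils::head(problems, 20), collapse = "\n  ")))
  }

  structure(list(subjects = subjects, records = records, scales = scales,
                 informants = informants, n_categories = as.integer(n_categories)),
            class = "sdqmix_data")
}

#' @export
print.sdqmix_data <- function(x, ...) {
  cat(sprintf("<sdqmix_data> %d subjects, %d informant records\n",
              nrow(x$subjects), nrow(x$records)))
  cat(sprintf("  scales: %s (0..%d)\n", paste(x$scales, collapse = ", "),
              x$n_categories - 1L))
  tab <- table(factor(x$records$informant, levels = x$informants))
  cat(sprintf("  records per informant: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Read a dataset from subjects/records CSV files
#'
#' CSV dialect: UTF-8, comma-separated, header row. Empty score cells become
#' missing values. Malformed rows are reported with their row numbers.
#'
#' @param subjects_path path to the subjects CSV.
#' @param records_path path to the records CSV.
#' @inheritParams sdq_data
#' @return An `sdqmix_data` object.
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(subjects_path, records_path,
                         scales = sdq_default_scales(),
                         informants = sdq_default_informants(),
                         n_categories = 11L) {
  for (p in c(subjects_path, records_path)) {
    if (!file.exists(p)) sdq_validation_error(sprintf("file not found: %s", p))
  }
  subjects <- utils::read.csv(subjects_path, stringsAsFactors = FALSE,
                              colClasses = "character")
  records <- utils::read.csv(records_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  sdq_data(subjects, records, scales = scales, informants = informants,
           n_categories = n_categories)
}

#' Write a dataset to subjects/records CSV files
#'
#' @param data an `sdqmix_data` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the two file paths written (`subjects.csv`,
#'   `records.csv`).
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "sdqmix_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ps <- file.path(dir, "subjects.csv")
  pr <- file.path(dir, "records.csv")
  utils::write.csv(data$subjects, ps, row.names = FALSE, na = "")
  utils::write.csv(data$records, pr, row.names = FALSE, na = "")
  invisible(c(subjects = ps, records = pr))
}

# n x (J*S) integer score matrix (0-based categories, NA = unobserved),
# columns ordered informant-major: (informant 1, scale 1..S), (informant 2, ...)
score_matrix <- function(data) {
  subj_ids <- data$subjects$id
  n <- length(subj_ids)
  J <- length(data$informants)
  S <- length(data$scales)
  out <- matrix(NA_integer_, n, J * S)
  colnames(out) <- as.vector(t(outer(data$informants, data$scales, paste, sep = ".")))
  if (nrow(data$records)) {
    row_idx <- match(data$records$id, subj_ids)
    inf_idx <- match(data$records$informant, data$informants)
    for (j in seq_len(J)) {
      sel <- which(inf_idx == j)
      if (!length(sel)) next
      for (s in seq_len(S)) {
        out[row_idx[sel], (j - 1L) * S + s] <- data$records[[data$scales[s]]][sel]
      }
    }
  }
  rownames(out) <- subj_ids
  out
}
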