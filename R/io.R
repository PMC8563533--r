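# Versioned JSON serialization of fitted models, and batch scoring of new
# cases from a saved model.

MODEL_SCHEMA_VERSION <- "1.0"

#' Save fitted mixture parameters to JSON
#'
#' Writes a versioned, full-precision JSON representation of an
#' `sdqmix_params` object so fitted models can be shipped and used to score
#' new cases. Round-trips bit-exactly through [load_model()].
#'
#' @param params an `sdqmix_params` object (or an `sdqmix_fit`, whose
#'   parameters are saved).
#' @param path output file path.
#' @export
save_model <- function(params, path) {
  if (inherits(params, "sdqmix_fit")) params <- params$params
  stopifnot(inherits(params, "sdqmix_params"))
  obj <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    parameterization = params$parameterization,
    K = params$K,
    pi = params$pi,
    scales = params$meta$scales,
    informants = params$meta$informants,
    n_categories = params$meta$n_categories,
    difficulties = params$meta$difficulties,
    fit = params$meta$fit
  )
  if (params$parameterization == "adjacent") {
    obj$beta <- as.numeric(params$beta)
    obj$alpha <- as.numeric(params$alpha)
  } else {
    obj$logp <- as.numeric(params$logp)
  }
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Load fitted mixture parameters from JSON
#'
#' @param path path to a file written by [save_model()].
#' @return An `sdqmix_params` object.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) sdq_config_error(sprintf("model file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema_version, MODEL_SCHEMA_VERSION)) {
    sdq_config_error(sprintf("unsupported model schema version '%s' (expected %s)",
                             obj$schema_version, MODEL_SCHEMA_VERSION))
  }
  K <- as.integer(obj$K)
  J <- length(obj$informants)
  S <- length(obj$scales)
  m <- as.integer(obj$n_categories)
  fit <- obj$fit
  if (params_is_adjacent <- identical(obj$parameterization, "adjacent")) {
    mixture_params(obj$pi, array(obj$beta, dim = c(K, J, S)),
                   array(obj$alpha, dim = c(J, S, m)),
                   scales = obj$scales, informants = obj$informants,
                   n_categories = m, fit = fit)
  } else {
    mixture_params(obj$pi, beta = NULL, scales = obj$scales,
                   informants = obj$informants, n_categories = m,
                   parameterization = "multinomial",
                   logp = array(obj$logp, dim = c(K, J, S, m)), fit = fit)
  }
}

#' Score new cases with a fitted model
#'
#' Computes posterior profile-membership probabilities and modal assignments
#' for each subject in a records table, from any combination of observed
#' informants and subscale scores. Subjects with no observed scores receive
#' the prior mixing proportions.
#'
#' @param model an `sdqmix_params` object, an `sdqmix_fit`, or the path to a
#'   model JSON written by [save_model()].
#' @param records a records data.frame (columns `id`, `informant`, one per
#'   scale) or the path to a records CSV.
#' @param labels optional profile labels for the modal column.
#' @return data.frame: `id`, one probability column per profile
#'   (`prob_1 .. prob_K`), `modal` (index) and `modal_label`.
#' @export
score_cases <- function(model, records, labels = NULL) {
  params <- if (inherits(model, "sdqmix_fit")) model$params
    else if (inherits(model, "sdqmix_params")) model
    else load_model(model)
  if (is.character(records) && length(records) == 1) {
    records <- utils::read.csv(records, stringsAsFactors = FALSE,
                               colClasses = "character")
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  scales <- params$meta$scales
  missing_cols <- setdiff(c("id", "informant", scales), names(records))
  if (length(missing_cols)) {
    sdq_config_error(sprintf("records lack the model's columns: %s",
                             paste(missing_cols, collapse = ", ")))
  }
  ids <- unique(as.character(records$id))
  subjects <- data.frame(id = ids, stringsAsFactors = FALSE)
  data <- sdq_data(subjects, records, scales = scales,
                   informants = params$meta$informants,
                   n_categories = params$meta$n_categories)
  W <- posterior_matrix(score_matrix(data), params)
  modal <- max.col(W, ties.method = "first")
  out <- data.frame(id = data$subjects$id, stringsAsFactors = FALSE)
  for (c in seq_len(params$K)) out[[paste0("prob_", c)]] <- W[, c]
  out$modal <- modal
  if (is.null(labels)) labels <- paste0("class", seq_len(params$K))
  out$modal_label <- labels[modal]
  out
}
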