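#' Cohort containers
#'
#' A *paired cohort* bundles a genes x samples log2 expression matrix with the
#' per-patient normal/tumor pairing for one cancer type; a *survival cohort*
#' bundles an expression matrix with a clinical table (time-to-event, event
#' indicator, optional covariates). Both are lightweight lists with validated
#' structure; downstream functions accept and return them.
#'
#' @param expression numeric matrix, genes in rows (unique rownames), samples
#'   in columns (unique colnames), log2 units, all values finite.
#' @param pairs tibble with columns `patient_id`, `normal_sample_id`,
#'   `tumor_sample_id`; every sample id must be a column of `expression`.
#' @param cancer single string labelling the cancer type.
#' @param clinical tibble with columns `sample_id`, `time` (> 0), `event`
#'   (0/1), plus any covariate columns; sample ids must be unique and present
#'   in `expression`.
#' @param name optional cohort identifier string.
#'
#' @return An object of class `paired_cohort` or `survival_cohort`.
#' @name cohorts
NULL

validate_expression <- function(expression, arg = "expression") {
  if (!is.matrix(expression) || !is.numeric(expression)) {
    abort(sprintf("`%s` must be a numeric matrix", arg), class = "progsig_validation_error")
  }
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    abort(sprintf("`%s` must have gene rownames and sample colnames", arg),
          class = "progsig_validation_error")
  }
  if (anyDuplicated(rownames(expression))) {
    abort("duplicate gene ids in expression matrix", class = "progsig_validation_error")
  }
  if (anyDuplicated(colnames(expression))) {
    abort("duplicate sample ids in expression matrix", class = "progsig_validation_error")
  }
  if (!all(is.finite(expression))) {
    abort("expression matrix contains non-finite values", class = "progsig_validation_error")
  }
  invisible(expression)
}

#' @rdname cohorts
#' @export
paired_cohort <- function(expression, pairs, cancer) {
  validate_expression(expression)
  pairs <- as_tibble(pairs)
  needed <- c("patient_id", "normal_sample_id", "tumor_sample_id")
  if (!all(needed %in% names(pairs))) {
    abort(paste("`pairs` needs columns", paste(needed, collapse = ", ")),
          class = "progsig_validation_error")
  }
  samp <- c(pairs$normal_sample_id, pairs$tumor_sample_id)
  if (anyDuplicated(samp)) {
    abort("a sample id appears in more than one pair slot", class = "progsig_validation_error")
  }
  missing <- setdiff(samp, colnames(expression))
  if (length(missing)) {
    abort(sprintf("paired sample ids absent from expression matrix: %s",
                  paste(head(missing, 5), collapse = ", ")),
          class = "progsig_validation_error")
  }
  structure(list(expression = expression, pairs = pairs,
                 cancer = as.character(cancer)[1]),
            class = "paired_cohort")
}

#' @rdname cohorts
#' @export
survival_cohort <- function(expression, clinical, name = "cohort") {
  validate_expression(expression)
  clinical <- validate_clinical(clinical)
  missing <- setdiff(clinical$sample_id, colnames(expression))
  if (length(missing)) {
    abort(sprintf("clinical sample ids absent from expression matrix: %s",
                  paste(head(missing, 5), collapse = ", ")),
          class = "progsig_validation_error")
  }
  structure(list(expression = expression, clinical = clinical,
                 name = as.character(name)[1]),
            class = "survival_cohort")
}

validate_clinical <- function(clinical) {
  clinical <- as_tibble(clinical)
  needed <- c("sample_id", "time", "event")
  if (!all(needed %in% names(clinical))) {
    abort("clinical table needs columns sample_id, time, event",
          class = "progsig_validation_error")
  }
  if (anyDuplicated(clinical$sample_id)) {
    abort("duplicate sample ids in clinical table", class = "progsig_validation_error")
  }
  if (any(!is.finite(clinical$time)) || any(clinical$time <= 0)) {
    abort("clinical `time` must be finite and > 0", class = "progsig_validation_error")
  }
  if (!all(clinical$event %in% c(0, 1))) {
    abort("clinical `event` must be 0/1", class = "progsig_validation_error")
  }
  clinical
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("<paired_cohort> %s: %d genes, %d pairs\n",
              x$cancer, nrow(x$expression), nrow(x$pairs)))
  invisible(x)
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("<survival_cohort> %s: %d genes, %d samples, %d events\n",
              x$name, nrow(x$expression), nrow(x$clinical), sum(x$clinical$event)))
  invisible(x)
}
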