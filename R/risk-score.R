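#' Univariate Cox proportional-hazards fit
#'
#' Fits recurrence-free survival on a single continuous or binary covariate
#' by partial likelihood (Efron tie handling by default) and reports the
#' coefficient, its standard error, the Wald statistic `z = beta/se`, the
#' hazard ratio and its 95% CI. The default engine is `survival::coxph`; the
#' `"fast"` engine is this package's own Newton-Raphson fit of the same
#' partial likelihood (used inside resampling loops), and the two agree to
#' numerical tolerance.
#'
#' @param x numeric covariate (e.g. one gene's expression), one value per
#'   sample.
#' @param time,event survival time (> 0) and 0/1 event indicator.
#' @param ties `"efron"` or `"breslow"` (survival engine only).
#' @param engine `"survival"` or `"fast"`.
#' @return one-row tibble: `estimate`, `se`, `z`, `hr`, `conf.low`,
#'   `conf.high`, `p.value`, `n`, `n_event`.
#' @export
fit_univariate_cox <- function(x, time, event, ties = "efron",
                               engine = c("survival", "fast")) {
  engine <- match.arg(engine)
  ok <- is.finite(x) & is.finite(time) & !is.na(event)
  x <- x[ok]; time <- time[ok]; event <- event[ok]
  if (sum(event) < 2) abort("need at least 2 events", class = "progsig_data_error")
  if (sd(x) == 0) abort("covariate has zero variance",
                        class = "progsig_degenerate_error")
  if (engine == "survival") {
    fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = ties)
    beta <- unname(fit$coefficients)
    se <- sqrt(unname(fit$var[1, 1]))
  } else {
    res <- .cox_uni_fast(x, time, as.integer(event))
    beta <- res[1]
    se <- res[2]
  }
  z <- beta / se
  tibble(estimate = beta, se = se, z = z, hr = exp(beta),
         conf.low = exp(beta - 1.96 * se), conf.high = exp(beta + 1.96 * se),
         p.value = 2 * pnorm(abs(z), lower.tail = FALSE),
         n = length(x), n_event = sum(event))
}

new_scoring_model <- function(tb, training_cohort = NA_character_,
                              created = NA_character_) {
  stopifnot(all(c("gene", "z", "mu", "tau") %in% names(tb)))
  if (any(tb$tau <= 0)) abort("tau must be > 0 for every gene",
                              class = "progsig_validation_error")
  if (anyDuplicated(tb$gene)) abort("duplicate genes in scoring model",
                                    class = "progsig_validation_error")
  structure(as_tibble(tb[c("gene", "z", "mu", "tau")]),
            training_cohort = training_cohort, created = created,
            class = c("scoring_model", class(as_tibble(tb))))
}

#' Train the frozen Wald-weighted scoring model
#'
#' For each signature gene present in the training cohort a univariate Cox
#' model of recurrence-free survival on that gene's expression yields the
#' Wald statistic `Z_i = beta_i / se_i`; the scaling coefficients `mu_i`,
#' `tau_i` are the mean and SD of the gene's expression across all training
#' samples. The resulting triple per gene is the frozen scoring system to be
#' applied unchanged to validation cohorts.
#'
#' Genes with constant expression (or failed fits) are dropped with a
#' warning; if more than half of the signature is missing from the training
#' matrix the call errors.
#'
#' @param training a [survival_cohort()].
#' @param signature character vector of signature gene ids.
#' @param ties tie handling passed to the Cox fit.
#' @param engine Cox engine, see [fit_univariate_cox()].
#' @return a `scoring_model`: tibble (gene, z, mu, tau) with training
#'   metadata attributes.
#' @export
build_scoring_model <- function(training, signature, ties = "efron",
                                engine = c("survival", "fast")) {
  stopifnot(inherits(training, "survival_cohort"))
  engine <- match.arg(engine)
  present <- intersect(signature, rownames(training$expression))
  if (length(present) < length(signature) / 2) {
    abort(sprintf("only %d of %d signature genes present in training matrix",
                  length(present), length(signature)),
          class = "progsig_data_error")
  }
  cl <- training$clinical
  if (sum(cl$event) < 2) abort("need at least 2 events", class = "progsig_data_error")
  expr <- training$expression[present, cl$sample_id, drop = FALSE]
  event <- as.integer(cl$event)
  fit_one <- if (engine == "fast") {
    function(x) {
      res <- .cox_uni_fast(x, cl$time, event)
      res[3]
    }
  } else {
    function(x) fit_univariate_cox(x, cl$time, cl$event, ties = ties)$z
  }
  stats <- vapply(present, function(g) {
    x <- expr[g, ]
    tau <- sd(x)
    if (!is.finite(tau) || tau == 0) return(c(NA_real_, NA_real_, NA_real_))
    z <- tryCatch(fit_one(x), error = function(e) NA_real_)
    c(z, mean(x), tau)
  }, numeric(3))
  ok <- is.finite(stats[1, ])
  n_drop <- sum(!ok)
  if (n_drop > 0) warn(sprintf("build_scoring_model: dropped %d degenerate genes",
                               n_drop))
  if (!any(ok)) abort("no signature gene could be fit",
                      class = "progsig_data_error")
  new_scoring_model(tibble(gene = present[ok], z = unname(stats[1, ok]),
                           mu = unname(stats[2, ok]), tau = unname(stats[3, ok])),
                    training_cohort = training$name,
                    created = format(Sys.time(), "%Y-%m-%d"))
}

#' Compute patient risk scores and dichotomize at the cohort median
#'
#' The risk score of a patient is `S = sum_i Z_i * (e_i - mu_i) / tau_i` over
#' the model genes present in the cohort, where `e_i` is the patient's
#' expression of gene `i` and `Z_i`, `mu_i`, `tau_i` come from the frozen
#' model. Patients with `S` strictly greater than the cohort median are
#' signature-positive. Genes missing from the cohort are dropped from the sum
#' (count reported); with `restandardize = TRUE` the scaling coefficients
#' `mu`, `tau` are recomputed on the scored cohort instead of reusing the
#' training values.
#'
#' @param model a `scoring_model`.
#' @param cohort a [survival_cohort()].
#' @param restandardize recompute mu/tau on this cohort (default FALSE:
#'   frozen training coefficients).
#' @return tibble `sample_id`, `score`, `group` (factor negative/positive),
#'   with attributes `median` and `n_genes_used`.
#' @export
compute_risk_scores <- function(model, cohort, restandardize = FALSE) {
  stopifnot(inherits(model, "scoring_model"), inherits(cohort, "survival_cohort"))
  present <- model$gene %in% rownames(cohort$expression)
  if (!any(present)) abort("no model gene present in cohort",
                           class = "progsig_data_error")
  if (any(!present)) {
    inform(sprintf("compute_risk_scores: %d of %d model genes absent from cohort",
                   sum(!present), nrow(model)))
  }
  m <- model[present, ]
  expr <- cohort$expression[m$gene, cohort$clinical$sample_id, drop = FALSE]
  if (restandardize) {
    m$mu <- rowMeans(expr)
    m$tau <- apply(expr, 1, sd)
    if (any(m$tau == 0)) {
      m <- m[m$tau > 0, ]
      expr <- expr[m$gene, , drop = FALSE]
      if (!nrow(m)) abort("all model genes constant in cohort",
                          class = "progsig_degenerate_error")
    }
  }
  scores <- drop(crossprod(expr, m$z / m$tau)) - sum(m$z * m$mu / m$tau)
  grp <- dichotomize(scores)
  out <- tibble(sample_id = cohort$clinical$sample_id,
                score = unname(scores), group = grp)
  attr(out, "median") <- median(scores)
  attr(out, "n_genes_used") <- nrow(m)
  out
}

#' Median dichotomization of risk scores
#'
#' Positive iff the score is strictly greater than the median; scores tied
#' with the median are negative. If every score is identical all patients are
#' negative and a warning is emitted.
#'
#' @param scores numeric vector (length >= 2).
#' @return factor with levels `negative`, `positive`.
#' @export
dichotomize <- function(scores) {
  if (length(scores) < 2) abort("need at least 2 samples",
                                class = "progsig_validation_error")
  med <- median(scores)
  if (all(scores == scores[1])) warn("all risk scores identical; every sample negative")
  factor(ifelse(scores > med, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' @export
print.scoring_model <- function(x, ...) {
  cat(sprintf("<scoring_model> %d genes (training: %s)\n",
              nrow(x), attr(x, "training_cohort")))
  NextMethod()
}
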