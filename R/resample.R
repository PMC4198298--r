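#' Draw random same-size gene signatures
#'
#' Uniform samples without replacement of `size` genes from `pool`,
#' reproducible under `seed`. These are the null signatures against which the
#' observed signature's prognostic power or coherence is compared.
#'
#' @param pool character vector of candidate genes.
#' @param size signature size (<= length(pool)).
#' @param n number of random signatures.
#' @param seed integer seed (required).
#' @return list of `n` character vectors.
#' @export
random_signatures <- function(pool, size, n, seed) {
  if (missing(seed)) abort("`seed` is required", class = "progsig_config_error")
  if (size > length(pool)) abort("size exceeds pool", class = "progsig_validation_error")
  if (n < 1) abort("n must be >= 1", class = "progsig_validation_error")
  set.seed(seed)
  replicate(n, sample(pool, size), simplify = FALSE)
}

#' One-tailed empirical p-value (add-one estimator)
#'
#' `p = (1 + #(null >= observed)) / (1 + N)` for the right tail — never zero,
#' and monotone non-increasing in the observed statistic.
#'
#' @param observed scalar statistic.
#' @param null numeric vector of null statistics.
#' @export
empirical_p <- function(observed, null) {
  if (!length(null)) abort("empty null sample", class = "progsig_validation_error")
  (1 + sum(null >= observed)) / (1 + length(null))
}

new_resampling_result <- function(observed, null_values, statistic_name,
                                  n_requested, n_skipped, seed) {
  structure(list(observed = observed, null_values = null_values,
                 p = empirical_p(observed, null_values),
                 statistic = statistic_name,
                 n_resamples = length(null_values),
                 n_requested = n_requested, n_skipped = n_skipped,
                 seed = seed),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("<resampling_result> %s\n  observed = %.4f, null n = %d (skipped %d), one-tailed p = %.4g\n",
              x$statistic, x$observed, x$n_resamples, x$n_skipped, x$p))
  invisible(x)
}

# run the full train -> score -> dichotomize -> Cox pipeline for one signature
# on one (training, validation) pair; returns the validation Wald z of the
# signature-positive group, or NULL on a degenerate failure.
signature_validation_z <- function(signature, training, validation,
                                   engine = "fast", restandardize = FALSE,
                                   ties = "efron") {
  tryCatch({
    model <- suppressWarnings(
      build_scoring_model(training, signature, ties = ties, engine = engine))
    risk <- suppressMessages(
      compute_risk_scores(model, validation, restandardize = restandardize))
    cl <- validation$clinical
    grp <- as.integer(risk$group == "positive")
    if (length(unique(grp)) < 2) return(NULL)
    fit <- fit_univariate_cox(grp, cl$time, cl$event, ties = ties,
                              engine = engine)
    fit$z
  }, error = function(e) NULL)
}

# Lean resampling engine: pre-aligns expression to clinical order once, then
# evaluates the train -> score -> dichotomize -> Cox pipeline per signature
# with the Newton-Raphson Cox fit and no intermediate containers. Mirrors the
# semantics of build_scoring_model()/compute_risk_scores()/fit_univariate_cox()
# exactly (an equivalence test asserts this); exists because each resample
# refits every signature gene.
pipeline_z_factory <- function(training, validation, restandardize = FALSE) {
  tr_expr <- training$expression[, training$clinical$sample_id, drop = FALSE]
  tr_time <- training$clinical$time
  tr_event <- as.integer(training$clinical$event)
  va_expr <- validation$expression[, validation$clinical$sample_id, drop = FALSE]
  va_time <- validation$clinical$time
  va_event <- as.integer(validation$clinical$event)
  function(genes) {
    present <- genes[genes %in% rownames(tr_expr) & genes %in% rownames(va_expr)]
    if (length(present) < length(genes) / 2) return(NULL)
    xs <- tr_expr[present, , drop = FALSE]
    z <- mu <- tau <- numeric(length(present))
    for (k in seq_along(present)) {
      x <- xs[k, ]
      tau_k <- sd(x)
      if (!is.finite(tau_k) || tau_k == 0) { z[k] <- NA_real_; next }
      res <- .cox_uni_fast(x, tr_time, tr_event)
      z[k] <- res[3]; mu[k] <- mean(x); tau[k] <- tau_k
    }
    ok <- is.finite(z)
    if (!any(ok)) return(NULL)
    present <- present[ok]; z <- z[ok]; mu <- mu[ok]; tau <- tau[ok]
    ev <- va_expr[present, , drop = FALSE]
    if (restandardize) {
      mu <- rowMeans(ev)
      tau <- apply(ev, 1, sd)
      keep <- tau > 0
      if (!any(keep)) return(NULL)
      ev <- ev[keep, , drop = FALSE]
      z <- z[keep]; mu <- mu[keep]; tau <- tau[keep]
    }
    scores <- drop(crossprod(ev, z / tau)) - sum(z * mu / tau)
    grp <- as.integer(scores > median(scores))
    if (all(grp == grp[1])) return(NULL)
    fit <- .cox_uni_fast(grp, va_time, va_event)
    if (!is.finite(fit[3])) return(NULL)
    fit[3]
  }
}

resample_loop <- function(signatures, stat_fun) {
  vals <- purrr::map(signatures, stat_fun)
  null_values <- purrr::compact(vals)
  n_skipped <- length(vals) - length(null_values)
  if (n_skipped / length(vals) > 0.05) {
    abort(sprintf("resampling failed: %d of %d resamples degenerate",
                  n_skipped, length(vals)),
          class = "progsig_numeric_error")
  }
  list(null = unlist(null_values), n_skipped = n_skipped)
}

#' Resampling test of non-random prognostic power
#'
#' The observed statistic is the validation-cohort Wald z of the dichotomized
#' signature status, computed through the full pipeline: per-gene univariate
#' Cox fits on the training cohort, frozen Wald-weighted scoring, validation
#' scoring, median dichotomization, and a univariate Cox fit of survival on
#' the positive/negative group. The identical pipeline is applied to `n`
#' random same-size signatures drawn from `pool`; the one-tailed p is the
#' right-tail add-one empirical p. Degenerate resamples are skipped and
#' counted; a skip fraction above 5% aborts the run.
#'
#' @param signature observed signature gene ids.
#' @param training,validation [survival_cohort()]s sharing a gene universe.
#' @param pool gene pool from which null signatures are drawn.
#' @param n_resamples number of random signatures (the study convention is
#'   1,000; tests use fewer).
#' @param seed integer seed (required).
#' @param engine Cox engine for the per-gene fits (default the fast
#'   Newton-Raphson engine).
#' @param restandardize recompute scaling coefficients on the validation
#'   cohort, see [compute_risk_scores()].
#' @return a `resampling_result`.
#' @export
prognostic_null_test <- function(signature, training, validation, pool,
                                 n_resamples = 1000, seed,
                                 engine = "fast", restandardize = FALSE) {
  if (missing(seed)) abort("`seed` is required", class = "progsig_config_error")
  if (n_resamples < 1) abort("n_resamples must be >= 1",
                             class = "progsig_validation_error")
  stat_fun <- if (engine == "fast") {
    pipeline_z_factory(training, validation, restandardize = restandardize)
  } else {
    function(s) signature_validation_z(s, training, validation, engine = engine,
                                       restandardize = restandardize)
  }
  observed <- stat_fun(signature)
  if (is.null(observed)) abort("observed signature pipeline is degenerate",
                               class = "progsig_numeric_error")
  sigs <- random_signatures(pool, length(intersect(signature,
                                                   rownames(training$expression))),
                            n_resamples, seed = seed)
  res <- resample_loop(sigs, stat_fun)
  new_resampling_result(observed, res$null, "validation Wald z",
                        n_resamples, res$n_skipped, seed)
}

#' Pooled sum-of-Wald resampling test against a comparison gene pool
#'
#' Sums the validation Wald z over several (training, validation) cohort
#' pairs and compares it with the same sum for random same-size signatures
#' drawn from a comparison pool (e.g. cancer-related genes outside the
#' curated signature universe).
#'
#' @param signature observed signature gene ids.
#' @param cohort_pairs list of `list(training =, validation =)` pairs.
#' @param pool comparison gene pool (disjoint from `signature`).
#' @inheritParams prognostic_null_test
#' @return a `resampling_result`.
#' @export
pooled_sum_z_test <- function(signature, cohort_pairs, pool,
                              n_resamples = 1000, seed,
                              engine = "fast", restandardize = FALSE) {
  if (missing(seed)) abort("`seed` is required", class = "progsig_config_error")
  if (!length(cohort_pairs)) abort("need at least one cohort pair",
                                   class = "progsig_validation_error")
  if (length(intersect(signature, pool))) {
    warn("signature and comparison pool overlap; the pool should exclude the signature universe")
  }
  pair_funs <- if (engine == "fast") {
    purrr::map(cohort_pairs, function(pr) {
      pipeline_z_factory(pr$training, pr$validation, restandardize = restandardize)
    })
  } else {
    purrr::map(cohort_pairs, function(pr) {
      function(s) signature_validation_z(s, pr$training, pr$validation,
                                         engine = engine,
                                         restandardize = restandardize)
    })
  }
  sum_z <- function(s) {
    zs <- purrr::map(pair_funs, function(f) f(s))
    if (any(purrr::map_lgl(zs, is.null))) return(NULL)
    sum(unlist(zs))
  }
  observed <- sum_z(signature)
  if (is.null(observed)) abort("observed signature pipeline is degenerate",
                               class = "progsig_numeric_error")
  sigs <- random_signatures(pool, length(signature), n_resamples, seed = seed)
  res <- resample_loop(sigs, sum_z)
  new_resampling_result(observed, res$null, "sum of validation Wald z",
                        n_resamples, res$n_skipped, seed)
}

#' Resampling test of co-expression coherence
#'
#' The observed statistic is the coherence (sum of the tree-ensemble weighted
#' adjacency matrix) of the signature genes; the null is the same statistic
#' for random same-size gene sets drawn from `pool`.
#'
#' @param signature observed signature gene ids (present in `expression`).
#' @param expression genes x samples matrix covering signature and pool.
#' @param pool gene pool for null signatures.
#' @param n_resamples number of random signatures (>= 1).
#' @param seed integer seed (required).
#' @param ensemble_size trees per target for the network inference.
#' @return a `resampling_result`.
#' @export
coherence_null_test <- function(signature, expression, pool,
                                n_resamples = 1000, seed,
                                ensemble_size = 100) {
  if (missing(seed)) abort("`seed` is required", class = "progsig_config_error")
  if (n_resamples < 1) abort("n_resamples must be >= 1",
                             class = "progsig_validation_error")
  missing_g <- setdiff(signature, rownames(expression))
  if (length(missing_g)) abort("signature genes missing from expression",
                               class = "progsig_validation_error")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_resamples + 1)
  observed <- coherence_statistic(
    infer_adjacency(expression[signature, , drop = FALSE],
                    ensemble_size = ensemble_size, seed = seeds[1]))
  sigs <- random_signatures(pool, length(signature), n_resamples, seed = seed)
  stats <- purrr::map2(sigs, seeds[-1], function(s, sd_) {
    tryCatch(
      coherence_statistic(
        suppressWarnings(infer_adjacency(expression[s, , drop = FALSE],
                                         ensemble_size = ensemble_size,
                                         seed = sd_))),
      error = function(e) NULL)
  })
  null_values <- purrr::compact(stats)
  n_skipped <- n_resamples - length(null_values)
  if (n_skipped / n_resamples > 0.05) {
    abort("coherence resampling failed on more than 5% of resamples",
          class = "progsig_numeric_error")
  }
  new_resampling_result(observed, unlist(null_values),
                        "adjacency-sum coherence", n_resamples, n_skipped, seed)
}
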