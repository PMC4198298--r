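#' Kaplan-Meier product-limit curve
#'
#' Wraps `survival::survfit` and returns the curve as a tibble. Censored-only
#' times reduce the at-risk count without a step; the survival function is
#' non-increasing and starts at 1.
#'
#' @param time,event survival times (> 0) and 0/1 event indicators.
#' @param group optional grouping factor; one curve per level.
#' @return tibble `time`, `n_risk`, `n_event`, `n_censor`, `survival` (and
#'   `group` when grouped), class `km_curve`.
#' @export
km_curve <- function(time, event, group = NULL) {
  if (!length(time)) abort("empty input", class = "progsig_validation_error")
  if (any(time <= 0)) abort("times must be > 0", class = "progsig_validation_error")
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    out <- tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                  n_censor = fit$n.censor, survival = fit$surv)
  } else {
    group <- as.factor(group)
    fit <- survival::survfit(survival::Surv(time, event) ~ group)
    strata <- rep(names(fit$strata), fit$strata)
    out <- tibble(group = sub("^group=", "", strata),
                  time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                  n_censor = fit$n.censor, survival = fit$surv)
  }
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square on one degree of freedom, two-sided p-value,
#' via `survival::survdiff`.
#'
#' @param time,event survival data.
#' @param group two-level factor (or coercible).
#' @return one-row tibble `chi_square`, `df`, `p.value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) != 2) {
    abort("log-rank test needs exactly 2 non-empty groups",
          class = "progsig_validation_error")
  }
  if (sum(event) < 1) abort("need at least one event", class = "progsig_data_error")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  tibble(chi_square = sd_$chisq, df = 1L,
         p.value = pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}

#' Multivariate Cox proportional-hazards regression
#'
#' Joint partial-likelihood fit (Efron ties) of survival on a set of
#' covariate columns from the clinical table. Categorical covariates must
#' have their reference level declared explicitly via `reference_levels` —
#' there is no silent alphabetical default. Collinear covariates raise a
#' degenerate-design error naming the offending terms.
#'
#' @param clinical tibble with `time`, `event` and the covariate columns.
#' @param covariates character vector of covariate column names.
#' @param reference_levels named list, one entry per categorical covariate,
#'   giving its reference level.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return tibble `term`, `estimate`, `se`, `hr`, `conf.low`, `conf.high`,
#'   `z`, `p.value`.
#' @export
cox_multivariate <- function(clinical, covariates,
                             reference_levels = list(), ties = "efron") {
  clinical <- as_tibble(clinical)
  if (!all(c("time", "event") %in% names(clinical))) {
    abort("clinical needs time and event columns", class = "progsig_validation_error")
  }
  missing_cov <- setdiff(covariates, names(clinical))
  if (length(missing_cov)) {
    abort(paste("covariates absent from clinical table:",
                paste(missing_cov, collapse = ", ")),
          class = "progsig_validation_error")
  }
  if (sum(clinical$event) < 2) abort("need at least 2 events",
                                     class = "progsig_data_error")
  dat <- clinical[c("time", "event", covariates)]
  for (cv in covariates) {
    v <- dat[[cv]]
    if (is.character(v) || is.factor(v) || is.logical(v)) {
      v <- as.factor(as.character(v))
      ref <- reference_levels[[cv]]
      if (is.null(ref)) {
        abort(sprintf("declare a reference level for categorical covariate '%s'", cv),
              class = "progsig_config_error")
      }
      if (!ref %in% levels(v)) {
        abort(sprintf("reference level '%s' not observed for '%s'", ref, cv),
              class = "progsig_config_error")
      }
      dat[[cv]] <- stats::relevel(v, ref = ref)
    }
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties)
  co <- fit$coefficients
  if (any(is.na(co))) {
    abort(paste("degenerate (collinear) design; offending terms:",
                paste(names(co)[is.na(co)], collapse = ", ")),
          class = "progsig_degenerate_error")
  }
  se <- sqrt(diag(fit$var))
  tibble(term = names(co), estimate = unname(co), se = se,
         hr = exp(unname(co)),
         conf.low = exp(unname(co) - 1.96 * se),
         conf.high = exp(unname(co) + 1.96 * se),
         z = unname(co) / se,
         p.value = 2 * pnorm(abs(unname(co) / se), lower.tail = FALSE))
}

#' Stratified evaluation of signature status
#'
#' Splits the cohort by a categorical stratum variable (e.g. lymph-node
#' status or stage) and, within each level, fits a univariate Cox model of
#' survival on the cohort-level signature group and runs the log-rank test.
#' The dichotomization is NOT redone within strata: the cohort-level
#' positive/negative labels are reused (set `redichotomize = TRUE` to re-split
#' at each stratum's own median score). Strata with fewer than 2 events are
#' skipped with a warning.
#'
#' @param clinical tibble with `sample_id`, `time`, `event` and the stratum
#'   column.
#' @param risk risk assignment from [compute_risk_scores()].
#' @param stratum name of the stratum column in `clinical`.
#' @param redichotomize re-dichotomize scores within each stratum.
#' @return tibble with one row per analysed stratum: `stratum`, `n`,
#'   `n_event`, `hr`, `conf.low`, `conf.high`, `p.value`, `logrank_p`, and a
#'   `km` list-column of [km_curve()] tibbles.
#' @export
stratified_vag_analysis <- function(clinical, risk, stratum,
                                    redichotomize = FALSE) {
  clinical <- as_tibble(clinical)
  if (!stratum %in% names(clinical)) {
    abort(sprintf("stratum column '%s' missing", stratum),
          class = "progsig_validation_error")
  }
  dat <- dplyr::inner_join(clinical, risk, by = "sample_id")
  levels_ <- unique(as.character(dat[[stratum]]))
  rows <- purrr::map(levels_, function(lv) {
    d <- dat[as.character(dat[[stratum]]) == lv, ]
    if (sum(d$event) < 2) {
      warn(sprintf("stratum '%s' skipped: fewer than 2 events", lv))
      return(NULL)
    }
    grp <- if (redichotomize) dichotomize(d$score) else d$group
    if (nlevels(droplevels(grp)) < 2) {
      warn(sprintf("stratum '%s' skipped: one signature group empty", lv))
      return(NULL)
    }
    fit <- fit_univariate_cox(as.integer(grp == "positive"), d$time, d$event)
    lr <- logrank_test(d$time, d$event, grp)
    tibble(stratum = lv, n = nrow(d), n_event = sum(d$event),
           hr = fit$hr, conf.low = fit$conf.low, conf.high = fit$conf.high,
           p.value = fit$p.value, logrank_p = lr$p.value,
           km = list(km_curve(d$time, d$event, grp)))
  })
  dplyr::bind_rows(purrr::compact(rows))
}
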