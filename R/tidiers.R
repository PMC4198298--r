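#' Tidy and glance methods
#'
#' `tidy()` returns the per-element table of a fitted object (per-gene
#' weights for a scoring model, null quantiles for a resampling result);
#' `glance()` returns a one-row summary.
#'
#' @param x a `scoring_model` or `resampling_result`.
#' @param ... unused.
#' @name progsig-tidiers
NULL

#' @rdname progsig-tidiers
#' @export
tidy.scoring_model <- function(x, ...) {
  tibble(gene = x$gene, z = x$z, mu = x$mu, tau = x$tau)
}

#' @rdname progsig-tidiers
#' @export
glance.scoring_model <- function(x, ...) {
  tibble(n_genes = nrow(x),
         training_cohort = attr(x, "training_cohort"),
         mean_abs_z = mean(abs(x$z)),
         n_positive_z = sum(x$z > 0))
}

#' @rdname progsig-tidiers
#' @export
tidy.resampling_result <- function(x, ...) {
  tibble(statistic = x$statistic,
         observed = x$observed,
         null_mean = mean(x$null_values),
         null_q025 = quantile(x$null_values, 0.025, names = FALSE),
         null_q500 = quantile(x$null_values, 0.5, names = FALSE),
         null_q975 = quantile(x$null_values, 0.975, names = FALSE),
         p.value = x$p)
}

#' @rdname progsig-tidiers
#' @export
glance.resampling_result <- function(x, ...) {
  tibble(statistic = x$statistic, observed = x$observed, p.value = x$p,
         n_resamples = x$n_resamples, n_skipped = x$n_skipped, seed = x$seed)
}
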