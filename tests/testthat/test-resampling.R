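test_that("random signatures are reproducible uniform subsets of the pool", {
  pool <- sprintf("p%03d", 1:60)
  sigs <- random_signatures(pool, size = 10, n = 50, seed = 1)
  expect_length(sigs, 50)
  expect_true(all(vapply(sigs, function(s)
    length(s) == 10 && !anyDuplicated(s) && all(s %in% pool), logical(1))))
  sigs2 <- random_signatures(pool, size = 10, n = 50, seed = 1)
  expect_identical(sigs, sigs2)
  # size = |pool| forces every draw to equal the pool
  forced <- random_signatures(pool, size = 60, n = 5, seed = 2)
  expect_true(all(vapply(forced, function(s) setequal(s, pool), logical(1))))
  expect_error(random_signatures(pool, size = 61, n = 1, seed = 3),
               class = "progsig_validation_error")
})

test_that("the add-one empirical p follows its definition and never hits zero", {
  null <- c(1, 2, 3, 4, 5)
  expect_equal(empirical_p(10, null), 1 / 6)
  expect_equal(empirical_p(0, null), 1)
  expect_equal(empirical_p(3, null), (1 + 3) / 6)
  # monotone non-increasing in the observed statistic
  obs <- seq(-1, 7, by = 0.5)
  ps <- sapply(obs, empirical_p, null = null)
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps > 0))
  # observed above all 1000 nulls -> 1/1001
  expect_equal(empirical_p(99, rnorm(1000)), 1 / 1001, tolerance = 1e-12)
})

sim_pair <- function(seed, n = 150, n_genes = 120, beta_genes = character(),
                     beta = 0.5, loading = 0) {
  b <- if (length(beta_genes)) setNames(rep(beta, length(beta_genes)), beta_genes)
  tr <- simulate_survival_cohort(n_samples = n, n_genes = n_genes,
                                 signature_genes = beta_genes %||% sprintf("g%04d", 1:5),
                                 beta = b, latent_loading = loading,
                                 name = "training", seed = seed)$cohort
  va <- simulate_survival_cohort(n_samples = n, n_genes = n_genes,
                                 signature_genes = beta_genes %||% sprintf("g%04d", 1:5),
                                 beta = b, latent_loading = loading,
                                 name = "validation", seed = seed + 1)$cohort
  list(training = tr, validation = va)
}
`%||%` <- function(a, b) if (length(a)) a else b

test_that("the prognostic null test runs the full pipeline and is deterministic", {
  prog_genes <- sprintf("g%04d", 1:6)
  pr <- sim_pair(seed = 500, beta_genes = prog_genes)
  pool <- rownames(pr$training$expression)
  res <- prognostic_null_test(prog_genes, pr$training, pr$validation, pool,
                              n_resamples = 60, seed = 9)
  res2 <- prognostic_null_test(prog_genes, pr$training, pr$validation, pool,
                               n_resamples = 60, seed = 9)
  expect_identical(res$null_values, res2$null_values)
  expect_identical(res$p, res2$p)
  expect_equal(res$p, empirical_p(res$observed, res$null_values))
  expect_s3_class(glance(res), "tbl_df")
  expect_error(prognostic_null_test(prog_genes, pr$training, pr$validation,
                                    pool, n_resamples = 0, seed = 1),
               class = "progsig_validation_error")
})

test_that("the lean resampling engine matches the general pipeline path", {
  prog_genes <- sprintf("g%04d", 1:6)
  pr <- sim_pair(seed = 1300, beta_genes = prog_genes)
  fast_fun <- progsig:::pipeline_z_factory(pr$training, pr$validation)
  set.seed(16)
  for (s in c(list(prog_genes),
              replicate(4, sample(rownames(pr$training$expression), 9),
                        simplify = FALSE))) {
    z_fast <- fast_fun(s)
    z_general <- progsig:::signature_validation_z(s, pr$training, pr$validation,
                                                  engine = "survival")
    expect_equal(z_fast, z_general, tolerance = 1e-6)
  }
  # restandardized variant agrees too
  z_fast_r <- progsig:::pipeline_z_factory(pr$training, pr$validation,
                                           restandardize = TRUE)(prog_genes)
  z_gen_r <- progsig:::signature_validation_z(pr$training$expression |>
                                                rownames() |> head(6),
                                              pr$training, pr$validation,
                                              engine = "survival",
                                              restandardize = TRUE)
  expect_equal(z_fast_r, z_gen_r, tolerance = 1e-6)
})

test_that("a planted prognostic signature beats the random-signature null", {
  prog_genes <- sprintf("g%04d", 1:6)
  pr <- sim_pair(seed = 600, beta_genes = prog_genes, beta = 0.6)
  pool <- rownames(pr$training$expression)
  res <- prognostic_null_test(prog_genes, pr$training, pr$validation, pool,
                              n_resamples = 100, seed = 10)
  expect_lte(res$p, 0.05)
})

test_that("with a single cohort pair the pooled test reduces to the prognostic test", {
  prog_genes <- sprintf("g%04d", 1:6)
  pr <- sim_pair(seed = 700, beta_genes = prog_genes)
  pool <- setdiff(rownames(pr$training$expression), prog_genes)
  a <- prognostic_null_test(prog_genes, pr$training, pr$validation, pool,
                            n_resamples = 40, seed = 11)
  b <- pooled_sum_z_test(prog_genes, list(list(training = pr$training,
                                               validation = pr$validation)),
                         pool, n_resamples = 40, seed = 11)
  expect_equal(a$observed, b$observed, tolerance = 1e-10)
  expect_identical(a$null_values, b$null_values)
  expect_identical(a$p, b$p)
})

test_that("the pooled sum-of-z null is centred near zero under the global null", {
  pairs <- lapply(c(800, 900, 1000), function(s) {
    pr <- sim_pair(seed = s, n = 100, n_genes = 80)
    list(training = pr$training, validation = pr$validation)
  })
  pool <- rownames(pairs[[1]]$training$expression)
  set.seed(15)
  sig <- sample(pool, 8)
  res <- pooled_sum_z_test(sig, pairs, setdiff(pool, sig),
                           n_resamples = 40, seed = 12)
  expect_lt(abs(mean(res$null_values)), 2)
})

test_that("coherence null test separates a coherent signature from noise", {
  sim <- simulate_survival_cohort(n_samples = 80, n_genes = 60,
                                  signature_genes = sprintf("g%04d", 1:12),
                                  latent_loading = 0.9, seed = 42)
  expr <- sim$cohort$expression
  sig <- sprintf("g%04d", 1:12)
  pool <- sprintf("g%04d", 13:60)
  res <- coherence_null_test(sig, expr, pool, n_resamples = 40, seed = 13,
                             ensemble_size = 60)
  expect_lte(res$p, 0.05)
  expect_error(coherence_null_test(sig, expr, pool, n_resamples = 0, seed = 1),
               class = "progsig_validation_error")
  expect_error(coherence_null_test(c(sig, "absent"), expr, pool,
                                   n_resamples = 5, seed = 1),
               class = "progsig_validation_error")
})

test_that("resampling results render as tidy tables and plots", {
  prog_genes <- sprintf("g%04d", 1:6)
  pr <- sim_pair(seed = 1100, beta_genes = prog_genes)
  res <- prognostic_null_test(prog_genes, pr$training, pr$validation,
                              rownames(pr$training$expression),
                              n_resamples = 30, seed = 14)
  td <- tidy(res)
  expect_true(all(c("observed", "null_mean", "p.value") %in% names(td)))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
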