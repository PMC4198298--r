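sim_training <- function(seed = 50, n = 200, n_genes = 60) {
  genes <- sprintf("g%04d", 1:10)
  simulate_survival_cohort(n_samples = n, n_genes = n_genes,
                           signature_genes = genes,
                           beta = setNames(rep(0.4, 5), genes[1:5]),
                           latent_loading = 0.3, seed = seed)$cohort
}

test_that("both Cox engines agree with each other and with the NR oracle", {
  co <- sim_training()
  cl <- co$clinical
  x <- co$expression["g0001", cl$sample_id]
  a <- fit_univariate_cox(x, cl$time, cl$event, engine = "survival")
  b <- fit_univariate_cox(x, cl$time, cl$event, engine = "fast")
  orc <- cox_nr_oracle(x, cl$time, cl$event)
  expect_equal(a$estimate, b$estimate, tolerance = 1e-7)
  expect_equal(a$se, b$se, tolerance = 1e-7)
  expect_equal(a$estimate, orc$beta, tolerance = 1e-6)
  expect_equal(a$se, orc$se, tolerance = 1e-6)
})

test_that("Wald z is invariant to covariate rescaling while beta halves", {
  co <- sim_training(seed = 51)
  cl <- co$clinical
  x <- co$expression["g0002", cl$sample_id]
  f1 <- fit_univariate_cox(x, cl$time, cl$event)
  f2 <- fit_univariate_cox(2 * x, cl$time, cl$event)
  expect_equal(f2$estimate, f1$estimate / 2, tolerance = 1e-6)
  expect_equal(f2$z, f1$z, tolerance = 1e-6)
})

test_that("degenerate covariates and missing events raise classed errors", {
  co <- sim_training(seed = 52)
  cl <- co$clinical
  expect_error(fit_univariate_cox(rep(1, nrow(cl)), cl$time, cl$event),
               class = "progsig_degenerate_error")
  expect_error(fit_univariate_cox(rnorm(5), c(1, 2, 3, 4, 5), rep(0, 5)),
               class = "progsig_data_error")
})

test_that("the scoring model freezes Wald z and training mean/SD per gene", {
  co <- sim_training(seed = 53)
  cl <- co$clinical
  sig <- sprintf("g%04d", 1:10)
  model <- build_scoring_model(co, sig)
  expect_s3_class(model, "scoring_model")
  expect_equal(nrow(model), 10)
  g <- "g0003"
  fit <- fit_univariate_cox(co$expression[g, cl$sample_id], cl$time, cl$event)
  expect_equal(model$z[model$gene == g], fit$z, tolerance = 1e-7)
  expect_equal(model$mu[model$gene == g],
               mean(co$expression[g, cl$sample_id]), tolerance = 1e-12)
  expect_equal(model$tau[model$gene == g],
               sd(co$expression[g, cl$sample_id]), tolerance = 1e-12)
})

test_that("single-gene models work; constant genes are dropped with a warning", {
  co <- sim_training(seed = 54)
  m1 <- build_scoring_model(co, "g0001")
  expect_equal(nrow(m1), 1)
  co$expression["g0002", ] <- 5
  expect_warning(m2 <- build_scoring_model(co, c("g0001", "g0002")),
                 "dropped 1")
  expect_equal(m2$gene, "g0001")
  expect_error(build_scoring_model(co, c("g0001", "nope1", "nope2")),
               class = "progsig_data_error")
})

test_that("risk scores follow the weighted standardized sum exactly", {
  # one gene: Z = 2, mu = 5, tau = 1, e = 6 -> S = 2
  expr <- matrix(c(6, 4), 1, 2, dimnames = list("gA", c("s1", "s2")))
  model <- progsig:::new_scoring_model(
    tibble::tibble(gene = "gA", z = 2, mu = 5, tau = 1))
  cohort <- make_cohort(expr, time = c(3, 4), event = c(1, 0))
  risk <- compute_risk_scores(model, cohort)
  expect_equal(risk$score, c(2, -2))
  # three genes: Z = (1, -2, 0.5), tau = (1, 2, 4), e = 1 -> S = 0.125
  expr3 <- matrix(1, 3, 2, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expr3[, 2] <- c(0, 0, 0)
  m3 <- progsig:::new_scoring_model(
    tibble::tibble(gene = c("a", "b", "c"), z = c(1, -2, 0.5),
                   mu = c(0, 0, 0), tau = c(1, 2, 4)))
  risk3 <- compute_risk_scores(m3, make_cohort(expr3, c(1, 2), c(1, 1)))
  expect_equal(risk3$score[1], 1 - 1 + 0.125)
  expect_equal(risk3$score[2], 0)
  # all-zero weights give all-zero scores
  m0 <- progsig:::new_scoring_model(
    tibble::tibble(gene = c("a", "b", "c"), z = 0, mu = 0, tau = 1))
  expect_warning(r0 <- compute_risk_scores(m0, make_cohort(expr3, c(1, 2), c(1, 1))))
  expect_equal(r0$score, c(0, 0))
})

test_that("risk scores equal the brute-force sum and ignore gene order", {
  set.seed(77)
  for (i in 1:5) {
    genes <- sprintf("G%02d", 1:12)
    expr <- matrix(rnorm(12 * 9, 8), 12, 9,
                   dimnames = list(genes, sprintf("s%d", 1:9)))
    model <- progsig:::new_scoring_model(
      tibble::tibble(gene = genes, z = rnorm(12), mu = rnorm(12, 8),
                     tau = runif(12, 0.5, 2)))
    cohort <- make_cohort(expr, time = rexp(9) + 0.1, event = rbinom(9, 1, 0.7))
    risk <- compute_risk_scores(model, cohort)
    expect_equal(risk$score, unname(risk_score_brute(model, expr)),
                 tolerance = 1e-10)
    shuffled <- model[sample(nrow(model)), ]
    risk2 <- compute_risk_scores(shuffled, cohort)
    expect_equal(risk2$score, risk$score, tolerance = 1e-12)
  }
})

test_that("genes missing from the cohort are dropped from the sum", {
  genes <- c("a", "b", "c")
  model <- progsig:::new_scoring_model(
    tibble::tibble(gene = genes, z = c(1, 1, 1), mu = 0, tau = 1))
  expr <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(c("a", "b"),
                                                      c("s1", "s2")))
  cohort <- make_cohort(expr, c(1, 2), c(1, 1))
  expect_message(risk <- compute_risk_scores(model, cohort), "1 of 3")
  expect_equal(attr(risk, "n_genes_used"), 2)
  expect_equal(risk$score, c(1 + 2, 3 + 4))
  model_absent <- progsig:::new_scoring_model(
    tibble::tibble(gene = "zz", z = 1, mu = 0, tau = 1))
  expect_error(compute_risk_scores(model_absent, cohort),
               class = "progsig_data_error")
})

test_that("restandardization recomputes scaling on the scored cohort", {
  co <- sim_training(seed = 55)
  model <- build_scoring_model(co, sprintf("g%04d", 1:10))
  co2 <- sim_training(seed = 56)
  co2$expression <- co2$expression + 3  # platform shift
  frozen <- compute_risk_scores(model, co2)
  rescaled <- compute_risk_scores(model, co2, restandardize = TRUE)
  # group assignment is median-based, so a pure shift changes scores but the
  # restandardized scores must be centred near zero
  expect_gt(abs(mean(frozen$score)), abs(mean(rescaled$score)))
  expect_lt(abs(mean(rescaled$score)), 1)
})

test_that("median dichotomization uses a strict threshold with ties negative", {
  g <- dichotomize(c(1, 2, 3, 4))
  expect_equal(as.character(g), c("negative", "negative", "positive", "positive"))
  g2 <- dichotomize(c(1, 2, 3))
  expect_equal(as.character(g2), c("negative", "negative", "positive"))
  expect_warning(g3 <- dichotomize(c(2, 2, 2)), "identical")
  expect_true(all(g3 == "negative"))
  expect_error(dichotomize(1), class = "progsig_validation_error")
  # group sizes differ by at most the number of samples tied at the median
  set.seed(9)
  s <- rnorm(101)
  tab <- table(dichotomize(s))
  expect_lte(abs(tab[["positive"]] - tab[["negative"]]), sum(s == median(s)))
})
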