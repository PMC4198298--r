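test_that("paired t-test reproduces the hand-computed case", {
  # differences (1, 2, 3): mean 2, sd 1, t = 2 / (1/sqrt(3)) = 3.4641
  res <- paired_t_test(tumor = c(2, 4, 6), normal = c(1, 2, 3))
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-6)
  expect_equal(res$df, 2)
  expect_equal(res$p_raw, 0.0742, tolerance = 1e-3)
  expect_equal(res$direction, "up")
  # agrees with stats::t.test
  tt <- t.test(c(2, 4, 6), c(1, 2, 3), paired = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p_raw, tt$p.value, tolerance = 1e-12)
})

test_that("degenerate paired inputs raise classed errors", {
  expect_error(paired_t_test(tumor = c(1.5, 2.5), normal = c(1, 2)),
               class = "progsig_degenerate_error")
  expect_error(paired_t_test(tumor = 1, normal = 0.5),
               class = "progsig_data_error")
})

test_that("vectorised cohort-wide DE equals per-gene t.test", {
  sim <- simulate_paired_cohorts(n_cancers = 1, n_genes = 30, n_pairs = 12,
                                 n_de_genes = 5, accordant_in = 1, seed = 17)
  co <- sim$cohorts[[1]]
  de <- paired_de(co)
  for (g in rownames(co$expression)[c(1, 7, 30)]) {
    tt <- t.test(co$expression[g, co$pairs$tumor_sample_id],
                 co$expression[g, co$pairs$normal_sample_id], paired = TRUE)
    row <- de[de$gene == g, ]
    expect_equal(row$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(row$p_raw, tt$p.value, tolerance = 1e-10)
  }
  expect_true(all(de$p_adj >= de$p_raw))
  expect_true(all(de$direction[de$t > 0] == "up"))
})

test_that("cohort accessors give the same answers as raw vectors", {
  sim <- simulate_paired_cohorts(n_cancers = 1, n_genes = 10, n_pairs = 8,
                                 n_de_genes = 2, accordant_in = 1, seed = 19)
  co <- sim$cohorts[[1]]
  g <- rownames(co$expression)[4]
  tum <- co$expression[g, co$pairs$tumor_sample_id]
  nor <- co$expression[g, co$pairs$normal_sample_id]
  expect_equal(paired_t_test(cohort = co, gene = g)$t,
               paired_t_test(tumor = tum, normal = nor)$t, tolerance = 1e-12)
  expect_equal(fold_change(cohort = co, gene = g),
               fold_change(tumor = tum, normal = nor), tolerance = 1e-12)
})

test_that("paired t-test p-values are uniform under the null", {
  set.seed(123)
  pvals <- replicate(1000, {
    d <- rnorm(10)
    paired_t_test(tumor = d, normal = rep(0, 10))$p_raw
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("BH adjustment handles the textbook cases", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), class = "progsig_validation_error")
})

test_that("fold change is the geometric-mean ratio of paired log2 values", {
  expect_equal(fold_change(tumor = c(3, 4), normal = c(2, 3)), 2.0)
  expect_equal(fold_change(tumor = c(3, 4), normal = c(3, 4)), 1.0)
  expect_equal(fold_change(tumor = c(1, 2) + 0.3219, normal = c(1, 2)),
               1.25, tolerance = 1e-4)
})

make_de_table <- function(spec_rows) {
  # spec_rows: list of c(gene, cancer, p_adj, direction)
  do.call(rbind, lapply(spec_rows, function(r) {
    data.frame(gene = r[[1]], cancer = r[[2]],
               p_adj = as.numeric(r[[3]]), direction = r[[4]],
               t = ifelse(r[[4]] == "up", 2, -2), p_raw = as.numeric(r[[3]]) / 2,
               fold_change = 1.5)
  }))
}

test_that("accordant-direction selection applies the at-least-k rule", {
  cancers <- paste0("c", 1:6)
  rows <- c(
    lapply(cancers[1:4], function(cn) list("gA", cn, 0.01, "up")),      # 4 up
    lapply(cancers[5:6], function(cn) list("gA", cn, 0.5, "down")),
    lapply(cancers[1:2], function(cn) list("gB", cn, 0.01, "up")),      # 2 up 2 down
    lapply(cancers[3:4], function(cn) list("gB", cn, 0.01, "down")),
    lapply(cancers[1:3], function(cn) list("gC", cn, 0.01, "up"))       # only 3
  )
  de <- make_de_table(rows)
  sel <- select_common_de(de, alpha = 0.05, min_cancers = 4)
  expect_equal(sel$gene, "gA")
  expect_equal(sel$direction, "up")
  expect_equal(sel$n_support, 4L)
})

test_that("significant discordance disqualifies only in strict mode", {
  cancers <- paste0("c", 1:6)
  rows <- c(
    lapply(cancers[1:4], function(cn) list("gA", cn, 0.01, "up")),
    lapply(cancers[5:6], function(cn) list("gA", cn, 0.01, "down"))
  )
  de <- make_de_table(rows)
  expect_equal(select_common_de(de, min_cancers = 4)$gene, "gA")
  expect_equal(nrow(select_common_de(de, min_cancers = 4, strict = TRUE)), 0)
})

test_that("selection is monotone in alpha and min_cancers", {
  sim <- simulate_paired_cohorts(n_cancers = 6, n_genes = 150, n_pairs = 15,
                                 n_de_genes = 20, effect_size = 0.8,
                                 accordant_in = 5, seed = 33)
  de <- purrr::map_dfr(sim$cohorts, paired_de)
  base <- select_common_de(de, alpha = 0.03, min_cancers = 5)$gene
  looser_alpha <- select_common_de(de, alpha = 0.10, min_cancers = 5)$gene
  looser_k <- select_common_de(de, alpha = 0.03, min_cancers = 3)$gene
  expect_true(all(base %in% looser_alpha))
  expect_true(all(base %in% looser_k))
})

test_that("restrict_to limits the selection universe; complement_pool is the set difference", {
  cancers <- paste0("c", 1:6)
  rows <- c(lapply(cancers[1:5], function(cn) list("gA", cn, 0.01, "up")),
            lapply(cancers[1:5], function(cn) list("gB", cn, 0.01, "down")))
  de <- make_de_table(rows)
  sel <- select_common_de(de, restrict_to = "gB")
  expect_equal(sel$gene, "gB")
  expect_equal(complement_pool(c("a", "b", "c"), "b"), c("a", "c"))
  expect_equal(complement_pool(c("a", "c"), c("x", "y")), c("a", "c"))
})

test_that("term enrichment equals the hypergeometric tail and is one-sided", {
  universe <- sprintf("u%03d", 1:100)
  term <- universe[1:50]
  gene_set <- universe[1:10]  # entirely inside the term
  res <- term_enrichment(gene_set, list(half = term, all = universe), universe)
  expect_equal(res$p_raw[res$term == "all"], 1)
  p_hyper <- stats::phyper(9, 50, 50, 10, lower.tail = FALSE)
  expect_equal(res$p_raw[res$term == "half"], p_hyper, tolerance = 1e-10)
  # empty intersection cannot be enriched one-sided
  res2 <- term_enrichment(universe[51:60], list(t = universe[1:10]), universe)
  expect_gte(res2$p_raw, 0.5)
  expect_error(term_enrichment("a", list(t = "a"), character()),
               class = "progsig_validation_error")
})
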