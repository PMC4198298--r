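#' Paired t-test on within-patient tumor minus normal differences
#'
#' The test statistic is `mean(d) / (sd(d)/sqrt(n))` on the per-patient
#' differences `d = tumor - normal`, with `n - 1` degrees of freedom and a
#' two-sided p-value. Direction is `up` when t > 0, `down` when t < 0, and
#' `NA` at an exact tie.
#'
#' @param tumor,normal numeric vectors of paired log2 values (same length,
#'   same patient order), or supply `cohort` + `gene` instead.
#' @param cohort a [paired_cohort()].
#' @param gene gene id to test within `cohort`.
#' @return one-row tibble: `t`, `df`, `p_raw`, `direction`, `mean_diff`.
#' @export
paired_t_test <- function(tumor = NULL, normal = NULL, cohort = NULL,
                          gene = NULL) {
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "paired_cohort"), !is.null(gene))
    tumor <- cohort$expression[gene, cohort$pairs$tumor_sample_id]
    normal <- cohort$expression[gene, cohort$pairs$normal_sample_id]
  }
  if (length(tumor) != length(normal)) {
    abort("tumor and normal must be paired vectors of equal length",
          class = "progsig_validation_error")
  }
  d <- tumor - normal
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 2) abort("need at least 2 complete pairs", class = "progsig_data_error")
  s <- sd(d)
  if (s == 0) abort("zero variance of paired differences",
                    class = "progsig_degenerate_error")
  t_stat <- mean(d) / (s / sqrt(n))
  tibble(t = t_stat, df = n - 1,
         p_raw = 2 * pt(abs(t_stat), n - 1, lower.tail = FALSE),
         direction = dplyr::case_when(t_stat > 0 ~ "up",
                                      t_stat < 0 ~ "down",
                                      TRUE ~ NA_character_),
         mean_diff = mean(d))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must be finite and in [0, 1]", class = "progsig_validation_error")
  }
  p.adjust(p, method = "BH")
}

#' Paired fold change
#'
#' Defined on the log2 scale as `2^(mean(tumor) - mean(normal))`, i.e. the
#' geometric-mean tumor/normal ratio — consistent with testing on log2
#' values. Set `linear = TRUE` for the ratio of linear-scale means.
#'
#' @inheritParams paired_t_test
#' @param linear use mean(2^tumor)/mean(2^normal) instead.
#' @return positive scalar fold change.
#' @export
fold_change <- function(tumor = NULL, normal = NULL, cohort = NULL,
                        gene = NULL, linear = FALSE) {
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "paired_cohort"), !is.null(gene))
    tumor <- cohort$expression[gene, cohort$pairs$tumor_sample_id]
    normal <- cohort$expression[gene, cohort$pairs$normal_sample_id]
  }
  if (!length(tumor)) abort("need at least one pair", class = "progsig_data_error")
  if (linear) {
    mean(2^tumor) / mean(2^normal)
  } else {
    2^(mean(tumor) - mean(normal))
  }
}

#' Genome-wide paired differential expression for one cohort
#'
#' Runs the paired t-test for every gene (vectorised across the matrix),
#' adjusts p-values by Benjamini-Hochberg within the cohort, and attaches the
#' paired fold change. Genes with zero difference variance get `NA`
#' statistics and are excluded from the adjustment.
#'
#' @param cohort a [paired_cohort()].
#' @param genes optional subset of gene ids (default: all genes).
#' @return tibble with one row per gene: `gene`, `cancer`, `t`, `df`,
#'   `p_raw`, `p_adj`, `direction`, `fold_change`, `mean_diff`.
#' @export
paired_de <- function(cohort, genes = NULL) {
  stopifnot(inherits(cohort, "paired_cohort"))
  genes <- genes %||% rownames(cohort$expression)
  diff <- cohort$expression[genes, cohort$pairs$tumor_sample_id, drop = FALSE] -
    cohort$expression[genes, cohort$pairs$normal_sample_id, drop = FALSE]
  n <- ncol(diff)
  if (n < 2) abort("need at least 2 pairs", class = "progsig_data_error")
  m <- rowMeans(diff)
  s <- sqrt(rowSums((diff - m)^2) / (n - 1))
  t_stat <- ifelse(s > 0, m / (s / sqrt(n)), NA_real_)
  p_raw <- 2 * pt(abs(t_stat), n - 1, lower.tail = FALSE)
  p_adj <- rep(NA_real_, length(p_raw))
  ok <- is.finite(p_raw)
  p_adj[ok] <- bh_adjust(p_raw[ok])
  tibble(
    gene = genes, cancer = cohort$cancer,
    t = unname(t_stat), df = n - 1, p_raw = unname(p_raw), p_adj = unname(p_adj),
    direction = dplyr::case_when(t_stat > 0 ~ "up",
                                 t_stat < 0 ~ "down",
                                 TRUE ~ NA_character_) |> unname(),
    fold_change = unname(2^m), mean_diff = unname(m)
  )
}

#' Cross-cancer accordant-direction signature selection
#'
#' A gene is selected when some direction `d` exists such that the gene is
#' significant (`p_adj < alpha`) with direction `d` in at least `min_cancers`
#' cancer types. By default, significant cancers in the opposite direction do
#' not disqualify a gene as long as the accordant count is reached; set
#' `strict = TRUE` to also require that no cancer is significant in the
#' opposite direction.
#'
#' @param de_results row-bound [paired_de()] tables across cancers.
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @param min_cancers minimum accordant significant cancers (default 4).
#' @param accordant require a shared direction (default TRUE; when FALSE any
#'   `min_cancers` significant cancers qualify).
#' @param strict disallow any significant discordant cancer.
#' @param restrict_to optional gene set to which selection is restricted
#'   (e.g. a curated interacting-gene list).
#' @return tibble `gene`, `direction`, `n_support`, sorted by support.
#' @export
select_common_de <- function(de_results, alpha = 0.05, min_cancers = 4,
                             accordant = TRUE, strict = FALSE,
                             restrict_to = NULL) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)",
                                      class = "progsig_config_error")
  de_results <- as_tibble(de_results)
  if (!is.null(restrict_to)) {
    de_results <- de_results[de_results$gene %in% restrict_to, ]
  }
  sig <- de_results[!is.na(de_results$p_adj) & de_results$p_adj < alpha &
                      !is.na(de_results$direction), ]
  if (!nrow(sig)) {
    return(tibble(gene = character(), direction = character(),
                  n_support = integer()))
  }
  counts <- dplyr::count(sig, .data$gene, .data$direction, name = "n_support")
  if (accordant) {
    best <- dplyr::slice_max(dplyr::group_by(counts, .data$gene),
                             .data$n_support, n = 1, with_ties = FALSE)
    best <- dplyr::ungroup(best)
    if (strict) {
      disc <- dplyr::summarise(dplyr::group_by(counts, .data$gene),
                               n_dir = dplyr::n(), .groups = "drop")
      best <- best[best$gene %in% disc$gene[disc$n_dir == 1], ]
    }
    out <- best[best$n_support >= min_cancers, ]
  } else {
    tot <- dplyr::summarise(dplyr::group_by(sig, .data$gene),
                            n_support = dplyr::n(), .groups = "drop")
    tot$direction <- NA_character_
    out <- tot[tot$n_support >= min_cancers, c("gene", "direction", "n_support")]
  }
  dplyr::arrange(out, dplyr::desc(.data$n_support), .data$gene)
}

#' Cancer-related pool: selected genes outside the signature universe
#'
#' Returns the genes passing the cross-cancer selection that do NOT belong to
#' the curated interacting-gene universe — the comparison pool for the pooled
#' sum-of-Wald resampling test.
#'
#' @param all_selected character vector of genes passing selection genome-wide.
#' @param signature_universe the curated interacting-gene set.
#' @export
complement_pool <- function(all_selected, signature_universe) {
  setdiff(all_selected, signature_universe)
}

#' One-sided Fisher's exact term enrichment
#'
#' For each term the 2x2 table (in gene set x in term) over the universe is
#' tested one-sided for over-representation; p-values are BH-adjusted across
#' terms.
#'
#' @param gene_set character vector (subset of `universe`).
#' @param term_gene_sets named list of character vectors (each a subset of
#'   `universe`).
#' @param universe character vector of all considered genes.
#' @return tibble `term`, `n_set`, `n_term`, `n_overlap`, `odds_ratio`,
#'   `p_raw`, `p_adj`.
#' @export
term_enrichment <- function(gene_set, term_gene_sets, universe) {
  if (!length(universe)) abort("empty universe", class = "progsig_validation_error")
  gene_set <- intersect(gene_set, universe)
  rows <- purrr::imap_dfr(term_gene_sets, function(term_genes, term) {
    term_genes <- intersect(term_genes, universe)
    a <- length(intersect(gene_set, term_genes))
    b <- length(gene_set) - a
    c_ <- length(term_genes) - a
    d <- length(universe) - a - b - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), 2), alternative = "greater")
    tibble(term = term, n_set = length(gene_set),
           n_term = length(term_genes), n_overlap = a,
           odds_ratio = unname(ft$estimate), p_raw = ft$p.value)
  })
  rows$p_adj <- bh_adjust(rows$p_raw)
  dplyr::arrange(rows, .data$p_raw)
}
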