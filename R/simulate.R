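#' Simulate paired normal/tumor cohorts with planted differential expression
#'
#' Generates one paired cohort per cancer type on the log2 scale. For patient
#' `p` and gene `g`, normal = baseline(g) + patient effect + noise and tumor
#' additionally carries the planted signed log2 effect when `g` is perturbed
#' in that cancer. The additive per-patient, per-gene random effect induces
#' the within-pair correlation that the paired design exploits.
#'
#' Planted effects can be given explicitly via `de_effects` (tibble with
#' columns `gene`, `cancer`, `effect`); otherwise `n_de_genes` genes are
#' chosen, each perturbed by `effect_size` (sign drawn once per gene, the
#' same in every perturbed cancer) in `accordant_in` randomly chosen cancers.
#'
#' @param n_cancers number of cancer types (paired cohorts).
#' @param n_genes genes per cohort (shared universe `g0001`, ...).
#' @param n_pairs patients (normal/tumor pairs) per cancer.
#' @param n_de_genes number of planted differentially expressed genes.
#' @param effect_size absolute log2 effect for planted genes.
#' @param accordant_in number of cancers in which each planted gene is
#'   perturbed.
#' @param prop_down proportion of planted genes perturbed downwards.
#' @param pair_effect_sd SD of the per-patient random effect (log2 units).
#' @param noise_sd residual SD (log2 units).
#' @param baseline_mean mean gene baseline (log2 units); per-gene baselines
#'   are drawn around it with SD 1 to mimic between-gene abundance spread.
#' @param de_effects optional explicit effect table (gene, cancer, effect);
#'   overrides `n_de_genes`/`effect_size`/`accordant_in`/`prop_down`.
#' @param seed integer seed; identical seed + config reproduces the output
#'   bit for bit.
#'
#' @return list with `cohorts` (list of [paired_cohort()], one per cancer)
#'   and `truth`, a tibble of the planted effects (gene, cancer, effect,
#'   direction).
#' @export
simulate_paired_cohorts <- function(n_cancers = 6, n_genes = 1000,
                                    n_pairs = 30, n_de_genes = 50,
                                    effect_size = 1.0, accordant_in = 5,
                                    prop_down = 0.5,
                                    pair_effect_sd = 0.5, noise_sd = 0.5,
                                    baseline_mean = 8, de_effects = NULL,
                                    seed) {
  if (missing(seed)) abort("`seed` is required", class = "progsig_config_error")
  if (n_cancers < 1 || n_genes < 1 || n_pairs < 1) {
    abort("sizes must be positive", class = "progsig_config_error")
  }
  if (pair_effect_sd <= 0 || noise_sd <= 0) {
    abort("pair_effect_sd and noise_sd must be > 0", class = "progsig_config_error")
  }
  if (is.null(de_effects) && n_de_genes > n_genes) {
    abort("n_de_genes cannot exceed n_genes", class = "progsig_config_error")
  }
  if (is.null(de_effects) && accordant_in > n_cancers) {
    abort("accordant_in cannot exceed n_cancers", class = "progsig_config_error")
  }
  set.seed(seed)

  genes <- sprintf("g%04d", seq_len(n_genes))
  cancers <- paste0("cancer", seq_len(n_cancers))

  if (is.null(de_effects)) {
    if (n_de_genes > 0) {
      de_genes <- sample(genes, n_de_genes)
      signs <- ifelse(seq_len(n_de_genes) <= round(prop_down * n_de_genes), -1, 1)
      de_effects <- purrr::map2_dfr(de_genes, signs, function(g, s) {
        tibble(gene = g,
               cancer = sample(cancers, min(accordant_in, n_cancers)),
               effect = s * effect_size)
      })
    } else {
      de_effects <- tibble(gene = character(), cancer = character(),
                           effect = numeric())
    }
  } else {
    de_effects <- as_tibble(de_effects)
    bad <- setdiff(de_effects$gene, genes)
    if (length(bad)) abort("de_effects refers to genes outside the universe",
                           class = "progsig_config_error")
  }

  baseline <- rnorm(n_genes, baseline_mean, 1)
  names(baseline) <- genes

  cohorts <- lapply(cancers, function(cn) {
    eff <- numeric(n_genes)
    names(eff) <- genes
    here <- de_effects[de_effects$cancer == cn, ]
    eff[here$gene] <- here$effect

    patient_eff <- matrix(rnorm(n_genes * n_pairs, 0, pair_effect_sd),
                          n_genes, n_pairs)
    normal <- baseline + patient_eff +
      matrix(rnorm(n_genes * n_pairs, 0, noise_sd), n_genes, n_pairs)
    tumor <- baseline + patient_eff + eff +
      matrix(rnorm(n_genes * n_pairs, 0, noise_sd), n_genes, n_pairs)

    pid <- sprintf("%s_p%03d", cn, seq_len(n_pairs))
    nid <- paste0(pid, "_N")
    tid <- paste0(pid, "_T")
    expr <- cbind(normal, tumor)
    rownames(expr) <- genes
    colnames(expr) <- c(nid, tid)
    paired_cohort(expr,
                  tibble(patient_id = pid, normal_sample_id = nid,
                         tumor_sample_id = tid),
                  cancer = cn)
  })
  names(cohorts) <- cancers

  truth <- dplyr::mutate(de_effects,
                         direction = ifelse(.data$effect > 0, "up", "down"))
  list(cohorts = cohorts, truth = truth)
}

#' Simulate a survival cohort with a signature-driven hazard
#'
#' Expression is drawn on a log2-like scale with unit SD around per-gene
#' baselines. Signature genes share a single latent factor: gene value =
#' loading * factor + sqrt(1 - loading^2) * noise, so every pair of signature
#' genes has correlation loading^2; non-signature genes are independent.
#' Event times follow an exponential proportional-hazards model with linear
#' predictor sum(beta_g * centered expression) over signature genes; censoring
#' is the minimum of an independent exponential time and an administrative
#' cutoff.
#'
#' @param n_samples patients.
#' @param n_genes size of the gene universe.
#' @param signature_genes character vector of signature gene ids (must lie in
#'   the universe `g0001`...), or an integer count to take the first k genes.
#' @param beta named numeric vector of true log-hazard coefficients per
#'   expression unit (names = gene ids, default: zero for all signature
#'   genes); genes absent from `beta` get coefficient 0.
#' @param latent_loading loading in `[0, 1)` of signature genes on the shared
#'   factor; pairwise signature correlation is `latent_loading^2`.
#' @param baseline_hazard events per time unit at the mean expression profile.
#' @param censoring_rate rate of the independent exponential censoring time.
#' @param admin_censor_time administrative censoring horizon.
#' @param baseline_mean mean log2 baseline.
#' @param name cohort label.
#' @param seed integer seed (required).
#'
#' @return list with `cohort` (a [survival_cohort()]) and `truth`, a tibble
#'   (gene, beta, in_signature).
#' @export
simulate_survival_cohort <- function(n_samples = 300, n_genes = 1000,
                                     signature_genes = 45, beta = NULL,
                                     latent_loading = 0.5,
                                     baseline_hazard = 0.1,
                                     censoring_rate = 0.04,
                                     admin_censor_time = 60,
                                     baseline_mean = 8,
                                     name = "sim", seed) {
  if (missing(seed)) abort("`seed` is required", class = "progsig_config_error")
  if (n_samples < 2 || n_genes < 1) {
    abort("sizes must be positive", class = "progsig_config_error")
  }
  if (baseline_hazard <= 0 || censoring_rate <= 0 || admin_censor_time <= 0) {
    abort("hazard, censoring rate and admin time must be > 0",
          class = "progsig_config_error")
  }
  if (latent_loading < 0 || latent_loading >= 1) {
    abort("latent_loading must lie in [0, 1)", class = "progsig_config_error")
  }
  set.seed(seed)

  genes <- sprintf("g%04d", seq_len(n_genes))
  if (is.numeric(signature_genes) && length(signature_genes) == 1) {
    signature_genes <- genes[seq_len(signature_genes)]
  }
  if (!all(signature_genes %in% genes)) {
    abort("signature genes must lie inside the gene universe",
          class = "progsig_config_error")
  }

  baseline <- rnorm(n_genes, baseline_mean, 1)
  z <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  rownames(z) <- genes
  if (latent_loading > 0 && length(signature_genes) > 0) {
    f <- rnorm(n_samples)
    z[signature_genes, ] <- latent_loading * matrix(f, length(signature_genes),
                                                    n_samples, byrow = TRUE) +
      sqrt(1 - latent_loading^2) * z[signature_genes, , drop = FALSE]
  }
  expr <- baseline + z
  colnames(expr) <- sprintf("%s_s%04d", name, seq_len(n_samples))

  b <- setNames(numeric(n_genes), genes)
  if (!is.null(beta)) {
    if (is.null(names(beta))) abort("`beta` must be named by gene id",
                                    class = "progsig_config_error")
    bad <- setdiff(names(beta), genes)
    if (length(bad)) abort("`beta` names must lie in the gene universe",
                           class = "progsig_config_error")
    b[names(beta)] <- beta
  }
  active <- names(b)[b != 0]
  lp <- if (length(active)) {
    drop(crossprod(z[active, , drop = FALSE], b[active]))
  } else {
    numeric(n_samples)
  }

  event_time <- rexp(n_samples, rate = baseline_hazard * exp(lp))
  censor_time <- pmin(rexp(n_samples, rate = censoring_rate), admin_censor_time)
  time <- pmin(event_time, censor_time)
  event <- as.integer(event_time <= censor_time)
  time <- pmax(time, .Machine$double.eps)

  clinical <- tibble(sample_id = colnames(expr), time = time, event = event)
  list(cohort = survival_cohort(expr, clinical, name = name),
       truth = tibble(gene = genes, beta = unname(b),
                      in_signature = genes %in% signature_genes))
}
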