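#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], with every
#' stochastic stage given a seed derived from one master seed by a fixed
#' splitting rule (`seed + 1000 * stage index`), so each stage is
#' independently reproducible.
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed master integer seed.
#' @param stages which stages to run, in pipeline order.
#' @param paired,survival,selection,resampling,network stage parameter lists;
#'   entries override the defaults shown in the function body.
#' @return a `RunConfig`-style named list.
#' @export
pipeline_config <- function(out_dir, seed,
                            stages = c("simulate", "signature", "train",
                                       "score", "evaluate", "resample",
                                       "network"),
                            paired = list(), survival = list(),
                            selection = list(), resampling = list(),
                            network = list()) {
  if (missing(out_dir) || missing(seed)) {
    abort("out_dir and seed are required", class = "progsig_config_error")
  }
  merge_defaults <- function(defaults, user) utils::modifyList(defaults, user)
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = stages,
    stage_seeds = setNames(as.integer(seed) + 1000L * seq_along(stages),
                           stages),
    paired = merge_defaults(
      list(n_cancers = 6, n_genes = 1000, n_pairs = 30, n_de_genes = 50,
           effect_size = 1.0, accordant_in = 5, pair_effect_sd = 0.5,
           noise_sd = 0.5), paired),
    survival = merge_defaults(
      list(n_samples = 300, signature_size = 45, n_prognostic = 10,
           beta = 0.4, latent_loading = 0.5), survival),
    selection = merge_defaults(list(alpha = 0.05, min_cancers = 4), selection),
    resampling = merge_defaults(list(n_resamples = 200), resampling),
    network = merge_defaults(
      list(n_resamples = 100, ensemble_size = 100), network)
  )
}

stage_path <- function(config, ...) file.path(config$out_dir, ...)

require_artifact <- function(config, file, stage, produced_by) {
  p <- stage_path(config, file)
  if (!file.exists(p)) {
    abort(sprintf("stage '%s' needs '%s' produced by stage '%s'",
                  stage, file, produced_by),
          class = "progsig_dependency_error")
  }
  p
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes the enabled stages in order — simulate paired and survival
#' cohorts, derive the accordant-direction signature, train the frozen
#' scoring model, score the validation cohort, evaluate survival separation,
#' run the prognostic resampling null, and run the network-coherence null —
#' writing per-stage TSV/YAML artifacts under `config$out_dir` plus a
#' manifest (JSON) recording seeds, artifact checksums, stage timings and
#' counters. With fixed seeds two runs produce identical artifacts (manifest
#' timings aside).
#'
#' @param config list from [pipeline_config()].
#' @return the manifest, invisibly a list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list(), files = character())
  t_all <- Sys.time()

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- Sys.time()
    info <- fun()
    manifest$stages[[name]] <<- c(
      list(seed = unname(config$stage_seeds[name]),
           seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
      info)
    invisible(NULL)
  }

  run_stage("simulate", function() {
    pc <- config$paired
    sim <- simulate_paired_cohorts(
      n_cancers = pc$n_cancers, n_genes = pc$n_genes, n_pairs = pc$n_pairs,
      n_de_genes = pc$n_de_genes, effect_size = pc$effect_size,
      accordant_in = pc$accordant_in, pair_effect_sd = pc$pair_effect_sd,
      noise_sd = pc$noise_sd, seed = config$stage_seeds[["simulate"]])
    for (cn in names(sim$cohorts)) {
      co <- sim$cohorts[[cn]]
      write_expression(co$expression, stage_path(config, paste0("expr_", cn, ".tsv")))
      readr::write_tsv(co$pairs, stage_path(config, paste0("pairs_", cn, ".tsv")))
    }
    readr::write_tsv(sim$truth, stage_path(config, "paired_truth.tsv"))

    # survival cohorts: hazard driven by a subset of the planted DE genes
    sv <- config$survival
    sig_genes <- unique(sim$truth$gene)
    sig_genes <- sig_genes[seq_len(min(sv$signature_size, length(sig_genes)))]
    prog <- sig_genes[seq_len(min(sv$n_prognostic, length(sig_genes)))]
    beta <- setNames(rep(sv$beta, length(prog)), prog)
    for (role in c("training", "validation")) {
      off <- if (role == "training") 1L else 2L
      simv <- simulate_survival_cohort(
        n_samples = sv$n_samples, n_genes = pc$n_genes,
        signature_genes = sig_genes, beta = beta,
        latent_loading = sv$latent_loading, name = role,
        seed = config$stage_seeds[["simulate"]] + off)
      write_expression(simv$cohort$expression,
                       stage_path(config, paste0("expr_", role, ".tsv")))
      write_clinical(simv$cohort$clinical,
                     stage_path(config, paste0("clinical_", role, ".tsv")))
    }
    write_gene_list(sig_genes, stage_path(config, "signature_universe.txt"))
    list(n_cancers = pc$n_cancers, n_genes = pc$n_genes)
  })

  run_stage("signature", function() {
    de <- purrr::map_dfr(paste0("cancer", seq_len(config$paired$n_cancers)),
      function(cn) {
        expr <- read_expression(
          require_artifact(config, paste0("expr_", cn, ".tsv"), "signature", "simulate"))
        pairs <- read_pairing(
          require_artifact(config, paste0("pairs_", cn, ".tsv"), "signature", "simulate"))
        paired_de(paired_cohort(expr, pairs, cancer = cn))
      })
    readr::write_tsv(de, stage_path(config, "de_results.tsv"))
    sel <- select_common_de(de, alpha = config$selection$alpha,
                            min_cancers = config$selection$min_cancers)
    readr::write_tsv(sel, stage_path(config, "signature_selected.tsv"))
    write_gene_list(sel$gene, stage_path(config, "signature.txt"))
    list(n_selected = nrow(sel))
  })

  load_cohort <- function(role, stage) {
    expr <- read_expression(
      require_artifact(config, paste0("expr_", role, ".tsv"), stage, "simulate"))
    cl <- read_clinical(
      require_artifact(config, paste0("clinical_", role, ".tsv"), stage, "simulate"))
    survival_cohort(expr, cl, name = role)
  }

  run_stage("train", function() {
    signature <- read_gene_list(
      require_artifact(config, "signature.txt", "train", "signature"))
    training <- load_cohort("training", "train")
    model <- build_scoring_model(training, signature)
    write_scoring_model(model, stage_path(config, "scoring_model.yml"))
    list(n_model_genes = nrow(model))
  })

  run_stage("score", function() {
    model <- read_scoring_model(
      require_artifact(config, "scoring_model.yml", "score", "train"))
    validation <- load_cohort("validation", "score")
    risk <- compute_risk_scores(model, validation)
    readr::write_tsv(risk, stage_path(config, "risk_validation.tsv"))
    list(n_positive = sum(risk$group == "positive"),
         n_genes_used = attr(risk, "n_genes_used"))
  })

  run_stage("evaluate", function() {
    risk <- readr::read_tsv(
      require_artifact(config, "risk_validation.tsv", "evaluate", "score"),
      show_col_types = FALSE)
    validation <- load_cohort("validation", "evaluate")
    cl <- dplyr::inner_join(validation$clinical, risk, by = "sample_id")
    fit <- fit_univariate_cox(as.integer(cl$group == "positive"),
                              cl$time, cl$event)
    lr <- logrank_test(cl$time, cl$event, cl$group)
    eval_tab <- tibble(cohort = "validation", covariate = "signature + vs. -",
                       hr = fit$hr, conf.low = fit$conf.low,
                       conf.high = fit$conf.high, p.value = fit$p.value,
                       logrank_chi_square = lr$chi_square,
                       logrank_p = lr$p.value)
    readr::write_tsv(eval_tab, stage_path(config, "evaluation.tsv"))
    km <- km_curve(cl$time, cl$event, cl$group)
    readr::write_tsv(km, stage_path(config, "km_validation.tsv"))
    list(hr = fit$hr, logrank_p = lr$p.value)
  })

  run_stage("resample", function() {
    signature <- read_gene_list(
      require_artifact(config, "signature.txt", "resample", "signature"))
    training <- load_cohort("training", "resample")
    validation <- load_cohort("validation", "resample")
    pool <- intersect(rownames(training$expression),
                      rownames(validation$expression))
    res <- prognostic_null_test(signature, training, validation, pool,
                                n_resamples = config$resampling$n_resamples,
                                seed = config$stage_seeds[["resample"]])
    readr::write_tsv(glance(res), stage_path(config, "resampling_prognostic.tsv"))
    readr::write_tsv(tibble(null_z = res$null_values),
                     stage_path(config, "resampling_prognostic_null.tsv"))
    list(p = res$p, observed = res$observed, n_skipped = res$n_skipped)
  })

  run_stage("network", function() {
    signature <- read_gene_list(
      require_artifact(config, "signature.txt", "network", "signature"))
    training <- load_cohort("training", "network")
    pool <- setdiff(rownames(training$expression), signature)
    res <- coherence_null_test(signature, training$expression, pool,
                               n_resamples = config$network$n_resamples,
                               ensemble_size = config$network$ensemble_size,
                               seed = config$stage_seeds[["network"]])
    readr::write_tsv(glance(res), stage_path(config, "coherence_test.tsv"))
    adj <- infer_adjacency(training$expression[signature, , drop = FALSE],
                           ensemble_size = config$network$ensemble_size,
                           seed = config$stage_seeds[["network"]])
    readr::write_tsv(adjacency_edges(adj), stage_path(config, "network_edges.tsv"))
    list(p = res$p, observed = res$observed)
  })

  files <- setdiff(list.files(config$out_dir), "manifest.json")
  manifest$files <- setNames(
    unname(tools::md5sum(file.path(config$out_dir, files))), files)
  manifest$total_seconds <- as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  jsonlite::write_json(manifest, stage_path(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Human-readable pipeline report
#'
#' Renders the key result tables of a pipeline run — signature size,
#' per-cohort hazard ratios with confidence intervals and p-values, and the
#' resampling summaries — as a character vector of lines. Re-running the
#' report on the same artifacts yields byte-identical output (timings are
#' not included).
#'
#' @param config the [pipeline_config()] used for the run.
#' @return character vector of report lines, invisibly; also printed.
#' @export
pipeline_report <- function(config) {
  lines <- c("== prognostic signature pipeline report ==", "")
  grab <- function(f) {
    p <- stage_path(config, f)
    if (file.exists(p)) readr::read_tsv(p, show_col_types = FALSE) else NULL
  }
  sel <- grab("signature_selected.tsv")
  if (!is.null(sel)) {
    lines <- c(lines, sprintf("Signature: %d genes selected (accordant in >= %d cancers)",
                              nrow(sel), config$selection$min_cancers))
  }
  ev <- grab("evaluation.tsv")
  if (!is.null(ev)) {
    lines <- c(lines, "", "Survival separation (validation):",
               sprintf("  %-22s HR %.2f (%.2f, %.2f)  Wald p %.3g  log-rank p %.3g",
                       ev$covariate, ev$hr, ev$conf.low, ev$conf.high,
                       ev$p.value, ev$logrank_p))
  }
  rs <- grab("resampling_prognostic.tsv")
  if (!is.null(rs)) {
    lines <- c(lines, "", sprintf(
      "Prognostic resampling null: observed z = %.3f, one-tailed p = %.4g (%d resamples, %d skipped)",
      rs$observed, rs$p.value, rs$n_resamples, rs$n_skipped))
  }
  ch <- grab("coherence_test.tsv")
  if (!is.null(ch)) {
    lines <- c(lines, sprintf(
      "Coherence null: observed adjacency sum = %.3f, one-tailed p = %.4g (%d resamples)",
      ch$observed, ch$p.value, ch$n_resamples))
  }
  if (length(lines) == 2) {
    warn("no pipeline artifacts found; empty report")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
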