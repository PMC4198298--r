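#' Read and write expression matrices as TSV
#'
#' Expression files are tab-separated with gene ids in the first column
#' (header `gene_id`) and one column per sample. Values are log2-scale
#' expression. Round-tripping `read_expression(write_expression(m))`
#' reproduces `m` to within 1e-9.
#'
#' @param path file path.
#' @param matrix numeric genes x samples matrix with dimnames.
#' @return `read_expression` returns the matrix; `write_expression` returns
#'   `path` invisibly.
#' @export
read_expression <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if (ncol(raw) < 2) abort("expression file needs a gene column and >= 1 sample",
                           class = "progsig_parse_error")
  gene_ids <- raw[[1]]
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1]
    abort(sprintf("duplicate gene id '%s' in %s", dup, path),
          class = "progsig_parse_error")
  }
  samples <- names(raw)[-1]
  if (anyDuplicated(samples)) {
    abort(sprintf("duplicate sample id '%s' in %s",
                  samples[duplicated(samples)][1], path),
          class = "progsig_parse_error")
  }
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, samples))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("non-numeric value at gene '%s', sample '%s' in %s",
                  gene_ids[bad[1, 1]], samples[bad[1, 2]], path),
          class = "progsig_parse_error")
  }
  rownames(vals) <- gene_ids
  validate_expression(vals)
}

#' @rdname read_expression
#' @export
write_expression <- function(matrix, path) {
  validate_expression(matrix)
  df <- tibble::as_tibble(matrix, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read and write clinical tables
#'
#' Clinical TSVs carry columns `sample_id`, `time`, `event` followed by any
#' covariate columns. `time` must be positive and `event` coded 0/1.
#'
#' @param path file path.
#' @param clinical a tibble as described above.
#' @export
read_clinical <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  validate_clinical(tab)
}

#' @rdname read_clinical
#' @export
write_clinical <- function(clinical, path) {
  readr::write_tsv(validate_clinical(clinical), path)
  invisible(path)
}

#' Read and write gene-list files
#'
#' One gene symbol per line; `#` starts a comment; blank lines ignored.
#'
#' @param path file path.
#' @param genes character vector.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' @rdname read_gene_list
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Read a pairing table (patient_id, normal_sample_id, tumor_sample_id)
#' @param path file path.
#' @export
read_pairing <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("patient_id", "normal_sample_id", "tumor_sample_id")
  if (!all(needed %in% names(tab))) {
    abort("pairing file needs patient_id, normal_sample_id, tumor_sample_id",
          class = "progsig_parse_error")
  }
  tab
}

#' Serialize a frozen scoring model
#'
#' The scoring model is written as YAML mapping each gene to its Wald weight
#' `z` and scaling coefficients `mu`, `tau`, plus metadata (training cohort,
#' date, seed if recorded). Models are frozen at training time; reading one
#' back reproduces the tibble exactly.
#'
#' @param model a `scoring_model` (see [build_scoring_model()]).
#' @param path file path.
#' @export
write_scoring_model <- function(model, path) {
  stopifnot(inherits(model, "scoring_model"))
  doc <- list(
    training_cohort = attr(model, "training_cohort"),
    created = attr(model, "created"),
    genes = setNames(
      purrr::pmap(list(model$z, model$mu, model$tau),
                  function(z, mu, tau) list(z = z, mu = mu, tau = tau)),
      model$gene)
  )
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' @rdname write_scoring_model
#' @export
read_scoring_model <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$genes) || !length(doc$genes)) {
    abort("scoring model file has no genes", class = "progsig_parse_error")
  }
  tb <- tibble(
    gene = names(doc$genes),
    z = unname(purrr::map_dbl(doc$genes, "z")),
    mu = unname(purrr::map_dbl(doc$genes, "mu")),
    tau = unname(purrr::map_dbl(doc$genes, "tau"))
  )
  new_scoring_model(tb, training_cohort = doc$training_cohort %||% NA_character_,
                    created = doc$created %||% NA_character_)
}
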