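#' Tree-ensemble regulatory-network inference
#'
#' For each target gene a randomized regression-tree ensemble predicts the
#' target from all other genes across samples; the weight `w[i, j]` is the
#' variance-reduction importance of regulator `i` for target `j`, averaged
#' over trees. Targets are standardized to unit variance beforehand so that
#' importances are comparable across targets (each target column's weights
#' sum to roughly the explained-variance mass). The diagonal is exactly zero
#' (self-links excluded); constant genes give zero rows/columns with a
#' warning.
#'
#' Hyperparameters follow the cited tree-ensemble formulation: 100 trees per
#' target, `sqrt(p - 1)` candidate regulators per split, nodes grown until
#' fewer than 10 samples remain.
#'
#' @param expression genes x samples matrix restricted to the gene set of
#'   interest (>= 3 genes, >= 10 samples).
#' @param ensemble_size trees per target (default 100).
#' @param k_candidates candidate regulators per split; 0 means
#'   `floor(sqrt(p - 1))`.
#' @param min_node_size minimum samples per leaf (default 5).
#' @param seed integer seed (required: tree growth is randomized).
#' @return an `adjacency_matrix`: genes x genes nonnegative matrix with zero
#'   diagonal.
#' @export
infer_adjacency <- function(expression, ensemble_size = 100,
                            k_candidates = 0, min_node_size = 5, seed) {
  validate_expression(expression)
  if (missing(seed)) abort("`seed` is required", class = "progsig_config_error")
  if (nrow(expression) < 3) abort("need at least 3 genes",
                                  class = "progsig_validation_error")
  if (ncol(expression) < 10) abort("need at least 10 samples",
                                   class = "progsig_validation_error")
  sds <- apply(expression, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("%d constant genes produce zero network rows/columns",
                 sum(sds == 0)))
  }
  set.seed(seed)
  w <- .tree_ensemble_importance(t(expression), n_trees = ensemble_size,
                                 k_candidates = k_candidates,
                                 min_node_size = min_node_size,
                                 bootstrap = TRUE)
  dimnames(w) <- list(rownames(expression), rownames(expression))
  structure(w, class = c("adjacency_matrix", class(w)))
}

#' Co-expression coherence statistic
#'
#' The sum of all entries of the weighted adjacency matrix — a single number
#' measuring how much expression variance within the gene set is explained by
#' other members of the set. Compared against random same-size gene sets in
#' [coherence_null_test()].
#'
#' @param w an adjacency matrix from [infer_adjacency()].
#' @return nonnegative scalar.
#' @export
coherence_statistic <- function(w) {
  if (!is.matrix(w) || nrow(w) != ncol(w)) {
    abort("`w` must be a square adjacency matrix", class = "progsig_validation_error")
  }
  if (any(w < 0) || any(diag(w) != 0)) {
    abort("adjacency must be nonnegative with zero diagonal",
          class = "progsig_validation_error")
  }
  sum(w)
}

#' Convert an adjacency matrix to a tidy edge list
#' @param w an `adjacency_matrix`.
#' @return tibble `regulator`, `target`, `weight` sorted by weight.
#' @export
adjacency_edges <- function(w) {
  genes <- rownames(w)
  out <- tidyr::expand_grid(regulator = genes, target = genes)
  out$weight <- as.vector(t(unclass(w)))  # row-major: regulator varies slowest
  out <- out[out$regulator != out$target, ]
  dplyr::arrange(out, dplyr::desc(.data$weight))
}
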