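#' Collapse probe-level rows to gene level by averaging
#'
#' Each gene's expression row is the arithmetic mean of all probe rows that
#' map to it. Probes absent from the mapping are dropped (a message reports
#' how many).
#'
#' @param matrix numeric probes x samples matrix (probe ids as rownames).
#' @param mapping data frame with columns `probe` and `gene`.
#' @return genes x samples matrix.
#' @export
collapse_probes <- function(matrix, mapping) {
  validate_expression(matrix)
  mapping <- as_tibble(mapping)
  if (!all(c("probe", "gene") %in% names(mapping)) || nrow(mapping) == 0) {
    abort("`mapping` must be a non-empty table with columns probe, gene",
          class = "progsig_config_error")
  }
  mapping <- mapping[!duplicated(mapping$probe), ]
  mapped <- intersect(rownames(matrix), mapping$probe)
  n_drop <- nrow(matrix) - length(mapped)
  if (n_drop > 0) inform(sprintf("collapse_probes: dropped %d unmapped probes", n_drop))
  if (!length(mapped)) {
    abort("no probes in the matrix are covered by the mapping",
          class = "progsig_config_error")
  }
  sub <- matrix[mapped, , drop = FALSE]
  gene <- mapping$gene[match(mapped, mapping$probe)]
  sums <- rowsum(sub, group = gene)
  counts <- as.vector(table(gene)[rownames(sums)])
  out <- sums / counts
  validate_expression(out)
}

#' Filter genes by detection fraction
#'
#' Retains genes deemed present in at least `min_fraction` of samples
#' (default two thirds). Presence defaults to "value strictly greater than a
#' floor", the floor defaulting to the cohort-wide 10th percentile; supply
#' `present` to plug in any other per-value predicate (e.g. detection calls).
#'
#' @param matrix genes x samples matrix.
#' @param min_fraction minimum fraction of samples in which a gene must be
#'   present; in `(0, 1]`.
#' @param floor presence threshold used by the default predicate.
#' @param present optional predicate: function of the matrix returning a
#'   logical matrix of the same shape.
#' @return filtered matrix (possibly with zero rows, with a warning).
#' @export
detection_filter <- function(matrix, min_fraction = 2 / 3, floor = NULL,
                             present = NULL) {
  validate_expression(matrix)
  if (min_fraction <= 0 || min_fraction > 1) {
    abort("min_fraction must be in (0, 1]", class = "progsig_config_error")
  }
  pres <- if (is.null(present)) {
    if (is.null(floor)) floor <- quantile(matrix, 0.1, names = FALSE)
    matrix > floor
  } else {
    present(matrix)
  }
  keep <- rowMeans(pres) >= min_fraction
  if (!any(keep)) warn("detection_filter removed every gene")
  matrix[keep, , drop = FALSE]
}

normalize_chrom <- function(x) {
  sub("^chr", "", tolower(trimws(as.character(x))))
}

#' Remove genes on the sex chromosomes
#'
#' Drops genes whose annotated chromosome normalizes to X or Y (labels are
#' matched case-insensitively, with an optional `chr` prefix). Genes missing
#' from the annotation are retained with a warning rather than silently
#' shrinking the gene pool.
#'
#' @param matrix genes x samples matrix.
#' @param annotation data frame with columns `gene` and `chromosome`.
#' @export
drop_sex_chromosomes <- function(matrix, annotation) {
  validate_expression(matrix)
  annotation <- as_tibble(annotation)
  if (!all(c("gene", "chromosome") %in% names(annotation))) {
    abort("`annotation` needs columns gene, chromosome",
          class = "progsig_config_error")
  }
  if (anyDuplicated(annotation$gene)) {
    abort("annotation maps a gene to more than one chromosome",
          class = "progsig_validation_error")
  }
  chrom <- normalize_chrom(annotation$chromosome)[match(rownames(matrix),
                                                        annotation$gene)]
  unannotated <- is.na(chrom)
  if (any(unannotated)) {
    warn(sprintf("%d genes lack a chromosome annotation and were retained",
                 sum(unannotated)))
  }
  drop <- !unannotated & chrom %in% c("x", "y")
  matrix[!drop, , drop = FALSE]
}
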