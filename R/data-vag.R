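#' The VDAC1-associated gene signature (VAG)
#'
#' Returns the 45 gene symbols of the VDAC1-associated signature — VDAC1
#' itself plus 44 interacting genes commonly dysregulated in the accordant
#' direction across breast, colon, liver, lung, pancreatic and thyroid
#' carcinomas. Shipped as a plain-text fixture so analyses on user cohorts
#' can start from the published signature.
#'
#' @return character vector of 45 gene symbols.
#' @export
#' @examples
#' head(vag_signature())
vag_signature <- function() {
  read_gene_list(system.file("extdata", "vag_signature.txt",
                             package = "progsig", mustWork = TRUE))
}
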