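#' Assemble a cohort dataset
#'
#' Cross-checks a Ct matrix, a clinical table and a gene panel into a single
#' validated cohort object. Every Ct sample must have a clinical row; clinical
#' rows without expression data are dropped with a warning. Samples are put in
#' Ct-matrix order in both components so downstream stages can index by
#' position. A per-gene missingness report (count of undetermined wells) is
#' attached.
#'
#' @param ct a [ct_matrix()].
#' @param clinical a [clinical_table()].
#' @param panel a [gene_panel()]; every Ct gene must be on the panel.
#' @return object of class \code{cohort_dataset}: list with \code{panel},
#'   \code{ct}, \code{clinical} and a \code{missingness} data.frame
#'   (gene, n_masked, all_masked).
#' @export
assemble_cohort <- function(ct, clinical, panel = default_gene_panel()) {
  stopifnot(inherits(ct, "ct_matrix"), inherits(clinical, "clinical_table"),
            inherits(panel, "gene_panel"))
  off_panel <- setdiff(ct$genes, panel$gene)
  if (length(off_panel) > 0L)
    stop("Ct gene(s) not on the panel: ", paste(off_panel, collapse = ", "))
  absent <- setdiff(ct$samples, clinical$sample_id)
  if (length(absent) > 0L)
    stop("Ct sample(s) without clinical annotation: ",
         paste(absent, collapse = ", "))
  unused <- setdiff(clinical$sample_id, ct$samples)
  if (length(unused) > 0L) {
    warning("dropping ", length(unused),
            " clinical row(s) without expression data: ",
            paste(unused, collapse = ", "))
  }
  clinical <- clinical[match(ct$samples, clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- NULL
  class(clinical) <- c("clinical_table", "data.frame")
  missingness <- data.frame(
    gene = ct$genes,
    n_masked = rowSums(ct$mask),
    all_masked = rowSums(ct$mask) == length(ct$samples),
    stringsAsFactors = FALSE)
  rownames(missingness) <- NULL
  structure(list(panel = panel, ct = ct, clinical = clinical,
                 missingness = missingness),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(paste0("cohort_dataset: %d samples, %d genes ",
                     "(%d reference), %d relapse event(s)\n"),
              length(x$ct$samples), length(x$ct$genes),
              sum(x$panel$is_reference & x$panel$gene %in% x$ct$genes),
              sum(x$clinical$relapse)))
  invisible(x)
}
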