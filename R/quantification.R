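#' Apply the detection cutoff to a Ct matrix
#'
#' Wells at or beyond the cutoff cycle are treated as non-expressed and
#' masked. The boundary is inclusive: a Ct exactly equal to the cutoff is
#' masked, the conventional reading of "a threshold cycle value equal to 35
#' used as the cutoff for non-expressed genes"; set \code{inclusive = FALSE}
#' to mask strictly greater values only.
#'
#' @param ct a [ct_matrix()].
#' @param cutoff cycles; default 35.
#' @param inclusive mask \code{Ct >= cutoff} (default) rather than
#'   \code{Ct > cutoff}.
#' @return a [ct_matrix()] with the additional wells masked.
#' @export
apply_detection_cutoff <- function(ct, cutoff = 35, inclusive = TRUE) {
  stopifnot(inherits(ct, "ct_matrix"), cutoff > 0)
  hit <- if (inclusive) !is.na(ct$ct) & ct$ct >= cutoff
         else !is.na(ct$ct) & ct$ct > cutoff
  ct_matrix(ct$ct, ct$mask | hit)
}

#' Rank candidate reference genes by expression stability
#'
#' Model-based reference-gene selection in the NormFinder spirit: expression
#' values (Ct or any log-scale measure) are first centered per sample (mean
#' over candidate genes) to remove the sample loading effect, then each gene
#' is scored by combining systematic between-group differences with its
#' within-group variability. For each gene and group the inter-group bias is
#' the deviation of the gene's group mean from its overall mean, shrunk
#' toward zero by an empirical-Bayes factor so that noisy estimates from
#' small groups are not mistaken for bias. The stability value is the average
#' over groups of |shrunken bias| + within-group sampling standard error;
#' lower is more stable. With no groups the value reduces to the per-gene
#' standard deviation of the sample-centered values.
#'
#' @param expr genes x samples numeric matrix on a log scale (e.g. raw Ct);
#'   \code{NA} allowed and ignored pairwise.
#' @param groups optional factor/vector of group labels per sample (at least
#'   2 samples per group).
#' @param center center each sample by its mean over genes first
#'   (default TRUE).
#' @return object of class \code{stability_ranking}: data.frame with columns
#'   \code{gene}, \code{stability}, \code{intra} (within-group variability
#'   component), \code{inter} (|shrunken bias| component), \code{rank},
#'   ordered most-stable first. Ties are broken alphabetically by gene so the
#'   ordering is always unambiguous.
#' @export
stability_ranking <- function(expr, groups = NULL, center = TRUE) {
  if (inherits(expr, "ct_matrix")) expr <- expr$ct
  if (inherits(expr, "delta_ct_matrix")) expr <- expr$dct
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (ncol(expr) < 2L) stop("stability ranking needs at least 2 samples")
  genes <- rownames(expr)
  if (center) {
    smean <- colMeans(expr, na.rm = TRUE)
    expr <- sweep(expr, 2L, smean, "-")
  }
  if (is.null(groups)) {
    intra <- apply(expr, 1L, stats::sd, na.rm = TRUE)
    res <- data.frame(gene = genes, stability = intra,
                      intra = intra, inter = 0, stringsAsFactors = FALSE)
  } else {
    groups <- as.factor(groups)
    if (length(groups) != ncol(expr))
      stop("'groups' must have one label per sample")
    if (any(table(groups) < 2L))
      stop("every group needs at least 2 samples")
    glev <- levels(groups)
    gmean <- rowMeans(expr, na.rm = TRUE)
    # per gene x group: mean deviation from the gene's overall mean (bias d),
    # within-group variance s2 and group size n
    d <- s2 <- nmat <- matrix(NA_real_, nrow(expr), length(glev),
                              dimnames = list(genes, glev))
    for (j in seq_along(glev)) {
      sub <- expr[, groups == glev[j], drop = FALSE]
      nmat[, j] <- rowSums(!is.na(sub))
      d[, j] <- rowMeans(sub, na.rm = TRUE) - gmean
      s2[, j] <- apply(sub, 1L, stats::var, na.rm = TRUE)
    }
    s2[is.na(s2)] <- 0
    samp_var <- s2 / pmax(nmat, 1)         # sampling variance of each d
    # empirical-Bayes shrinkage: genuine bias variance across genes/groups
    tau2 <- max(0, mean(d^2, na.rm = TRUE) - mean(samp_var, na.rm = TRUE))
    shrink <- tau2 / (tau2 + samp_var)
    d_shrunk <- d * shrink
    inter <- rowMeans(abs(d_shrunk), na.rm = TRUE)
    intra <- rowMeans(sqrt(samp_var), na.rm = TRUE)
    res <- data.frame(gene = genes, stability = inter + intra,
                      intra = intra, inter = inter, stringsAsFactors = FALSE)
  }
  res <- res[order(res$stability, res$gene), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("stability_ranking", "data.frame")
  res
}

#' Choose the normalization reference set
#'
#' Three strategies are supported: the card's two housekeeping assays
#' (\emph{RPL32} and \emph{18S}); the k most stable genes of a
#' [stability_ranking()]; or global-mean normalization, where each sample's
#' mean Ct over all measured genes plays the role of the reference.
#'
#' @param strategy \code{"housekeeping"}, \code{"stability_top_k"} or
#'   \code{"global_mean"}.
#' @param panel a [gene_panel()] (used by \code{housekeeping}).
#' @param ranking a [stability_ranking()] (needed by \code{stability_top_k}).
#' @param k number of reference genes for \code{stability_top_k}.
#' @param available optional character vector of measured genes; the
#'   housekeeping strategy errors if its genes are not all available.
#' @return object of class \code{reference_set}: list with \code{strategy}
#'   and \code{genes} (character vector, or \code{NULL} for
#'   \code{global_mean}, meaning "per-sample mean Ct of all measured genes").
#' @export
select_references <- function(strategy = c("housekeeping", "stability_top_k",
                                           "global_mean"),
                              panel = default_gene_panel(), ranking = NULL,
                              k = 2, available = NULL) {
  strategy <- match.arg(strategy)
  genes <- switch(strategy,
    housekeeping = {
      hk <- reference_genes(panel)
      if (length(hk) == 0L) stop("panel declares no housekeeping genes")
      if (!is.null(available) && length(setdiff(hk, available)) > 0L)
        stop("housekeeping gene(s) not measured: ",
             paste(setdiff(hk, available), collapse = ", "))
      hk
    },
    stability_top_k = {
      if (is.null(ranking)) stop("'ranking' is required for stability_top_k")
      utils::head(ranking$gene, k)
    },
    global_mean = NULL)
  structure(list(strategy = strategy, genes = genes), class = "reference_set")
}

#' Compute delta-Ct values against a reference set
#'
#' For each sample s, the reference level R(s) is the arithmetic mean Ct of
#' the reference genes (equivalently the log2 geometric mean of their linear
#' quantities), or the mean Ct over all measured genes under global-mean
#' normalization. Then dCt(g, s) = Ct(g, s) - R(s); per-sample additive Ct
#' offsets (loading differences) cancel. A cell is masked where the target
#' Ct is masked or no reference gene was measured in that sample (the whole
#' column is then masked with a warning). Genes consumed as explicit
#' references are dropped from the result.
#'
#' @param ct a [ct_matrix()], normally after [apply_detection_cutoff()].
#' @param refs a [select_references()] descriptor.
#' @param drop_refs drop explicit reference genes from the output
#'   (default TRUE; ignored for global-mean).
#' @return object of class \code{delta_ct_matrix}: list with \code{dct}
#'   (genes x samples, \code{NA} where masked), \code{genes}, \code{samples},
#'   and \code{normalization} (the reference descriptor).
#' @export
compute_delta_ct <- function(ct, refs, drop_refs = TRUE) {
  stopifnot(inherits(ct, "ct_matrix"), inherits(refs, "reference_set"))
  if (is.null(refs$genes)) {          # global mean
    R <- colMeans(ct$ct, na.rm = TRUE)
    keep <- ct$genes
  } else {
    miss <- setdiff(refs$genes, ct$genes)
    if (length(miss) > 0L)
      stop("reference gene(s) absent from Ct matrix: ",
           paste(miss, collapse = ", "))
    refct <- ct$ct[refs$genes, , drop = FALSE]
    R <- colMeans(refct, na.rm = TRUE)
    keep <- if (drop_refs) setdiff(ct$genes, refs$genes) else ct$genes
  }
  if (any(nodata <- !is.finite(R)))
    warning("no measured reference value in sample(s): ",
            paste(ct$samples[nodata], collapse = ", "),
            "; their delta-Ct column is masked")
  R[!is.finite(R)] <- NA_real_
  dct <- sweep(ct$ct[keep, , drop = FALSE], 2L, R, "-")
  structure(list(dct = dct, genes = keep, samples = ct$samples,
                 normalization = refs),
            class = "delta_ct_matrix")
}

#' Relative quantification by the comparative delta-delta-Ct method
#'
#' ddCt(g, s) = dCt(g, s) - C(g), where C(g) is the calibrator's delta-Ct for
#' gene g, and RQ = 2^-ddCt. With the default cohort-mean calibrator C(g) is
#' the mean dCt of gene g over all samples, so each RQ is the fold expression
#' relative to the cohort average and the geometric mean RQ of every gene is
#' 1 by construction. A named sample can be used as calibrator instead, in
#' which case that sample's RQ is 1 for every gene.
#'
#' @param dct a [compute_delta_ct()] result.
#' @param calibrator \code{"cohort_mean"} or a sample id.
#' @return object of class \code{expression_matrix}: list with \code{rq}
#'   (genes x samples, > 0 where defined), \code{log2rq} (= -ddCt),
#'   \code{genes}, \code{samples}, \code{calibrator}.
#' @export
compute_rq <- function(dct, calibrator = "cohort_mean") {
  stopifnot(inherits(dct, "delta_ct_matrix"))
  if (identical(calibrator, "cohort_mean")) {
    C <- rowMeans(dct$dct, na.rm = TRUE)
  } else {
    if (!calibrator %in% dct$samples)
      stop("calibrator sample not found: ", calibrator)
    C <- dct$dct[, calibrator]
    if (any(is.na(C)))
      warning("calibrator sample has masked gene(s); their RQ column is masked")
  }
  ddct <- sweep(dct$dct, 1L, C, "-")
  structure(list(rq = 2^(-ddct), log2rq = -ddct,
                 genes = dct$genes, samples = dct$samples,
                 calibrator = calibrator, normalization = dct$normalization),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (RQ): %d genes x %d samples, calibrator: %s\n",
              length(x$genes), length(x$samples),
              if (identical(x$calibrator, "cohort_mean")) "cohort mean"
              else x$calibrator))
  invisible(x)
}
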