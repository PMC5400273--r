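#' Unsupervised hierarchical clustering of patients on delta-Ct profiles
#'
#' Patients are clustered on their delta-Ct profiles using Euclidean distance
#' and Ward's minimum-variance criterion in its classical barycenter
#' formulation (\code{stats::hclust} method \code{"ward.D2"} on Euclidean
#' distances, i.e. Ward on squared Euclidean distances). Clustering runs on
#' raw delta-Ct values as measured; an optional z-score standardization per
#' gene is available. Masked cells are mean-imputed per gene with a warning.
#' A gene dendrogram (same distance/linkage on gene profiles) is returned for
#' heatmap display.
#'
#' @param dct a [compute_delta_ct()] matrix.
#' @param genes optional subset of gene symbols to cluster on (default all).
#' @param k number of patient clusters to cut (>= 2); default 2.
#' @param standardize z-score each gene across patients before computing
#'   distances (default FALSE: raw delta-Ct).
#' @return object of class \code{cluster_result}: list with \code{hclust}
#'   (patient tree), \code{labels} (named integer cluster labels at cut k;
#'   clusters numbered by first appearance in sample order), \code{k},
#'   \code{gene_hclust}, \code{display} (the [median_center()] matrix used
#'   for heatmaps) and \code{genes}.
#' @export
hierarchical_cluster <- function(dct, genes = NULL, k = 2, standardize = FALSE) {
  stopifnot(inherits(dct, "delta_ct_matrix"))
  if (is.null(genes)) genes <- dct$genes
  miss <- setdiff(genes, dct$genes)
  if (length(miss) > 0L)
    stop("gene(s) not in delta-Ct matrix: ", paste(miss, collapse = ", "))
  m <- dct$dct[genes, , drop = FALSE]
  n <- ncol(m)
  if (k < 2L) stop("'k' must be >= 2")
  if (k > n) stop("'k' (", k, ") exceeds the number of samples (", n, ")")
  if (anyNA(m)) {
    warning("masked delta-Ct cell(s) mean-imputed per gene for clustering")
    for (i in seq_len(nrow(m))) {
      mi <- is.na(m[i, ])
      if (any(mi)) m[i, mi] <- mean(m[i, ], na.rm = TRUE)
    }
  }
  mc <- if (standardize) t(scale(t(m))) else m
  hc <- stats::hclust(stats::dist(t(mc), method = "euclidean"),
                      method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  # renumber clusters by first appearance so labels do not depend on
  # internal merge order
  labels <- match(raw, unique(raw))
  names(labels) <- colnames(m)
  gene_hc <- if (nrow(mc) >= 3L)
    stats::hclust(stats::dist(mc, method = "euclidean"), method = "ward.D2")
  else NULL
  structure(list(hclust = hc, labels = labels, k = k,
                 gene_hclust = gene_hc, display = median_center(dct, genes),
                 genes = genes),
            class = "cluster_result")
}

#' Median-centered display matrix for expression heatmaps
#'
#' For heatmap display, each gene's delta-Ct values are centered on that
#' gene's median across patients and the sign is flipped so that expression
#' above the median (i.e. lower delta-Ct) is positive -- the usual
#' "red = above median, green = below" convention.
#'
#' @param dct a [compute_delta_ct()] matrix.
#' @param genes optional gene subset.
#' @return numeric matrix (genes x samples) with per-gene median 0.
#' @export
median_center <- function(dct, genes = NULL) {
  stopifnot(inherits(dct, "delta_ct_matrix"))
  if (is.null(genes)) genes <- dct$genes
  m <- dct$dct[genes, , drop = FALSE]
  med <- apply(m, 1L, stats::median, na.rm = TRUE)
  -sweep(m, 1L, med, "-")
}

#' Association between patient clusters and relapse occurrence
#'
#' Builds the cluster x relapse contingency table and tests independence
#' with Pearson's chi-square statistic (no continuity correction). Clusters
#' can be merged before testing, e.g. comparing clusters b and c together
#' against cluster a. A Fisher exact p-value is reported as a supplementary
#' column when any expected count falls below 5 (with a warning).
#'
#' @param labels cluster labels (from [hierarchical_cluster()], or any
#'   vector) named by or aligned with \code{clinical$sample_id}.
#' @param clinical a [clinical_table()].
#' @param merge optional named list mapping new group names to vectors of
#'   cluster labels to pool, e.g. \code{list(a = 1, bc = c(2, 3))}.
#' @return object of class \code{chi2_result}: list with \code{table}
#'   (clusters x relapse 0/1), \code{statistic}, \code{df}, \code{p},
#'   \code{relapse_prop} (per-cluster relapse proportion), and
#'   \code{fisher_p} (NA unless expected counts were small).
#' @export
cluster_relapse_association <- function(labels, clinical, merge = NULL) {
  if (inherits(labels, "cluster_result")) labels <- labels$labels
  if (!is.null(names(labels))) {
    idx <- match(names(labels), clinical$sample_id)
    if (anyNA(idx)) stop("cluster label sample(s) missing from clinical table")
    relapse <- clinical$relapse[idx]
  } else {
    if (length(labels) != nrow(clinical))
      stop("unnamed labels must align with the clinical table")
    relapse <- clinical$relapse
  }
  grp <- as.character(labels)
  if (!is.null(merge)) {
    for (nm in names(merge)) grp[labels %in% merge[[nm]]] <- nm
  }
  keep <- table(grp)
  if (any(keep == 0L)) {
    warning("dropping empty cluster(s)")
  }
  if (length(unique(grp)) < 2L) stop("need at least 2 clusters to test")
  tab <- table(cluster = grp, relapse = factor(relapse, levels = 0:1))
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  fisher_p <- NA_real_
  if (any(chi$expected < 5)) {
    warning("expected count(s) below 5; chi-square approximation is rough ",
            "(Fisher exact p reported alongside)")
    fisher_p <- stats::fisher.test(tab)$p.value
  }
  structure(list(table = tab,
                 statistic = unname(chi$statistic),
                 df = unname(chi$parameter),
                 p = chi$p.value,
                 relapse_prop = prop.table(tab, 1L)[, "1"],
                 fisher_p = fisher_p),
            class = "chi2_result")
}

#' @export
print.chi2_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi-square = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Expression heatmap with dendrograms
#'
#' Draws the median-centered matrix of a [hierarchical_cluster()] result with
#' patient and gene dendrogram ordering, red above / green below the median.
#'
#' @param x a \code{cluster_result}.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the ordered display matrix.
#' @export
plot.cluster_result <- function(x, ...) {
  disp <- x$display
  disp <- disp[, x$hclust$order, drop = FALSE]
  if (!is.null(x$gene_hclust)) disp <- disp[x$gene_hclust$order, , drop = FALSE]
  pal <- grDevices::colorRampPalette(c("green3", "black", "red2"))(63)
  graphics::image(t(disp), col = pal, axes = FALSE,
                  main = sprintf("%d genes, %d patients, k = %d",
                                 nrow(disp), ncol(disp), x$k), ...)
  invisible(disp)
}
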