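#' Signed fold induction from a ratio of group means
#'
#' Converts a positive expression ratio r (mean RQ in the case group over
#' mean RQ in the control group) into the signed fold convention used for
#' fold-induction profiles: +1 means 2-fold up-regulation, -1 means 2-fold
#' down-regulation, 0 means no change. Formally f(r) = r - 1 for r >= 1 and
#' -(1/r - 1) otherwise, which is antisymmetric under taking reciprocals.
#'
#' @param r positive ratio(s).
#' @return signed fold value(s), same length as \code{r}.
#' @examples
#' signed_fold(2)    # +1
#' signed_fold(0.5)  # -1
#' @export
signed_fold <- function(r) {
  if (any(!is.na(r) & r <= 0)) stop("ratio must be > 0")
  ifelse(is.na(r), NA_real_, ifelse(r >= 1, r - 1, -(1 / r - 1)))
}

#' Group-wise fold induction and per-gene significance
#'
#' For a clinical dichotomy (stage 1 vs 2-3, mSBR grade 1-3 vs 4-5, HER2
#' neg vs pos, non-recurrent vs recurrent), computes per gene the mean RQ in
#' each group, their ratio (case over control), the signed fold induction,
#' and a two-sided p-value. Test selection: Welch's t-test on delta-Ct (the
#' log scale, where qPCR noise is closest to Gaussian) when per-group
#' Shapiro-Wilk at 0.05 does not reject normality in either group, otherwise
#' the Kruskal-Wallis rank test on RQ. Both test p-values are always
#' reported alongside the selected one. Masked cells are excluded pairwise.
#'
#' @param rq an [compute_rq()] expression matrix.
#' @param dct the companion [compute_delta_ct()] matrix (for the t-test and
#'   normality gate).
#' @param clinical a [clinical_table()] covering the samples.
#' @param grouping one of \code{"stage"}, \code{"grade"}, \code{"her2"},
#'   \code{"relapse"}.
#' @param shapiro_alpha normality gate level (default 0.05).
#' @return object of class \code{group_comparison}: data.frame (one row per
#'   gene, ordered by ascending fold for profile plotting) with columns
#'   \code{gene, mean_rq_control, mean_rq_case, ratio, fold, test, p,
#'   p_t, p_kw, p_bh}; attributes \code{grouping}, \code{groups} (control,
#'   case), \code{n} (per-group sizes), \code{avg_overexpression_pct}
#'   (100 x mean over genes of (ratio - 1)) and \code{mean_fold}.
#'   \code{p_bh} is a Benjamini-Hochberg adjustment of the selected p-values,
#'   provided as an extra column only; all primary readouts use raw p.
#' @export
compare_groups <- function(rq, dct, clinical,
                           grouping = c("stage", "grade", "her2", "relapse"),
                           shapiro_alpha = 0.05) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(rq, "expression_matrix"),
            inherits(dct, "delta_ct_matrix"))
  g <- clinical_grouping(clinical, grouping)
  g <- g[match(rq$samples, clinical$sample_id)]
  if (any(is.na(g))) stop("clinical table does not cover all samples")
  ctrl <- levels(g)[1L]; case <- levels(g)[2L]
  n_ctrl <- sum(g == ctrl); n_case <- sum(g == case)
  if (n_ctrl == 0L || n_case == 0L)
    stop("both groups must be non-empty for grouping '", grouping, "'")
  do_tests <- n_ctrl >= 2L && n_case >= 2L
  if (!do_tests)
    warning("a group has fewer than 2 samples; tests skipped, folds reported")

  one_gene <- function(gene) {
    rqv <- rq$rq[gene, ]
    dv <- dct$dct[gene, ]
    m0 <- mean(rqv[g == ctrl], na.rm = TRUE)
    m1 <- mean(rqv[g == case], na.rm = TRUE)
    ratio <- m1 / m0
    p_t <- p_kw <- NA_real_
    test <- "none"
    p <- NA_real_
    constant <- stats::sd(dv, na.rm = TRUE) == 0   # degenerate gene row
    if (do_tests && !isTRUE(constant)) {
      d0 <- dv[g == ctrl & !is.na(dv)]; d1 <- dv[g == case & !is.na(dv)]
      r0 <- rqv[g == ctrl & !is.na(rqv)]; r1 <- rqv[g == case & !is.na(rqv)]
      if (length(d0) >= 2L && length(d1) >= 2L &&
          (stats::sd(d0) > 0 || stats::sd(d1) > 0)) {
        p_t <- tryCatch(stats::t.test(d0, d1)$p.value, error = function(e) NA_real_)
      }
      if (length(r0) >= 1L && length(r1) >= 1L) {
        kw <- tryCatch(stats::kruskal.test(list(r0, r1)),
                       error = function(e) NULL)
        if (!is.null(kw)) p_kw <- kw$p.value
      }
      normal <- function(v) {
        if (length(v) < 3L || stats::sd(v) == 0) return(FALSE)
        stats::shapiro.test(v)$p.value >= shapiro_alpha
      }
      if (!is.na(p_t) && normal(d0) && normal(d1)) {
        test <- "welch_t"; p <- p_t
      } else if (!is.na(p_kw)) {
        test <- "kruskal_wallis"; p <- p_kw
      } else if (!is.na(p_t)) {
        test <- "welch_t"; p <- p_t
      }
    }
    data.frame(gene = gene, mean_rq_control = m0, mean_rq_case = m1,
               ratio = ratio, fold = signed_fold(ratio), test = test,
               p = p, p_t = p_t, p_kw = p_kw, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, lapply(rq$genes, one_gene))
  res$p_bh <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$fold), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "grouping") <- grouping
  attr(res, "groups") <- c(control = ctrl, case = case)
  attr(res, "n") <- c(control = n_ctrl, case = n_case)
  attr(res, "avg_overexpression_pct") <- 100 * mean(res$ratio - 1, na.rm = TRUE)
  attr(res, "mean_fold") <- mean(res$fold, na.rm = TRUE)
  class(res) <- c("group_comparison", "data.frame")
  res
}

#' Fold-induction profile plot
#'
#' Bar profile of signed fold induction per gene, in ascending order, with
#' significant genes highlighted (p < 0.05 red, p < 0.10 dark grey).
#'
#' @param x a [compare_groups()] result.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot.group_comparison <- function(x, ...) {
  cols <- ifelse(!is.na(x$p) & x$p < 0.05, "red3",
                 ifelse(!is.na(x$p) & x$p < 0.10, "grey25", "grey70"))
  mid <- graphics::barplot(x$fold, names.arg = x$gene, col = cols, las = 2,
                           cex.names = 0.6, ylab = "fold induction",
                           main = paste0(attr(x, "groups")["case"], " vs ",
                                         attr(x, "groups")["control"]), ...)
  graphics::abline(h = 0)
  invisible(mid)
}
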