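#' Select the relapse-associated gene signature
#'
#' Filters a recurrent-vs-non-recurrent [compare_groups()] result to the
#' genes significantly overexpressed in the relapse group: selected p-value
#' below \code{alpha} and positive signed fold. On the published cohort this
#' selection yields EPO, ETS1, ENO1, PGK1, LDHA and TPI.
#'
#' @param comparison a \code{group_comparison} computed with
#'   \code{grouping = "relapse"}.
#' @param alpha significance level (default 0.05).
#' @return character vector of selected gene symbols (panel order preserved).
#' @export
select_signature <- function(comparison, alpha = 0.05) {
  stopifnot(inherits(comparison, "group_comparison"))
  if (!identical(attr(comparison, "grouping"), "relapse"))
    warning("signature selection is defined on the relapse grouping; got '",
            attr(comparison, "grouping"), "'")
  sel <- comparison$gene[!is.na(comparison$p) & comparison$p < alpha &
                           comparison$fold > 0]
  if (length(sel) == 0L)
    stop("no gene passes p < ", alpha,
         " with positive fold; consider relaxing the threshold")
  sel
}

#' Survival-based optimum expression cut-point for one gene
#'
#' Exhaustive search for the expression threshold that best separates
#' relapse-free survival: candidate thresholds are the midpoints between
#' consecutive sorted distinct values; at each candidate, patients are split
#' into expression > tau versus <= tau and the two-group log-rank statistic
#' is computed; the tau maximizing the statistic is returned. Splits leaving
#' fewer than \code{ceil(min_frac * n)} patients on either side are
#' inadmissible. Ties on the statistic are broken toward the more balanced
#' split, then toward the smaller tau.
#'
#' @param values one gene's expression (RQ) over patients.
#' @param times,events relapse-free survival times and 0/1 indicators.
#' @param min_frac minimum fraction of patients on each side (default 0.1).
#' @return list with \code{threshold}, \code{statistic}, \code{p},
#'   \code{n_candidates} (admissible midpoints examined), \code{profile}
#'   (data.frame of tau, statistic, n_high) and \code{min_frac}.
#' @export
optimal_cutpoint <- function(values, times, events, min_frac = 0.1) {
  ok <- !is.na(values)
  values <- values[ok]; times <- times[ok]; events <- as.integer(events[ok])
  n <- length(values)
  v <- sort(unique(values))
  if (length(v) < 2L) stop("need at least 2 distinct expression values")
  taus <- (v[-length(v)] + v[-1L]) / 2
  min_n <- ceiling(min_frac * n)
  prof <- lapply(taus, function(tau) {
    high <- values > tau
    n_high <- sum(high)
    if (n_high < min_n || (n - n_high) < min_n) return(NULL)
    core <- .logrank_core(times, events, high)
    stat <- if (is.null(core) || core$V <= 0) 0
            else (core$O1 - core$E1)^2 / core$V
    c(tau = tau, statistic = stat, n_high = n_high)
  })
  prof <- do.call(rbind, prof)
  if (is.null(prof)) stop("no admissible cut at min_frac = ", min_frac)
  prof <- as.data.frame(prof)
  best <- prof$statistic >= max(prof$statistic) - 1e-12
  cand <- prof[best, , drop = FALSE]
  balance <- abs(cand$n_high - (n - cand$n_high))
  cand <- cand[order(balance, cand$tau), , drop = FALSE]
  tau <- cand$tau[1L]; stat <- cand$statistic[1L]
  list(threshold = tau, statistic = stat,
       p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       n_candidates = nrow(prof), profile = prof, min_frac = min_frac)
}

#' Per-gene optimum threshold table for a signature
#'
#' Runs [optimal_cutpoint()] on each signature gene's RQ values against
#' relapse-free survival and collects the optima. Alternatively, with
#' \code{mode = "published"}, returns the fixed published optima
#' ([published_threshold_table()]) in the same schema, for scoring new
#' cohorts against the reported cut-offs.
#'
#' @param rq an [compute_rq()] expression matrix.
#' @param signature character vector of signature genes (default the
#'   published six).
#' @param clinical a [clinical_table()] covering the samples.
#' @param mode \code{"search"} (optimize on this cohort) or
#'   \code{"published"}.
#' @param min_frac minimum group fraction per side for the search.
#' @return a \code{threshold_table}: data.frame with columns \code{gene},
#'   \code{threshold}, \code{statistic}, \code{n_candidates},
#'   \code{min_frac}; attribute \code{mode}.
#' @export
build_threshold_table <- function(rq, signature = signature_genes(), clinical,
                                  mode = c("search", "published"),
                                  min_frac = 0.1) {
  mode <- match.arg(mode)
  if (mode == "published") return(published_threshold_table())
  stopifnot(inherits(rq, "expression_matrix"))
  miss <- setdiff(signature, rq$genes)
  if (length(miss) > 0L)
    stop("signature gene(s) absent from expression matrix: ",
         paste(miss, collapse = ", "))
  idx <- match(rq$samples, clinical$sample_id)
  if (anyNA(idx)) stop("clinical table does not cover all samples")
  times <- clinical$rfs_months[idx]
  events <- clinical$relapse[idx]
  rows <- lapply(signature, function(g) {
    cp <- optimal_cutpoint(rq$rq[g, ], times, events, min_frac = min_frac)
    data.frame(gene = g, threshold = cp$threshold, statistic = cp$statistic,
               n_candidates = cp$n_candidates, min_frac = min_frac,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- c("threshold_table", "data.frame")
  attr(tab, "mode") <- "search"
  tab
}

#' Per-patient relapse risk scores
#'
#' The risk score of a patient is the number of signature genes whose RQ
#' strictly exceeds its optimum threshold: S = sum over genes of
#' 1[RQ > tau_g], an integer between 0 and the signature size. Expression
#' exactly at a threshold scores 0 for that gene. Patients with any masked
#' signature gene get a score computed over the measured genes and are
#' flagged incomplete.
#'
#' @param rq an [compute_rq()] expression matrix.
#' @param thresholds a [build_threshold_table()] /
#'   [published_threshold_table()] table.
#' @return object of class \code{risk_scores}: data.frame with
#'   \code{sample_id}, \code{score}, \code{incomplete}, plus one 0/1
#'   indicator column per signature gene (named \code{ind_<gene>}).
#' @export
compute_scores <- function(rq, thresholds) {
  stopifnot(inherits(rq, "expression_matrix"),
            inherits(thresholds, "threshold_table"))
  miss <- setdiff(thresholds$gene, rq$genes)
  if (length(miss) > 0L)
    stop("signature gene(s) absent from expression matrix: ",
         paste(miss, collapse = ", "))
  vals <- rq$rq[thresholds$gene, , drop = FALSE]
  ind <- (vals > thresholds$threshold) * 1L          # NA propagates
  score <- colSums(ind, na.rm = TRUE)
  incomplete <- colSums(is.na(ind)) > 0L
  out <- data.frame(sample_id = rq$samples, score = as.integer(score),
                    incomplete = incomplete, stringsAsFactors = FALSE)
  indt <- as.data.frame(t(ind))
  names(indt) <- paste0("ind_", thresholds$gene)
  out <- cbind(out, indt)
  rownames(out) <- NULL
  class(out) <- c("risk_scores", "data.frame")
  out
}

#' Choose the score threshold separating low- and high-risk patients
#'
#' For every candidate s in 0..(max score - 1), patients are dichotomized
#' into score <= s (low) versus score >= s + 1 (high) and the log-rank
#' statistic of the two relapse-free survival curves is computed; the s
#' maximizing it is returned together with the whole profile. Ties are broken
#' toward the smallest maximizing s, which yields the largest (most
#' inclusive) high-risk group.
#'
#' @param scores integer scores (a \code{risk_scores} frame or a vector).
#' @param times,events relapse-free survival times and 0/1 indicators.
#' @return list with \code{threshold} (s*), \code{statistic}, \code{p} and
#'   \code{profile} (data.frame of s, statistic, n_low, n_high; statistic NA
#'   where a side is empty or no events remain informative).
#' @export
select_score_threshold <- function(scores, times, events) {
  if (inherits(scores, "risk_scores")) scores <- scores$score
  if (length(unique(scores)) < 2L)
    stop("scores take a single value; no threshold can be chosen")
  events <- as.integer(events)
  cand <- seq(min(scores), max(scores) - 1L)
  prof <- do.call(rbind, lapply(cand, function(s) {
    low <- scores <= s
    if (!any(low) || all(low))
      return(data.frame(s = s, statistic = NA_real_,
                        n_low = sum(low), n_high = sum(!low)))
    core <- .logrank_core(times, events, low)
    stat <- if (is.null(core) || core$V <= 0) NA_real_
            else (core$O1 - core$E1)^2 / core$V
    data.frame(s = s, statistic = stat, n_low = sum(low), n_high = sum(!low))
  }))
  if (all(is.na(prof$statistic)))
    stop("no admissible score threshold (no informative split)")
  mx <- max(prof$statistic, na.rm = TRUE)
  best <- which(!is.na(prof$statistic) & prof$statistic >= mx - 1e-12)
  s_star <- prof$s[best[1L]]
  stat <- prof$statistic[best[1L]]
  list(threshold = s_star, statistic = stat,
       p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       profile = prof)
}

#' Evaluate low- versus high-risk score groups
#'
#' Splits patients at a score threshold s* (low: score <= s*, high:
#' score >= s* + 1), estimates a Kaplan-Meier relapse-free survival curve per
#' group, tests separation with the log-rank test, and summarizes the
#' cumulative relapse incidence of each group at 5 and 10 years (60 and 120
#' months). The in-sample log-rank p-value is optimistic whenever s* and the
#' per-gene thresholds were optimized on the same cohort; it is reported as
#' such.
#'
#' @param scores a \code{risk_scores} frame or integer vector aligned with
#'   \code{clinical}.
#' @param s_star score threshold (e.g. from [select_score_threshold()]).
#' @param clinical a [clinical_table()].
#' @param horizon_months times at which cumulative incidence is reported
#'   (default c(60, 120)).
#' @return object of class \code{risk_score_result}: list with \code{s_star},
#'   \code{group} (factor per patient, low/high), \code{n} and \code{events}
#'   (per group), \code{curves} (list of \code{survival_curve}),
#'   \code{logrank} (a [logrank_test()] result), \code{incidence}
#'   (data.frame: group, t, incidence, extrapolated) and \code{scores}.
#' @export
evaluate_risk_groups <- function(scores, s_star, clinical,
                                 horizon_months = c(60, 120)) {
  sid <- NULL
  if (inherits(scores, "risk_scores")) {
    sid <- scores$sample_id
    scores <- scores$score
  }
  if (!is.null(sid)) {
    idx <- match(sid, clinical$sample_id)
    if (anyNA(idx)) stop("score sample(s) missing from clinical table")
    clinical <- clinical[idx, , drop = FALSE]
  } else if (length(scores) != nrow(clinical)) {
    stop("unnamed scores must align with the clinical table")
  }
  group <- factor(ifelse(scores <= s_star, "low", "high"),
                  levels = c("low", "high"))
  if (any(table(group) == 0L))
    stop("both risk groups must be non-empty at s* = ", s_star)
  times <- clinical$rfs_months
  events <- clinical$relapse
  curves <- lapply(split(seq_along(times), group), function(i)
    km_estimate(times[i], events[i]))
  lr <- logrank_test(times, events, group)
  inc <- do.call(rbind, lapply(names(curves), function(gname) {
    sa <- survival_at(curves[[gname]], horizon_months)
    data.frame(group = gname, t = sa$t, incidence = sa$incidence,
               extrapolated = sa$extrapolated, stringsAsFactors = FALSE)
  }))
  structure(list(s_star = s_star, group = group,
                 n = table(group), events = c(tapply(events, group, sum)),
                 curves = curves, logrank = lr, incidence = inc,
                 scores = scores),
            class = "risk_score_result")
}

#' @export
print.risk_score_result <- function(x, ...) {
  cat(sprintf("risk groups at score threshold %d: low n = %d (%d events), high n = %d (%d events)\n",
              x$s_star, x$n["low"], x$events["low"], x$n["high"], x$events["high"]))
  cat(sprintf("log-rank p = %.4g (in-sample, optimistic if thresholds were searched on this cohort)\n",
              x$logrank$p))
  inc <- x$incidence
  for (i in seq_len(nrow(inc)))
    cat(sprintf("  %s-risk relapse rate by %g months: %.1f%%%s\n",
                inc$group[i], inc$t[i], 100 * inc$incidence[i],
                if (inc$extrapolated[i]) " (extrapolated)" else ""))
  invisible(x)
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' alpha = k/(k-1) * (1 - sum(item variances) / variance(item sums)),
#' variances taken over patients. By default items are the signature genes'
#' log2(RQ) values standardized to unit variance (so alpha depends only on
#' the inter-gene correlation structure); set \code{standardize = FALSE} to
#' compute on the values as given.
#'
#' @param items patients x items numeric matrix (or an
#'   \code{expression_matrix} plus \code{genes} to take log2 RQ of a gene
#'   subset).
#' @param genes optional gene subset when \code{items} is an
#'   \code{expression_matrix}.
#' @param standardize scale items to unit variance first (default TRUE).
#' @return alpha (numeric scalar).
#' @export
cronbach_alpha <- function(items, genes = NULL, standardize = TRUE) {
  if (inherits(items, "expression_matrix")) {
    if (is.null(genes)) genes <- items$genes
    items <- t(items$log2rq[genes, , drop = FALSE])
  }
  items <- as.matrix(items)
  if (ncol(items) < 2L) stop("need at least 2 items")
  if (nrow(items) < 2L) stop("need at least 2 patients")
  if (anyNA(items)) {
    keep <- stats::complete.cases(items)
    warning("dropping ", sum(!keep), " patient(s) with missing items")
    items <- items[keep, , drop = FALSE]
  }
  if (standardize) items <- scale(items)
  k <- ncol(items)
  item_var <- apply(items, 2L, stats::var)
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) stop("zero total variance; alpha undefined")
  k / (k - 1) * (1 - sum(item_var) / total_var)
}
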