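#' Kaplan-Meier relapse-free survival curve
#'
#' Product-limit estimate S(t) = prod over event times t_i <= t of
#' (1 - d_i / n_i). At tied times, events precede censorings (the standard
#' product-limit convention): censored subjects at time t are still at risk
#' for events at t. Computed via [survival::survfit()].
#'
#' @param times positive follow-up durations (months).
#' @param events event indicators (0 = censored, 1 = relapse).
#' @return object of class \code{survival_curve}: list with \code{time}
#'   (distinct observed times), \code{n_risk}, \code{n_event},
#'   \code{n_censor}, \code{surv} (step estimates at those times) and
#'   \code{n} (subjects).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input")
  if (any(times <= 0)) stop("all times must be > 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 surv = fit$surv, n = length(times)),
            class = "survival_curve")
}

#' Survival probability and cumulative incidence at a time point
#'
#' Right-continuous step lookup on a [km_estimate()] curve: S(t) is the
#' estimate at the latest observed time <= t, and the cumulative incidence
#' (e.g. the relapse rate by t) is 1 - S(t). Beyond the last observed time
#' the last value is carried forward and flagged as extrapolated.
#'
#' @param curve a \code{survival_curve}.
#' @param t time point(s) >= 0 (months).
#' @return data.frame with columns \code{t}, \code{surv}, \code{incidence},
#'   \code{extrapolated}.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"), all(t >= 0))
  idx <- findInterval(t, curve$time)
  s <- ifelse(idx == 0L, 1, curve$surv[pmax(idx, 1L)])
  data.frame(t = t, surv = s, incidence = 1 - s,
             extrapolated = t > max(curve$time))
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, S(last) = %.3f\n",
              x$n, sum(x$n_event), utils::tail(x$surv, 1L)))
  invisible(x)
}

# Fast two-group log-rank accumulation over risk sets. Kept free of class
# dispatch because the cut-point search calls it once per candidate
# threshold. Returns NULL when there are no events.
.logrank_core <- function(times, events, in1) {
  o <- order(times)
  times <- times[o]; events <- events[o]; in1 <- in1[o]
  n <- length(times)
  nrisk_total <- n - seq_len(n) + 1L           # at risk just before times[i]
  nrisk_1 <- rev(cumsum(rev(in1)))
  et <- unique(times[events == 1L])
  if (length(et) == 0L) return(NULL)
  first <- match(et, times)                     # first index at each tied time
  n_j <- nrisk_total[first]
  n1_j <- nrisk_1[first]
  d_j <- vapply(et, function(t) sum(events == 1L & times == t), integer(1L))
  d1_j <- vapply(et, function(t) sum(events == 1L & times == t & in1),
                 integer(1L))
  E1 <- sum(d_j * n1_j / n_j)
  O1 <- sum(d1_j)
  keep <- n_j > 1L
  V <- sum((d_j * (n1_j / n_j) * (1 - n1_j / n_j) *
              (n_j - d_j) / (n_j - 1))[keep])
  list(O1 = O1, E1 = E1, O2 = sum(d_j) - O1, E2 = sum(d_j) - E1, V = V)
}

#' Two-group Mantel-Haenszel (log-rank) test
#'
#' At each distinct event time the observed events in group 1 are compared
#' with their hypergeometric expectation given the risk sets; the sums give
#' the statistic (O1 - E1)^2 / V, referred to chi-square on 1 degree of
#' freedom. An observed/expected hazard-ratio summary
#' (O1/E1) / (O2/E2) is reported, infinite or undefined when a group has no
#' observed events.
#'
#' @param times positive durations.
#' @param events 0/1 event indicators.
#' @param group two-level grouping vector (factor, character or logical).
#' @return object of class \code{logrank_result}: list with \code{observed}
#'   and \code{expected} (length-2, named by group), \code{variance},
#'   \code{statistic}, \code{df} (1), \code{p}, \code{hazard_ratio}
#'   (group 2 vs group 1 by O/E), \code{groups}.
#' @export
logrank_test <- function(times, events, group) {
  if (any(times <= 0)) stop("all times must be > 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  group <- as.factor(as.vector(group))
  group <- droplevels(group)
  if (nlevels(group) != 2L)
    stop("log-rank test requires exactly 2 non-empty groups (got ",
         nlevels(group), ")")
  core <- .logrank_core(times, as.integer(events), group == levels(group)[1L])
  if (is.null(core)) stop("no events observed; log-rank statistic undefined")
  stat <- if (core$V > 0) (core$O1 - core$E1)^2 / core$V else 0
  oe1 <- core$O1 / core$E1
  oe2 <- core$O2 / core$E2
  hr <- oe2 / oe1                      # group 2 vs group 1
  structure(list(
    observed = stats::setNames(c(core$O1, core$O2), levels(group)),
    expected = stats::setNames(c(core$E1, core$E2), levels(group)),
    variance = core$V, statistic = stat, df = 1L,
    p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
    hazard_ratio = hr, groups = levels(group)),
    class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank (Mantel-Haenszel): chi-square = %.4g on 1 df, p = %.4g\n",
              x$statistic, x$p))
  cat(sprintf("  %s: O = %g, E = %.3g | %s: O = %g, E = %.3g | O/E HR (%s vs %s) = %.3g\n",
              x$groups[1L], x$observed[1L], x$expected[1L],
              x$groups[2L], x$observed[2L], x$expected[2L],
              x$groups[2L], x$groups[1L], x$hazard_ratio))
  invisible(x)
}

#' Plot Kaplan-Meier curves for one or more groups
#'
#' @param x a \code{survival_curve} or a named list of them.
#' @param col line colors.
#' @param xlab,ylab axis labels.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, \code{x}.
#' @export
plot.survival_curve <- function(x, col = "black",
                                xlab = "months", ylab = "relapse-free survival",
                                ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 verticals = FALSE, ylim = c(0, 1), col = col,
                 xlab = xlab, ylab = ylab, ...)
  cens <- x$time[x$n_censor > 0]
  if (length(cens) > 0L) {
    s_at <- survival_at(x, cens)$surv
    graphics::points(cens, s_at, pch = 3, col = col)
  }
  invisible(x)
}
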