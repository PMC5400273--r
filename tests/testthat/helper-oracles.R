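# Independent brute-force oracles. These deliberately share no code with the
# package internals: everything is computed by explicit enumeration.

# product-limit estimate at each distinct observed time, events before
# censorings at ties
oracle_km <- function(times, events) {
  ts <- sort(unique(times))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    t <- ts[i]
    at_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    if (d > 0) s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# two-group log-rank by explicit risk-table enumeration at every distinct
# event time; returns O1, E1, V and the chi-square statistic
oracle_logrank <- function(times, events, in1) {
  et <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t in et) {
    at <- times >= t
    n <- sum(at)
    n1 <- sum(at & in1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & in1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(O1 = O1, E1 = E1, V = V,
       statistic = if (V > 0) (O1 - E1)^2 / V else 0)
}

# exhaustive cut-point search over midpoints of consecutive distinct values,
# using the enumeration log-rank above; same tie-breaking contract
# (max statistic, then balance, then smaller tau)
oracle_cutpoint <- function(values, times, events, min_frac = 0.1) {
  v <- sort(unique(values))
  taus <- (v[-length(v)] + v[-1]) / 2
  n <- length(values)
  min_n <- ceiling(min_frac * n)
  best <- NULL
  for (tau in taus) {
    high <- values > tau
    if (sum(high) < min_n || sum(!high) < min_n) next
    stat <- oracle_logrank(times, events, high)$statistic
    bal <- abs(sum(high) - sum(!high))
    cand <- c(stat = stat, bal = bal, tau = tau)
    if (is.null(best) ||
        stat > best["stat"] + 1e-12 ||
        (abs(stat - best["stat"]) <= 1e-12 &&
         (bal < best["bal"] ||
          (bal == best["bal"] && tau < best["tau"])))) {
      best <- cand
    }
  }
  best
}

# Pearson chi-square by the definition sum (O-E)^2 / E
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Cronbach's alpha from an explicitly computed covariance matrix
oracle_cronbach <- function(items) {
  k <- ncol(items)
  C <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    C[i, j] <- sum((items[, i] - mean(items[, i])) *
                     (items[, j] - mean(items[, j]))) / (nrow(items) - 1)
  k / (k - 1) * (1 - sum(diag(C)) / sum(C))
}

# naive Ward agglomeration by the barycenter definition: at each step merge
# the pair of clusters whose union minimally increases the within-cluster
# sum of squares; records sqrt(2 * delta-SS) merge heights
oracle_ward_heights <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), function(i) i)
  heights <- numeric(0)
  ss <- function(idx) {
    c0 <- colMeans(X[idx, , drop = FALSE])
    sum(sweep(X[idx, , drop = FALSE], 2, c0)^2)
  }
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        dss <- ss(c(clusters[[i]], clusters[[j]])) -
          ss(clusters[[i]]) - ss(clusters[[j]])
        if (dss < best[1]) best <- c(dss, i, j)
      }
    }
    heights <- c(heights, sqrt(2 * best[1]))
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}
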