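test_that("signed fold matches the two-fold anchors and is antisymmetric", {
  expect_identical(signed_fold(2), 1)
  expect_identical(signed_fold(0.5), -1)
  expect_identical(signed_fold(1), 0)
  expect_error(signed_fold(0), "> 0")
  expect_error(signed_fold(-2), "> 0")
  set.seed(10)
  r <- exp(rnorm(200))
  expect_equal(signed_fold(r), -signed_fold(1 / r), tolerance = 1e-12)
})

# build a tiny quantified two-group dataset with an optional planted Ct shift
planted_comparison <- function(n_per = 100, shift = 1, seed = 21,
                               grouping = "relapse") {
  set.seed(seed)
  n <- 2 * n_per
  genes <- c("EPO", "ETS1", "ENO1")
  ct <- rbind(
    RPL32 = rnorm(n, 20, 0.2), `18S` = rnorm(n, 12, 0.2),
    EPO = rnorm(n, 26, 1), ETS1 = rnorm(n, 27, 1), ENO1 = rnorm(n, 25, 1))
  case <- c(rep(FALSE, n_per), rep(TRUE, n_per))
  ct["EPO", case] <- ct["EPO", case] - shift   # lower Ct = up-regulated
  colnames(ct) <- sprintf("S%03d", 1:n)
  clin <- data.frame(
    sample_id = colnames(ct), age_group = ">=50", er = "pos", pr = "pos",
    nodes = "neg", stage = ifelse(case, 2, 1),
    grade_msbr = ifelse(case, 4, 2), her2 = ifelse(case, "pos", "neg"),
    relapse = as.integer(case), rfs_months = 60, stringsAsFactors = FALSE)
  coh <- assemble_cohort(ct_matrix(ct), clinical_table(clin), small_panel())
  q <- quantify_cohort(coh)
  compare_groups(q$rq, q$dct, coh$clinical, grouping)
}

test_that("a planted 1-cycle shift is recovered as a 2-fold induction", {
  cmp <- planted_comparison(n_per = 100, shift = 1, seed = 21)
  row <- cmp[cmp$gene == "EPO", ]
  # the ratio of arithmetic mean RQs is a noisy (right-skewed) estimator of
  # the planted 2-fold effect; bound it rather than pin it
  expect_gt(row$ratio, 1.4); expect_lt(row$ratio, 2.9)
  expect_gt(row$fold, 0.4); expect_lt(row$fold, 1.9)
  expect_lt(row$p, 0.01)
  # unshifted genes stay near fold 0
  expect_lt(max(abs(cmp$fold[cmp$gene != "EPO"])), 0.5)
})

test_that("identical groups give zero folds and p of 1", {
  set.seed(33)
  half <- matrix(rnorm(5 * 10, c(20, 12, 26, 27, 25), 1), 5, 10,
                 dimnames = list(c("RPL32", "18S", "EPO", "ETS1", "ENO1"),
                                 NULL))
  ct <- cbind(half, half)
  colnames(ct) <- sprintf("S%03d", 1:20)
  clin <- toy_clinical(20, relapse = rep(0:1, each = 10), rfs = rep(50, 20))
  clin$sample_id <- colnames(ct)
  clin <- clinical_table(as.data.frame(clin))
  coh <- assemble_cohort(ct_matrix(ct), clin, small_panel())
  q <- quantify_cohort(coh)
  cmp <- compare_groups(q$rq, q$dct, coh$clinical, "relapse")
  expect_equal(cmp$fold, rep(0, 3), tolerance = 1e-12)
  expect_equal(cmp$p_kw, rep(1, 3), tolerance = 1e-12)
  expect_true(all(cmp$p > 0.99))
})

test_that("the rank-test branch equals the hand-computed chi-square on a toy", {
  # 6 observations, two groups of 3, no ties: H = 12/(N(N+1)) sum R_g^2/n_g - 3(N+1)
  x <- c(1.2, 3.4, 2.2)   # ranks 1, 3, 2 -> wait, against group 2 below
  y <- c(5.1, 8.0, 6.6)
  ranks <- rank(c(x, y))
  H <- 12 / (6 * 7) * (sum(ranks[1:3])^2 / 3 + sum(ranks[4:6])^2 / 3) - 3 * 7
  p_hand <- pchisq(H, df = 1, lower.tail = FALSE)
  expect_equal(kruskal.test(list(x, y))$p.value, p_hand, tolerance = 1e-12)
  # and compare_groups reports exactly this rank-test p for the gene
  ct <- rbind(RPL32 = rep(20, 6), `18S` = rep(12, 6),
              EPO = 26 - log2(c(x, y)))          # RQ ordered like x, y
  colnames(ct) <- sprintf("S%02d", 1:6)
  clin <- toy_clinical(6, relapse = rep(0:1, each = 3), rfs = rep(10, 6))
  clin <- clinical_table(as.data.frame(clin))
  coh <- assemble_cohort(ct_matrix(ct), clin, small_panel())
  q <- quantify_cohort(coh)
  cmp <- compare_groups(q$rq, q$dct, coh$clinical, "relapse")
  expect_equal(cmp$p_kw[cmp$gene == "EPO"], p_hand, tolerance = 1e-12)
})

test_that("swapping case and control negates folds and keeps p-values", {
  cmp1 <- planted_comparison(n_per = 30, shift = 0.8, seed = 5,
                             grouping = "relapse")
  # rebuild with inverted case labels by flipping the relapse indicator
  set.seed(5)
  n <- 60
  ct <- rbind(
    RPL32 = rnorm(n, 20, 0.2), `18S` = rnorm(n, 12, 0.2),
    EPO = rnorm(n, 26, 1), ETS1 = rnorm(n, 27, 1), ENO1 = rnorm(n, 25, 1))
  case <- c(rep(FALSE, 30), rep(TRUE, 30))
  ct["EPO", case] <- ct["EPO", case] - 0.8
  colnames(ct) <- sprintf("S%03d", 1:n)
  clin <- data.frame(
    sample_id = colnames(ct), age_group = ">=50", er = "pos", pr = "pos",
    nodes = "neg", stage = ifelse(case, 2, 1),
    grade_msbr = ifelse(case, 4, 2), her2 = ifelse(case, "pos", "neg"),
    relapse = as.integer(!case), rfs_months = 60, stringsAsFactors = FALSE)
  coh <- assemble_cohort(ct_matrix(ct), clinical_table(clin), small_panel())
  q <- quantify_cohort(coh)
  cmp2 <- compare_groups(q$rq, q$dct, coh$clinical, "relapse")
  m1 <- cmp1[order(cmp1$gene), ]
  m2 <- cmp2[order(cmp2$gene), ]
  expect_equal(m2$fold, -m1$fold, tolerance = 1e-10)
  expect_equal(m2$p, m1$p, tolerance = 1e-10)
})

test_that("the rank test is invariant to monotone transforms of expression", {
  cmp <- planted_comparison(n_per = 20, shift = 1, seed = 8)
  # same data, RQ cubed (monotone): rebuild rq by transforming log2rq
  set.seed(8)
  n <- 40
  ct <- rbind(
    RPL32 = rnorm(n, 20, 0.2), `18S` = rnorm(n, 12, 0.2),
    EPO = rnorm(n, 26, 1), ETS1 = rnorm(n, 27, 1), ENO1 = rnorm(n, 25, 1))
  case <- c(rep(FALSE, 20), rep(TRUE, 20))
  ct["EPO", case] <- ct["EPO", case] - 1
  colnames(ct) <- sprintf("S%03d", 1:n)
  clin <- data.frame(
    sample_id = colnames(ct), age_group = ">=50", er = "pos", pr = "pos",
    nodes = "neg", stage = ifelse(case, 2, 1),
    grade_msbr = ifelse(case, 4, 2), her2 = ifelse(case, "pos", "neg"),
    relapse = as.integer(case), rfs_months = 60, stringsAsFactors = FALSE)
  coh <- assemble_cohort(ct_matrix(ct), clinical_table(clin), small_panel())
  q <- quantify_cohort(coh)
  q$rq$rq <- q$rq$rq^3
  cmp3 <- compare_groups(q$rq, q$dct, coh$clinical, "relapse")
  expect_equal(cmp3$p_kw[order(cmp3$gene)], cmp$p_kw[order(cmp$gene)],
               tolerance = 1e-12)
})

test_that("average overexpression summarizes the ratio profile", {
  cmp <- planted_comparison(n_per = 50, shift = 1, seed = 13)
  expect_equal(attr(cmp, "avg_overexpression_pct"),
               100 * mean(cmp$ratio - 1), tolerance = 1e-12)
  expect_equal(attr(cmp, "mean_fold"), mean(cmp$fold), tolerance = 1e-12)
  # output is ordered by fold for profile plotting
  expect_false(is.unsorted(cmp$fold))
})

test_that("tiny groups skip tests with a warning but report folds", {
  cmpw <- NULL
  set.seed(2)
  ct <- rbind(RPL32 = rnorm(5, 20, 0.2), `18S` = rnorm(5, 12, 0.2),
              EPO = rnorm(5, 26, 1))
  colnames(ct) <- sprintf("S%02d", 1:5)
  clin <- toy_clinical(5, relapse = c(1, 0, 0, 0, 0), rfs = rep(10, 5))
  clin <- clinical_table(as.data.frame(clin))
  coh <- assemble_cohort(ct_matrix(ct), clin, small_panel())
  q <- quantify_cohort(coh)
  expect_warning(cmpw <- compare_groups(q$rq, q$dct, coh$clinical, "relapse"),
                 "fewer than 2")
  expect_true(all(is.na(cmpw$p)))
  expect_true(all(is.finite(cmpw$fold)))
})
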