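# Fixtures built in code at test time.

# minimal 2-reference / k-target Ct matrix with Gaussian noise
toy_ct_matrix <- function(n = 10, genes = c("EPO", "LDHA", "ENO1"),
                          base = 26, sd = 1, seed = 42) {
  set.seed(seed)
  all_genes <- c("RPL32", "18S", genes)
  ct <- rbind(
    matrix(rnorm(2 * n, mean = c(20, 12), sd = 0.2), 2, n),
    matrix(rnorm(length(genes) * n, mean = base, sd = sd), length(genes), n))
  dimnames(ct) <- list(all_genes, sprintf("S%02d", seq_len(n)))
  ct_matrix(ct)
}

# clinical table with arbitrary but valid covariates
toy_clinical <- function(n = 10, relapse = rep(0:1, length.out = n),
                         rfs = seq(10, 10 * n, by = 10), seed = 42) {
  set.seed(seed)
  clinical_table(data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    age_group = sample(c("<50", ">=50"), n, replace = TRUE),
    er = sample(c("neg", "pos"), n, replace = TRUE),
    pr = sample(c("neg", "pos"), n, replace = TRUE),
    nodes = sample(c("neg", "pos"), n, replace = TRUE),
    stage = sample(1:3, n, replace = TRUE),
    grade_msbr = sample(1:5, n, replace = TRUE),
    her2 = sample(c("neg", "pos"), n, replace = TRUE),
    relapse = relapse,
    rfs_months = rfs,
    stringsAsFactors = FALSE))
}

# deterministic 32-row clinical table reproducing the reference cohort's
# marginal category counts
cohort32_clinical <- function() {
  rep_each <- function(vals, counts) rep(vals, counts)
  clinical_table(data.frame(
    sample_id = sprintf("P%02d", 1:32),
    age_group = rep_each(c("<50", ">=50"), c(8, 24)),
    er = rep_each(c("neg", "pos"), c(1, 31)),
    pr = rep_each(c("neg", "pos"), c(8, 24)),
    nodes = rep_each(c("neg", "pos"), c(20, 12)),
    stage = rep_each(c(1, 2, 3), c(7, 24, 1)),
    grade_msbr = rep_each(c(1, 2, 3, 4, 5), c(9, 8, 8, 5, 2)),
    her2 = rep_each(c("neg", "pos"), c(27, 5)),
    relapse = rep_each(c(0, 1), c(18, 14)),
    rfs_months = c(seq(60, 145, length.out = 18), seq(12, 110, length.out = 14)),
    stringsAsFactors = FALSE))
}

# small panel for fast simulations: 2 references + 6 signature genes + 2 more
small_panel <- function() {
  gene_panel(data.frame(
    gene = c("18S", "RPL32", "EPO", "ETS1", "ENO1", "PGK1", "LDHA", "TPI",
             "PTEN", "VIM"),
    assay_id = paste0("A", 1:10),
    category = "test",
    is_reference = c(1, 1, rep(0, 8))))
}

small_baseline <- function(panel = small_panel()) {
  b <- stats::setNames(rep(26, nrow(panel)), panel$gene)
  b["18S"] <- 12; b["RPL32"] <- 20
  b
}

# quantify a simulated cohort with the default housekeeping route
quantify_cohort <- function(cohort, cutoff = 35) {
  ct <- apply_detection_cutoff(cohort$ct, cutoff)
  refs <- select_references("housekeeping", panel = cohort$panel,
                            available = ct$genes)
  dct <- compute_delta_ct(ct, refs)
  rq <- compute_rq(dct, "cohort_mean")
  list(dct = dct, rq = rq)
}
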