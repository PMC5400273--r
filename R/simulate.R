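#' Marginal covariate frequencies of the reference cohort
#'
#' Category counts of the 32-patient early-stage invasive ductal carcinoma
#' cohort the simulator emulates: age < 50 / >= 50 (8/24), estrogen receptor
#' neg/pos (1/31), progesterone receptor neg/pos (8/24), lymph nodes neg/pos
#' (20/12), tumor stage 1 vs 2-3 (7/25, with a single stage-3 patient),
#' mSBR grade 1-3 vs 4-5 (25/7), HER2 neg/pos (27/5) and recurrence no/yes
#' (18/14). Stage and grade are returned per level; the within-dichotomy
#' allocation of grades (9/8/8 across 1-3 and 5/2 across 4-5) is a simulator
#' convention, only the dichotomous margins being fixed.
#'
#' @return named list of named integer count vectors: \code{age}, \code{er},
#'   \code{pr}, \code{nodes}, \code{stage}, \code{grade}, \code{her2},
#'   \code{recurrence}.
#' @export
frequencies_from_table1 <- function() {
  list(
    age = c("<50" = 8L, ">=50" = 24L),
    er = c(neg = 1L, pos = 31L),
    pr = c(neg = 8L, pos = 24L),
    nodes = c(neg = 20L, pos = 12L),
    stage = c("1" = 7L, "2" = 24L, "3" = 1L),
    grade = c("1" = 9L, "2" = 8L, "3" = 8L, "4" = 5L, "5" = 2L),
    her2 = c(neg = 27L, pos = 5L),
    recurrence = c(no = 18L, yes = 14L)
  )
}

#' Default baseline Ct levels for the packaged panel
#'
#' Mean threshold-cycle per gene in a typical tumor sample: the ribosomal
#' controls amplify early (18S around cycle 12, RPL32 around 20); target
#' transcripts span cycles 22-31; LEP, a low-abundance adipokine transcript,
#' sits at cycle 34 so that a realistic fraction of its wells falls beyond
#' the detection cutoff of 35.
#'
#' @param panel a [gene_panel()].
#' @return named numeric vector of baseline mean Ct per panel gene.
#' @export
default_baseline_ct <- function(panel = default_gene_panel()) {
  base <- stats::setNames(numeric(nrow(panel)), panel$gene)
  base["18S"] <- 12
  base["RPL32"] <- 20
  tg <- target_genes(panel)
  base[tg] <- seq(22, 31, length.out = length(tg))
  if ("LEP" %in% tg) base["LEP"] <- 34
  base
}

#' Simulation configuration
#'
#' Defines the statistical structure of a synthetic qPCR cohort. Expression
#' is simulated on the Ct (log2) scale, so relative quantification is
#' log-normal: each well gets
#' \code{Ct(g, s) = baseline_ct[g] + offset[s] - e(g, s)} where
#' \code{offset[s]} is a per-sample loading offset (cancelled by delta-Ct
#' normalization) and \code{e(g, s) ~ Normal(shift(g, s), sd)} is log2
#' expression; positive group shifts mean up-regulation (lower Ct).
#' Reference genes have small noise (\code{reference_sd}) and no group
#' shifts. Relapse times follow an exponential proportional-hazards model:
#' the hazard is \code{hazard_rate * exp(lp)} per month, where in
#' \code{"linear"} mode \code{lp} sums \code{hazard_coef[g] * z(g, s)} over
#' signature genes (z = cohort-centered log2 expression) and in
#' \code{"threshold"} mode it sums \code{hazard_coef[g] * 1[z(g, s) >
#' threshold_log2rq]}, a planted step effect at a known cut on the log2-RQ
#' scale (\code{threshold_log2rq = 1} corresponds to RQ = 2 versus the
#' cohort mean). Censoring combines an administrative horizon with an
#' independent exponential censoring rate. Clinical covariates are drawn to
#' match the configured marginal counts, independently of expression except
#' through \code{group_effects}.
#'
#' Defaults reproduce the reference study conditions: 32 patients, the
#' packaged 47-assay panel, per-gene noise of 1.5 cycles, a +0.5-cycle
#' up-shift of all target genes in high-grade tumors, a +3.7-cycle HER2
#' up-shift in HER2+ tumors, hazard coefficients of 0.35 per signature gene
#' on centered log2 expression, baseline hazard 0.0037/month, a 150-month
#' horizon with 0.002/month independent censoring (together giving roughly
#' the 14/32 observed event fraction), and detection cutoff 35.
#'
#' @param n_patients cohort size (default 32).
#' @param panel a [gene_panel()].
#' @param baseline_ct named vector of per-gene mean Ct.
#' @param target_sd,reference_sd noise (cycles) for target/reference genes.
#' @param sample_offset_sd sd (cycles) of the per-sample loading offset.
#' @param group_effects list of \code{list(covariate, level, genes, shift)};
#'   \code{genes} may be \code{"targets"} for all non-reference genes.
#' @param signature signature gene symbols driving the hazard.
#' @param hazard_coef per-gene log-hazard coefficient(s), recycled over the
#'   signature.
#' @param hazard_rate baseline hazard (events/month), > 0.
#' @param hazard_mode \code{"linear"} or \code{"threshold"}.
#' @param threshold_log2rq planted cut on centered log2 expression
#'   (threshold mode).
#' @param horizon_months administrative censoring horizon (> 0).
#' @param censor_rate independent exponential censoring rate (/month).
#' @param frequencies covariate counts as in [frequencies_from_table1()];
#'   rescaled to \code{n_patients}.
#' @param dropout_ct_threshold detection cutoff recorded in the config
#'   (applied downstream, not by the generator).
#' @param seed integer RNG seed.
#' @return object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_patients = 32,
                       panel = default_gene_panel(),
                       baseline_ct = default_baseline_ct(panel),
                       target_sd = 1.5,
                       reference_sd = 0.2,
                       sample_offset_sd = 0.5,
                       group_effects = list(
                         list(covariate = "grade", level = "high",
                              genes = "targets", shift = 0.5),
                         list(covariate = "her2", level = "pos",
                              genes = "HER2", shift = 3.7)),
                       signature = signature_genes(),
                       hazard_coef = 0.35,
                       hazard_rate = 0.0037,
                       hazard_mode = c("linear", "threshold"),
                       threshold_log2rq = 1,
                       horizon_months = 150,
                       censor_rate = 0.002,
                       frequencies = frequencies_from_table1(),
                       dropout_ct_threshold = 35,
                       seed = 1L) {
  hazard_mode <- match.arg(hazard_mode)
  stopifnot(n_patients >= 2, target_sd > 0, reference_sd > 0,
            sample_offset_sd >= 0, hazard_rate > 0, horizon_months > 0,
            censor_rate >= 0, dropout_ct_threshold > 0)
  miss <- setdiff(panel$gene, names(baseline_ct))
  if (length(miss) > 0L)
    stop("baseline_ct missing gene(s): ", paste(miss, collapse = ", "))
  if (length(setdiff(signature, panel$gene)) > 0L)
    stop("signature gene(s) not on the panel: ",
         paste(setdiff(signature, panel$gene), collapse = ", "))
  hazard_coef <- stats::setNames(rep_len(hazard_coef, length(signature)),
                                 signature)
  structure(list(
    n_patients = as.integer(n_patients), panel = panel,
    baseline_ct = baseline_ct, target_sd = target_sd,
    reference_sd = reference_sd, sample_offset_sd = sample_offset_sd,
    group_effects = group_effects, signature = signature,
    hazard_coef = hazard_coef, hazard_rate = hazard_rate,
    hazard_mode = hazard_mode, threshold_log2rq = threshold_log2rq,
    horizon_months = horizon_months, censor_rate = censor_rate,
    frequencies = frequencies,
    dropout_ct_threshold = dropout_ct_threshold,
    seed = as.integer(seed)), class = "sim_config")
}

# rescale integer category counts to a new total, largest-remainder rounding
.rescale_counts <- function(counts, n) {
  x <- counts / sum(counts) * n
  f <- floor(x)
  rem <- n - sum(f)
  if (rem > 0) {
    extra <- order(x - f, decreasing = TRUE)[seq_len(rem)]
    f[extra] <- f[extra] + 1
  }
  # every level the source deems present should survive if n allows
  stats::setNames(as.integer(f), names(counts))
}

.sample_covariate <- function(counts, n) {
  counts <- .rescale_counts(counts, n)
  sample(rep(names(counts), counts))
}

#' Simulate a synthetic qPCR cohort with ground truth
#'
#' Draws a full cohort (Ct matrix, clinical table, panel) from a
#' [sim_config()] together with the ground truth needed for parameter
#' recovery tests: per-patient linear predictors, planted signature and
#' shifts, latent event and censoring times, and (in threshold mode) the
#' planted per-gene indicators. Identical config and seed give a
#' bit-identical cohort.
#'
#' @param config a [sim_config()].
#' @return list with \code{cohort} (a [assemble_cohort()] dataset) and
#'   \code{truth} (list: \code{lp}, \code{signature}, \code{shift} matrix,
#'   \code{event_time}, \code{censor_time}, \code{indicators} or NULL,
#'   \code{expression} (the latent log2 expression matrix)).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  panel <- config$panel
  genes <- panel$gene
  ids <- sprintf("P%03d", seq_len(n))

  fr <- config$frequencies
  stage <- .sample_covariate(fr$stage, n)
  grade <- .sample_covariate(fr$grade, n)
  clin <- data.frame(
    sample_id = ids,
    age_group = .sample_covariate(fr$age, n),
    er = .sample_covariate(fr$er, n),
    pr = .sample_covariate(fr$pr, n),
    nodes = .sample_covariate(fr$nodes, n),
    stage = as.integer(stage),
    grade_msbr = as.integer(grade),
    her2 = .sample_covariate(fr$her2, n),
    relapse = 0L, rfs_months = 1,
    stringsAsFactors = FALSE)

  # group shifts on log2 expression (positive = up-regulated, lower Ct)
  shift <- matrix(0, length(genes), n, dimnames = list(genes, ids))
  for (ef in config$group_effects) {
    in_level <- switch(ef$covariate,
      grade = (clin$grade_msbr >= 4) == (ef$level == "high"),
      stage = (clin$stage >= 2) == (ef$level %in% c("2-3", "high")),
      her2 = clin$her2 == ef$level,
      er = clin$er == ef$level,
      pr = clin$pr == ef$level,
      nodes = clin$nodes == ef$level,
      age = clin$age_group == ef$level,
      stop("unknown covariate in group_effects: ", ef$covariate))
    gset <- if (identical(ef$genes, "targets")) target_genes(panel) else ef$genes
    shift[gset, in_level] <- shift[gset, in_level] + ef$shift
  }

  sds <- ifelse(panel$is_reference, config$reference_sd, config$target_sd)
  expr <- shift + matrix(stats::rnorm(length(genes) * n, sd = rep(sds, n)),
                         length(genes), n)
  dimnames(expr) <- list(genes, ids)
  offset <- stats::rnorm(n, sd = config$sample_offset_sd)
  ct <- config$baseline_ct[genes] + matrix(offset, length(genes), n,
                                           byrow = TRUE) - expr
  dimnames(ct) <- list(genes, ids)

  z <- expr[config$signature, , drop = FALSE]
  z <- z - rowMeans(z)
  indicators <- NULL
  if (config$hazard_mode == "threshold") {
    indicators <- (z > config$threshold_log2rq) * 1L
    lp <- as.vector(config$hazard_coef %*% indicators)
  } else {
    lp <- as.vector(config$hazard_coef %*% z)
  }
  names(lp) <- ids
  event_time <- stats::rexp(n, rate = config$hazard_rate * exp(lp))
  censor_time <- if (config$censor_rate > 0)
    pmin(config$horizon_months, stats::rexp(n, rate = config$censor_rate))
  else rep(config$horizon_months, n)
  rfs <- pmin(event_time, censor_time)
  if (all(rfs <= 0)) stop("degenerate configuration: all follow-up times are 0")
  clin$relapse <- as.integer(event_time <= censor_time)
  clin$rfs_months <- rfs

  cohort <- assemble_cohort(ct_matrix(ct), clinical_table(clin), panel)
  truth <- list(lp = lp, signature = config$signature, shift = shift,
                event_time = event_time, censor_time = censor_time,
                indicators = indicators, expression = expr)
  list(cohort = cohort, truth = truth)
}

#' Write a simulated cohort to plain-text files
#'
#' Writes \code{ct.csv} (wide Ct table), \code{clinical.csv} and
#' \code{truth.json} into a directory.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ct_table(sim$cohort$ct, file.path(dir, "ct.csv"))
  write_clinical_table(sim$cohort$clinical, file.path(dir, "clinical.csv"))
  truth <- sim$truth
  truth$shift <- NULL
  truth$expression <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
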