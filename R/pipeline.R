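#' Pipeline configuration
#'
#' Bundles every stage option of the full analysis into one validated object.
#' Exactly one input mode must be given: file paths (\code{ct_path},
#' \code{clinical_path}) or a simulation block (\code{simulate}, a
#' [sim_config()]).
#'
#' @param ct_path,clinical_path input files ([read_ct_table()] /
#'   [read_clinical_table()] formats).
#' @param simulate a [sim_config()] to generate the cohort instead.
#' @param panel a [gene_panel()].
#' @param normalization \code{"housekeeping"}, \code{"normfinder"} (the k
#'   most stable genes) or \code{"global_mean"}.
#' @param cutoff detection cutoff in cycles.
#' @param calibrator \code{"cohort_mean"} or a sample id.
#' @param groupings clinical dichotomies to profile.
#' @param cluster_k_all,cluster_k_signature patient cluster counts for the
#'   full-panel and signature clusterings.
#' @param thresholds \code{"search"} or \code{"published"}.
#' @param min_frac minimum group fraction per side of a cut.
#' @param score_threshold \code{"auto"} (log-rank optimized) or an integer.
#' @param signature_alpha selection level for the relapse signature.
#' @param out_dir output directory, or \code{NULL} for no files.
#' @param seed integer seed (controls the simulate block).
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(ct_path = NULL, clinical_path = NULL,
                            simulate = NULL, panel = default_gene_panel(),
                            normalization = c("housekeeping", "normfinder",
                                              "global_mean"),
                            cutoff = 35, calibrator = "cohort_mean",
                            groupings = c("stage", "grade", "her2", "relapse"),
                            cluster_k_all = 2, cluster_k_signature = 3,
                            thresholds = c("search", "published"),
                            min_frac = 0.1, score_threshold = "auto",
                            signature_alpha = 0.05,
                            out_dir = NULL, seed = 1L) {
  normalization <- match.arg(normalization)
  thresholds <- match.arg(thresholds)
  has_files <- !is.null(ct_path) && !is.null(clinical_path)
  has_sim <- !is.null(simulate)
  if (has_files == has_sim)
    stop("exactly one of (ct_path + clinical_path) or simulate must be given")
  if (has_sim) {
    stopifnot(inherits(simulate, "sim_config"))
    simulate$seed <- as.integer(seed)
  }
  structure(list(ct_path = ct_path, clinical_path = clinical_path,
                 simulate = simulate, panel = panel,
                 normalization = normalization, cutoff = cutoff,
                 calibrator = calibrator, groupings = groupings,
                 cluster_k_all = cluster_k_all,
                 cluster_k_signature = cluster_k_signature,
                 thresholds = thresholds, min_frac = min_frac,
                 score_threshold = score_threshold,
                 signature_alpha = signature_alpha,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full relapse risk-score pipeline
#'
#' Executes quantification (detection cutoff, normalization, delta-Ct, RQ),
#' group-wise fold-induction profiles, hierarchical clustering (full panel
#' and signature) with cluster-relapse association, signature selection,
#' per-gene threshold optimization, risk scoring and risk-group survival
#' evaluation. With an output directory, writes \code{delta_ct.csv},
#' \code{rq.csv}, per-grouping \code{diffexp_<grouping>.tsv},
#' \code{cluster_labels.csv}, \code{thresholds.csv}, \code{scores.csv} and a
#' machine-readable \code{summary.json}. Identical config and seed give an
#' identical bundle.
#'
#' @param config a [pipeline_config()].
#' @return object of class \code{pipeline_result}: list with \code{cohort},
#'   \code{dct}, \code{rq}, \code{stability}, \code{comparisons} (per
#'   grouping), \code{cluster_all}, \code{cluster_signature},
#'   \code{cluster_assoc}, \code{signature}, \code{thresholds},
#'   \code{scores}, \code{score_threshold}, \code{risk}, \code{alpha}
#'   (Cronbach) and \code{summary} (the list written to summary.json).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- .stage("input", {
    if (!is.null(config$simulate)) {
      simulate_cohort(config$simulate)$cohort
    } else {
      assemble_cohort(read_ct_table(config$ct_path),
                      read_clinical_table(config$clinical_path),
                      config$panel)
    }
  })
  ct <- .stage("cutoff", apply_detection_cutoff(cohort$ct, config$cutoff))
  stab <- .stage("stability",
                 stability_ranking(ct, groups = clinical_grouping(
                   cohort$clinical, "relapse")))
  refs <- .stage("references", switch(config$normalization,
    housekeeping = select_references("housekeeping", panel = cohort$panel,
                                     available = ct$genes),
    normfinder = select_references("stability_top_k", ranking = stab, k = 2),
    global_mean = select_references("global_mean")))
  dct <- .stage("delta_ct", compute_delta_ct(ct, refs))
  rq <- .stage("rq", compute_rq(dct, config$calibrator))

  comparisons <- .stage("diffexp", {
    out <- lapply(config$groupings, function(g)
      compare_groups(rq, dct, cohort$clinical, g))
    names(out) <- config$groupings
    out
  })

  cl_all <- .stage("cluster_all",
                   hierarchical_cluster(dct, k = config$cluster_k_all))
  assoc_all <- .stage("cluster_assoc",
                      cluster_relapse_association(cl_all, cohort$clinical))

  sig <- .stage("signature", {
    if ("relapse" %in% names(comparisons))
      select_signature(comparisons$relapse, alpha = config$signature_alpha)
    else signature_genes()
  })
  cl_sig <- .stage("cluster_signature", {
    k <- min(config$cluster_k_signature, length(dct$samples))
    hierarchical_cluster(dct, genes = sig, k = k)
  })

  thr <- .stage("thresholds",
                build_threshold_table(rq, sig, cohort$clinical,
                                      mode = config$thresholds,
                                      min_frac = config$min_frac))
  scores <- .stage("scores", compute_scores(rq, thr))
  sthr <- .stage("score_threshold", {
    if (identical(config$score_threshold, "auto"))
      select_score_threshold(scores, cohort$clinical$rfs_months,
                             cohort$clinical$relapse)
    else list(threshold = as.integer(config$score_threshold),
              statistic = NA_real_, p = NA_real_, profile = NULL)
  })
  risk <- .stage("risk_groups",
                 evaluate_risk_groups(scores, sthr$threshold, cohort$clinical))
  alpha <- .stage("cronbach",
                  tryCatch(cronbach_alpha(rq, genes = sig),
                           error = function(e) NA_real_))

  summary <- list(
    n_patients = length(cohort$ct$samples),
    n_genes = length(cohort$ct$genes),
    n_events = sum(cohort$clinical$relapse),
    normalization = config$normalization,
    reference_genes = if (is.null(refs$genes)) "global_mean"
                      else paste(refs$genes, collapse = ","),
    signature = sig,
    thresholds = stats::setNames(thr$threshold, thr$gene),
    score_threshold = sthr$threshold,
    group_sizes = as.list(stats::setNames(as.integer(risk$n), names(risk$n))),
    group_events = as.list(stats::setNames(as.integer(risk$events),
                                           names(risk$events))),
    logrank_p = risk$logrank$p,
    oe_hazard_ratio = risk$logrank$hazard_ratio,
    incidence = risk$incidence,
    cronbach_alpha = alpha,
    cluster_relapse_p = assoc_all$p,
    cluster_relapse_prop = as.list(as.numeric(assoc_all$relapse_prop)),
    avg_overexpression_pct = vapply(comparisons, attr, numeric(1L),
                                    "avg_overexpression_pct"),
    seed = config$seed)

  res <- structure(list(cohort = cohort, dct = dct, rq = rq,
                        stability = stab, comparisons = comparisons,
                        cluster_all = cl_all, cluster_signature = cl_sig,
                        cluster_assoc = assoc_all, signature = sig,
                        thresholds = thr, scores = scores,
                        score_threshold = sthr, risk = risk, alpha = alpha,
                        summary = summary),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) .write_bundle(res, config$out_dir)
  res
}

.write_bundle <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, file) {
    df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, file.path(dir, file), row.names = FALSE)
  }
  wr(res$dct$dct, "delta_ct.csv")
  wr(res$rq$rq, "rq.csv")
  for (g in names(res$comparisons)) {
    utils::write.table(as.data.frame(res$comparisons[[g]]),
                       file.path(dir, paste0("diffexp_", g, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(data.frame(sample_id = names(res$cluster_all$labels),
                              cluster_all = as.integer(res$cluster_all$labels),
                              cluster_signature =
                                as.integer(res$cluster_signature$labels)),
                   file.path(dir, "cluster_labels.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(res$thresholds),
                   file.path(dir, "thresholds.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(res$scores), file.path(dir, "scores.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("pipeline_result: %d patients, %d genes, %d events\n",
              s$n_patients, s$n_genes, s$n_events))
  cat("signature: ", paste(s$signature, collapse = ", "), "\n", sep = "")
  cat(sprintf("score threshold %d; low/high = %d/%d; log-rank p = %.4g; alpha = %.3f\n",
              s$score_threshold, s$group_sizes$low, s$group_sizes$high,
              s$logrank_p, s$cronbach_alpha))
  invisible(x)
}
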