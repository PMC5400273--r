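#' Clinical annotation tables
#'
#' Per-patient clinicopathological covariates and relapse-free survival
#' (RFS) outcome. RFS time runs from diagnosis to local or distant
#' recurrence, in months; patients without recurrence are censored at last
#' follow-up. Column vocabulary:
#' \describe{
#'   \item{sample_id}{unique patient/sample identifier}
#'   \item{age_group}{\code{"<50"} or \code{">=50"}}
#'   \item{er, pr, nodes, her2}{\code{"neg"} or \code{"pos"}}
#'   \item{stage}{tumor stage \code{1}, \code{2} or \code{3}; analyses
#'     dichotomize stage 1 vs 2-3}
#'   \item{grade_msbr}{modified Scarff-Bloom-Richardson grade 1-5; analyses
#'     dichotomize 1-3 (low) vs 4-5 (high)}
#'   \item{relapse}{event indicator, 0 or 1}
#'   \item{rfs_months}{positive relapse-free survival time in months}
#' }
#'
#' @param df data.frame with the columns above.
#' @return object of class \code{clinical_table} (a validated data.frame).
#' @export
clinical_table <- function(df) {
  required <- c("sample_id", "age_group", "er", "pr", "nodes", "stage",
                "grade_msbr", "her2", "relapse", "rfs_months")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("clinical table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df), required)
  if (length(extra) > 0L)
    warning("ignoring unused clinical column(s): ", paste(extra, collapse = ", "))
  df <- as.data.frame(df)[, required]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  chk_cat <- function(col, vocab) {
    v <- as.character(df[[col]])
    bad <- setdiff(unique(v), vocab)
    if (length(bad) > 0L)
      stop("column '", col, "' contains unknown token(s): ",
           paste(sQuote(bad), collapse = ", "),
           " (allowed: ", paste(vocab, collapse = ", "), ")")
    v
  }
  df$age_group <- chk_cat("age_group", c("<50", ">=50"))
  for (col in c("er", "pr", "nodes", "her2"))
    df[[col]] <- chk_cat(col, c("neg", "pos"))
  df$stage <- as.integer(chk_cat("stage", c("1", "2", "3")))
  df$grade_msbr <- as.integer(chk_cat("grade_msbr", c("1", "2", "3", "4", "5")))
  df$relapse <- as.integer(chk_cat("relapse", c("0", "1")))
  df$rfs_months <- as.numeric(df$rfs_months)
  if (any(is.na(df$rfs_months)) || any(df$rfs_months <= 0))
    stop("rfs_months must be positive for every patient")
  rownames(df) <- NULL
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read / write a clinical annotation CSV
#'
#' @param path file path; CSV with the columns documented in
#'   [clinical_table()]. Unknown extra columns are dropped with a warning.
#' @return [read_clinical_table()] returns a \code{clinical_table};
#'   [write_clinical_table()] returns \code{path} invisibly.
#' @export
read_clinical_table <- function(path) {
  clinical_table(utils::read.csv(path, stringsAsFactors = FALSE,
                                 colClasses = "character"))
}

#' @rdname read_clinical_table
#' @param x a \code{clinical_table}.
#' @export
write_clinical_table <- function(x, path) {
  out <- as.data.frame(x)
  out$rfs_months <- sprintf("%.17g", out$rfs_months)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dichotomize a clinical covariate into case/control groups
#'
#' Maps a grouping name to the dichotomies used for group-wise expression
#' comparison: tumor stage 2-3 vs 1, mSBR grade 4-5 vs 1-3, HER2 pos vs neg,
#' and recurrent vs non-recurrent patients. The first level is the control
#' group, the second the case group.
#'
#' @param clinical a \code{clinical_table}.
#' @param grouping one of \code{"stage"}, \code{"grade"}, \code{"her2"},
#'   \code{"relapse"}.
#' @return factor of length \code{nrow(clinical)} with levels
#'   \code{c(control, case)}, named by sample id.
#' @export
clinical_grouping <- function(clinical,
                              grouping = c("stage", "grade", "her2", "relapse")) {
  grouping <- match.arg(grouping)
  g <- switch(grouping,
    stage   = factor(ifelse(clinical$stage >= 2, "stage2-3", "stage1"),
                     levels = c("stage1", "stage2-3")),
    grade   = factor(ifelse(clinical$grade_msbr >= 4, "grade4-5", "grade1-3"),
                     levels = c("grade1-3", "grade4-5")),
    her2    = factor(clinical$her2, levels = c("neg", "pos")),
    relapse = factor(ifelse(clinical$relapse == 1, "recurrent", "non-recurrent"),
                     levels = c("non-recurrent", "recurrent")))
  names(g) <- clinical$sample_id
  g
}
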