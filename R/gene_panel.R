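#' Gene panel descriptions
#'
#' A gene panel lists the assays on a qPCR low-density array card: the gene
#' symbol, the assay identifier, a functional category, and whether the gene
#' is an endogenous (reference / housekeeping) control. The packaged default
#' panel is the 47-assay hypoxia card used throughout this package: 45 target
#' genes covering hypoxia signalling (cell survival, transcription factors,
#' extracellular matrix, glucose metabolism, angiogenesis, drug resistance)
#' plus the two endogenous controls \emph{RPL32} and \emph{18S}.
#'
#' @param entries data.frame with columns \code{gene}, \code{assay_id},
#'   \code{category} and logical (or 0/1) \code{is_reference}.
#' @return An object of class \code{gene_panel}: a validated data.frame with
#'   the four columns above (\code{is_reference} as logical).
#' @examples
#' panel <- default_gene_panel()
#' sum(panel$is_reference)       # 2 housekeeping assays
#' nrow(panel)                   # 47 assays
#' @export
gene_panel <- function(entries) {
  required <- c("gene", "assay_id", "category", "is_reference")
  missing <- setdiff(required, names(entries))
  if (length(missing) > 0L)
    stop("gene panel is missing column(s): ", paste(missing, collapse = ", "))
  entries <- as.data.frame(entries)[, required]
  entries$gene <- as.character(entries$gene)
  entries$assay_id <- as.character(entries$assay_id)
  entries$category <- as.character(entries$category)
  entries$is_reference <- as.logical(as.integer(entries$is_reference))
  dup <- entries$gene[duplicated(entries$gene)]
  if (length(dup) > 0L)
    stop("duplicated gene symbol(s) in panel: ", paste(unique(dup), collapse = ", "))
  if (!any(!entries$is_reference))
    stop("gene panel must contain at least one non-reference gene")
  rownames(entries) <- NULL
  class(entries) <- c("gene_panel", "data.frame")
  entries
}

#' @rdname gene_panel
#' @export
default_gene_panel <- function() {
  path <- system.file("extdata", "gene_panel.csv", package = "hypoxiscore",
                      mustWork = TRUE)
  read_gene_panel(path)
}

#' @rdname gene_panel
#' @param path path to a panel CSV with columns
#'   \code{gene,assay_id,category,is_reference}.
#' @export
read_gene_panel <- function(path) {
  gene_panel(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Reference (housekeeping) genes of a panel
#' @param panel a \code{gene_panel}.
#' @return character vector of reference gene symbols.
#' @export
reference_genes <- function(panel) {
  panel$gene[panel$is_reference]
}

#' Target (non-reference) genes of a panel
#' @param panel a \code{gene_panel}.
#' @return character vector of target gene symbols.
#' @export
target_genes <- function(panel) {
  panel$gene[!panel$is_reference]
}

#' The six-gene relapse signature
#'
#' Genes found significantly overexpressed in recurrent patients and used to
#' build the relapse risk score: EPO, ETS1, ENO1, PGK1, LDHA and TPI. Four of
#' the six encode glycolytic enzymes, consistent with the hypoxic shift to
#' anaerobic metabolism.
#'
#' @return character vector of the six gene symbols.
#' @export
signature_genes <- function() {
  c("EPO", "ETS1", "ENO1", "PGK1", "LDHA", "TPI")
}

#' Published optimum expression thresholds for the signature genes
#'
#' The per-gene relative-quantification cut-offs reported to best discriminate
#' relapse-free survival. A patient scores one point for each signature gene
#' whose RQ exceeds (strictly) its threshold.
#'
#' @return A \code{threshold_table} (see [build_threshold_table()]) with the
#'   six published optima and no search statistics (\code{NA}).
#' @examples
#' published_threshold_table()
#' @export
published_threshold_table <- function() {
  tab <- data.frame(
    gene = c("EPO", "ETS1", "ENO1", "PGK1", "LDHA", "TPI"),
    threshold = c(7.10, 1.81, 1.00, 1.37, 1.20, 1.14),
    statistic = NA_real_,
    n_candidates = NA_integer_,
    min_frac = NA_real_,
    stringsAsFactors = FALSE
  )
  class(tab) <- c("threshold_table", "data.frame")
  attr(tab, "mode") <- "published"
  tab
}
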