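#' Threshold-cycle (Ct) matrices
#'
#' A \code{ct_matrix} holds raw qPCR threshold-cycle values as a genes x
#' samples numeric matrix together with an explicit mask of undetermined
#' wells. Lower Ct means more transcript. Undetermined wells (no amplification
#' within the run) carry no numeric value and are kept distinct from wells
#' that are numeric but beyond a detection cutoff; the cutoff is applied
#' later by [apply_detection_cutoff()] so the raw data stay lossless.
#'
#' @param ct numeric matrix (genes x samples) with \code{NA} at undetermined
#'   wells; must have unique, non-empty dimnames.
#' @param mask optional logical matrix of the same shape; \code{TRUE} marks an
#'   undetermined well. Defaults to \code{is.na(ct)}.
#' @return An object of class \code{ct_matrix}: list with elements
#'   \code{ct} (numeric matrix, \code{NA} where masked), \code{mask}
#'   (logical matrix), \code{genes}, \code{samples}.
#' @examples
#' m <- matrix(c(25, 30, NA, 28), 2, 2,
#'             dimnames = list(c("EPO", "LDHA"), c("S1", "S2")))
#' x <- ct_matrix(m)
#' sum(x$mask)
#' @export
ct_matrix <- function(ct, mask = NULL) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("'ct' must be a numeric matrix")
  genes <- rownames(ct)
  samples <- colnames(ct)
  if (is.null(genes) || is.null(samples))
    stop("'ct' must have gene rownames and sample colnames")
  if (anyDuplicated(genes))
    stop("duplicated gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicated sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (is.null(mask)) mask <- is.na(ct)
  if (!identical(dim(mask), dim(ct)))
    stop("'mask' must have the same dimensions as 'ct'")
  ct[mask] <- NA_real_
  if (any(!is.na(ct) & ct <= 0))
    stop("all numeric Ct values must be > 0")
  structure(list(ct = ct, mask = mask, genes = genes, samples = samples),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d genes x %d samples, %d undetermined well(s)\n",
              length(x$genes), length(x$samples), sum(x$mask)))
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

# token set treated as undetermined in Ct table files
.undetermined_tokens <- c("Undetermined", "undetermined", "NA", "")

.parse_ct_token <- function(tok, where) {
  tok <- trimws(tok)
  out <- rep(NA_real_, length(tok))
  und <- tok %in% .undetermined_tokens
  num <- suppressWarnings(as.numeric(tok))
  bad <- !und & is.na(num)
  if (any(bad))
    stop("unrecognized Ct token(s) ", paste(sQuote(unique(tok[bad])), collapse = ", "),
         " at ", where[which(bad)[1L]])
  out[!und] <- num[!und]
  out
}

#' Read a Ct table from a TLDA-style CSV/TSV export
#'
#' Accepts either wide format (first column \code{gene}, one column per
#' sample) or long format (columns \code{gene,sample,ct}); the layout is
#' auto-detected from the header. The tokens \code{Undetermined}, \code{NA}
#' and the empty string become masked wells. Numbers must use dot decimals
#' regardless of locale.
#'
#' @param path file path.
#' @param sep field separator; by default inferred from the extension
#'   (\code{.tsv}/\code{.txt} -> tab, otherwise comma).
#' @return a [ct_matrix()].
#' @export
read_ct_table <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          stringsAsFactors = FALSE)
  hdr <- names(df)
  if (length(hdr) < 2L || tolower(hdr[1L]) != "gene")
    stop("Ct table must start with a 'gene' column")
  if (identical(tolower(hdr), c("gene", "sample", "ct"))) {
    genes <- unique(df[[1L]])
    samples <- unique(df[[2L]])
    key <- paste(df[[1L]], df[[2L]], sep = "\r")
    if (anyDuplicated(key))
      stop("duplicated gene/sample pair(s): ",
           paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "))
    ct <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
    vals <- .parse_ct_token(df[[3L]],
                            sprintf("row %d (gene %s, sample %s)",
                                    seq_len(nrow(df)), df[[1L]], df[[2L]]))
    ct[cbind(match(df[[1L]], genes), match(df[[2L]], samples))] <- vals
    mask <- is.na(ct)
    present <- matrix(FALSE, length(genes), length(samples))
    present[cbind(match(df[[1L]], genes), match(df[[2L]], samples))] <- TRUE
    mask[!present] <- TRUE
    return(ct_matrix(ct, mask))
  }
  samples <- hdr[-1L]
  if (anyDuplicated(samples))
    stop("duplicated sample id(s) in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  genes <- df[[1L]]
  if (anyDuplicated(genes))
    stop("duplicated gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  ct <- matrix(NA_real_, length(genes), length(samples),
               dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    ct[, j] <- .parse_ct_token(df[[j + 1L]],
                               sprintf("gene %s, column %s", genes, samples[j]))
  }
  ct_matrix(ct)
}

#' Write a Ct table
#'
#' Inverse of [read_ct_table()]. Values are written with 17 significant
#' digits so that a write/read round trip reproduces the matrix
#' bit-identically; masked wells are written as \code{Undetermined}.
#'
#' @param x a [ct_matrix()].
#' @param path output file path.
#' @param format \code{"wide"} or \code{"long"}.
#' @param sep field separator (default comma).
#' @return \code{path}, invisibly.
#' @export
write_ct_table <- function(x, path, format = c("wide", "long"), sep = ",") {
  format <- match.arg(format)
  fmt <- function(v) ifelse(is.na(v), "Undetermined", sprintf("%.17g", v))
  if (format == "wide") {
    out <- data.frame(gene = x$genes, apply(x$ct, 2L, fmt),
                      check.names = FALSE, stringsAsFactors = FALSE)
    names(out) <- c("gene", x$samples)
  } else {
    out <- data.frame(
      gene = rep(x$genes, times = length(x$samples)),
      sample = rep(x$samples, each = length(x$genes)),
      ct = fmt(as.vector(x$ct)),
      stringsAsFactors = FALSE)
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
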