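#' Marker matrix constructor
#'
#' Wraps an n x p numeric dosage matrix with its line identifiers. Dosages are
#' expected in either the 0/1/2 allele-count coding or the centred -1/0/1
#' coding; missing calls are `NA`.
#'
#' @param X numeric matrix, lines in rows, markers in columns. Row names (or
#'   `line_ids`) identify the lines.
#' @param line_ids character vector of unique line identifiers; defaults to
#'   `rownames(X)`.
#' @param coding dosage coding of `X`, `"012"` or `"-101"`.
#' @param standardized logical; `TRUE` when columns have already been centred
#'   and scaled to unit sample variance.
#' @return An object of class `marker_matrix`: a list with elements `X`,
#'   `line_ids`, `coding` and `standardized`.
#' @export
marker_matrix <- function(X, line_ids = rownames(X), coding = c("012", "-101"),
                          standardized = FALSE) {
  coding <- match.arg(coding)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(line_ids)) {
    stop("marker matrix needs line identifiers (row names or 'line_ids')")
  }
  line_ids <- as.character(line_ids)
  if (length(line_ids) != nrow(X)) {
    stop("length of 'line_ids' must equal nrow(X)")
  }
  if (anyDuplicated(line_ids)) {
    stop("duplicate line identifiers: ",
         paste(unique(line_ids[duplicated(line_ids)]), collapse = ", "))
  }
  rownames(X) <- line_ids
  out <- list(X = X, line_ids = line_ids, coding = coding,
              standardized = standardized)
  class(out) <- "marker_matrix"
  out
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d lines x %d markers (%s coding, %s)\n",
              nrow(x$X), ncol(x$X), x$coding,
              if (x$standardized) "standardized" else "raw"))
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$X)

minor_allele_freq <- function(x, coding) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  # allele frequency of the counted allele, folded to the minor allele
  q <- if (coding == "012") mean(x) / 2 else (mean(x) + 1) / 2
  min(q, 1 - q)
}

#' Marker quality control
#'
#' Removes markers with a low minor allele frequency or a high missing rate,
#' then mean-imputes the remaining missing dosages. Mirrors the standard QC of
#' genomic-selection pipelines (markers with MAF below 0.05 excluded).
#'
#' @param X raw dosage matrix or `marker_matrix` (not yet standardized).
#' @param maf_min minimum minor allele frequency; markers strictly below are
#'   removed. Default 0.05.
#' @param max_missing maximum tolerated per-marker missing fraction; markers
#'   strictly above are removed. Default 0.2.
#' @param coding dosage coding, `"012"` (default) or `"-101"`.
#' @return A `marker_matrix` with attributes `n_removed_maf` and
#'   `n_removed_missing` reporting counts removed by each rule.
#' @export
filter_markers <- function(X, maf_min = 0.05, max_missing = 0.2,
                           coding = c("012", "-101")) {
  if (inherits(X, "marker_matrix")) {
    if (X$standardized) stop("filter_markers() expects raw (unstandardized) dosages")
    coding <- X$coding
    X <- X$X
  } else {
    coding <- match.arg(coding)
    X <- as.matrix(X)
    storage.mode(X) <- "double"
  }
  rng <- range(X, na.rm = TRUE)
  ok <- switch(coding,
               "012" = rng[1] >= 0 && rng[2] <= 2,
               "-101" = rng[1] >= -1 && rng[2] <= 1)
  if (!ok) {
    stop(sprintf("dosages outside the declared '%s' coding (observed range [%g, %g])",
                 coding, rng[1], rng[2]))
  }
  miss_rate <- colMeans(is.na(X))
  keep_miss <- miss_rate <= max_missing
  maf <- apply(X, 2, minor_allele_freq, coding = coding)
  keep_maf <- !is.na(maf) & maf >= maf_min
  keep <- keep_miss & keep_maf
  if (!any(keep)) stop("all markers removed by QC filters")
  Xf <- X[, keep, drop = FALSE]
  # impute remaining missing calls to the marker mean
  if (anyNA(Xf)) {
    mu <- colMeans(Xf, na.rm = TRUE)
    idx <- which(is.na(Xf), arr.ind = TRUE)
    Xf[idx] <- mu[idx[, 2]]
  }
  out <- marker_matrix(Xf, coding = coding, standardized = FALSE)
  attr(out, "n_removed_maf") <- sum(keep_miss & !keep_maf)
  attr(out, "n_removed_missing") <- sum(!keep_miss)
  out
}

#' Column-standardize a marker matrix
#'
#' Centres each marker to mean zero and scales it to unit sample variance
#' (n - 1 denominator). Markers with zero raw variance carry no information
#' and are dropped rather than divided by zero.
#'
#' @param M a `marker_matrix` (missing values must already be imputed).
#' @return A standardized `marker_matrix`.
#' @export
standardize_markers <- function(M) {
  stopifnot(inherits(M, "marker_matrix"))
  if (M$standardized) return(M)
  X <- M$X
  if (anyNA(X)) stop("impute missing dosages (filter_markers) before standardizing")
  mu <- colMeans(X)
  X <- sweep(X, 2, mu, "-")
  s <- sqrt(colSums(X^2) / (nrow(X) - 1))
  keep <- s > 0
  if (!any(keep)) stop("no polymorphic markers left after standardization")
  X <- sweep(X[, keep, drop = FALSE], 2, s[keep], "/")
  marker_matrix(X, line_ids = M$line_ids, coding = M$coding, standardized = TRUE)
}

#' Read a marker matrix from delimited text
#'
#' Expects a header row of marker names and the line identifier in the first
#' column. Empty cells or "NA" are treated as missing calls.
#'
#' @param path file path to a CSV/TSV file.
#' @param sep field separator (default `,`).
#' @param coding dosage coding, see [marker_matrix()].
#' @return A raw `marker_matrix`.
#' @export
read_markers_csv <- function(path, sep = ",", coding = c("012", "-101")) {
  coding <- match.arg(coding)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, na.strings = c("", "NA"))
  marker_matrix(as.matrix(df), coding = coding)
}
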