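#' Kernel matrix constructor
#'
#' A validated symmetric positive semi-definite line-relationship matrix.
#' Symmetry is required within 1e-10 and eigenvalues may not fall below
#' -1e-8 times the largest eigenvalue; violations are errors, never silently
#' clipped.
#'
#' @param K n x n numeric matrix with line identifiers as dimnames.
#' @param method `"GB"` (linear / GBLUP) or `"GK"` (Gaussian).
#' @param h Gaussian bandwidth (GK only).
#' @param scale median squared distance used as the GK scaling factor.
#' @param line_ids line identifiers; default `rownames(K)`.
#' @return An object of class `kernel_matrix` with elements `K`, `line_ids`,
#'   `method`, `h`, `scale`.
#' @export
kernel_matrix <- function(K, method = c("GB", "GK"), h = NULL, scale = NULL,
                          line_ids = rownames(K)) {
  method <- match.arg(method)
  K <- as.matrix(K)
  if (is.null(line_ids)) stop("kernel needs line identifiers")
  line_ids <- as.character(line_ids)
  if (nrow(K) != ncol(K) || length(line_ids) != nrow(K)) {
    stop("kernel must be square with one id per row")
  }
  if (anyDuplicated(line_ids)) stop("duplicate line identifiers in kernel")
  if (max(abs(K - t(K))) > 1e-10) stop("kernel is not symmetric within 1e-10")
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev, 0)) {
    stop(sprintf("kernel is not numerically PSD (min eigenvalue %.3e)", min(ev)))
  }
  if (method == "GK") {
    if (max(abs(diag(K) - 1)) > 1e-12) stop("GK kernel must have unit diagonal")
    if (any(K <= 0) || any(K > 1 + 1e-12)) stop("GK entries must lie in (0, 1]")
  }
  dimnames(K) <- list(line_ids, line_ids)
  out <- list(K = K, line_ids = line_ids, method = method, h = h, scale = scale)
  class(out) <- "kernel_matrix"
  out
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix (%s): %d lines", x$method, nrow(x$K)))
  if (x$method == "GK") cat(sprintf(", h = %g, median d^2 = %g", x$h, x$scale))
  cat("\n")
  invisible(x)
}

#' Linear (GBLUP) kernel
#'
#' Computes the genomic relationship matrix K = XX'/p from the standardized
#' marker matrix, p being the number of retained markers. This is the
#' VanRaden-style kernel underlying GBLUP.
#'
#' @param M a `marker_matrix`; standardized if it is not already.
#' @return A `kernel_matrix` with `method = "GB"`.
#' @export
linear_kernel <- function(M) {
  stopifnot(inherits(M, "marker_matrix"))
  M <- standardize_markers(M)
  p <- ncol(M$X)
  if (p == 0) stop("no markers available to build the kernel")
  K <- tcrossprod(M$X) / p
  kernel_matrix(K, method = "GB", line_ids = M$line_ids)
}

#' Squared Euclidean distance matrix between lines
#'
#' d2[i, i'] = sum_k (x[i, k] - x[i', k])^2 over the marker columns.
#'
#' @param M a `marker_matrix` (any coding; must be finite).
#' @return n x n numeric matrix with zero diagonal.
#' @export
squared_distance_matrix <- function(M) {
  stopifnot(inherits(M, "marker_matrix"))
  X <- M$X
  if (anyNA(X)) stop("marker matrix has missing values; impute first")
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0   # numerical round-off
  diag(D2) <- 0
  dimnames(D2) <- list(M$line_ids, M$line_ids)
  D2
}

#' Gaussian kernel
#'
#' K[i, i'] = exp(-h * d2[i, i'] / median(d2)), the median taken over the
#' strictly off-diagonal squared distances so the self-distances (all zero)
#' do not deflate the scale. With the default bandwidth h = 1, the pair at
#' the median distance has kernel value exp(-1).
#'
#' @param M a `marker_matrix`; standardized if it is not already (so GB and GK
#'   are built from the same coordinates).
#' @param h bandwidth controlling the decay rate of kernel values; default 1.
#' @return A `kernel_matrix` with `method = "GK"`, unit diagonal, and the
#'   median squared distance stored in `$scale`.
#' @export
gaussian_kernel <- function(M, h = 1) {
  stopifnot(inherits(M, "marker_matrix"), h > 0)
  M <- standardize_markers(M)
  if (nrow(M$X) < 2) stop("need at least two lines for the Gaussian kernel")
  D2 <- squared_distance_matrix(M)
  med <- stats::median(D2[upper.tri(D2)])
  if (med <= 0) {
    stop("median squared distance is zero: lines with identical genotypes ",
         "dominate; the Gaussian kernel is degenerate")
  }
  K <- exp(-h * D2 / med)
  diag(K) <- 1
  kernel_matrix(K, method = "GK", h = h, scale = med, line_ids = M$line_ids)
}

#' Build a kernel from raw markers in one call
#'
#' Convenience wrapper: QC filter, standardize, then build the requested
#' kernel.
#'
#' @param X raw dosage matrix or `marker_matrix`.
#' @param method `"GB"` or `"GK"`.
#' @param h GK bandwidth.
#' @param maf_min,max_missing QC thresholds passed to [filter_markers()].
#' @param coding dosage coding of raw input.
#' @return A `kernel_matrix`.
#' @export
build_kernel <- function(X, method = c("GB", "GK"), h = 1, maf_min = 0.05,
                         max_missing = 0.2, coding = c("012", "-101")) {
  method <- match.arg(method)
  M <- filter_markers(X, maf_min = maf_min, max_missing = max_missing,
                      coding = coding)
  if (method == "GB") linear_kernel(M) else gaussian_kernel(M, h = h)
}

#' Export a kernel to CSV
#'
#' Writes the kernel with line identifiers as header row and first column, at
#' 17 significant digits so that [read_kernel_csv()] round-trips the values
#' bit-identically.
#'
#' @param K a `kernel_matrix`.
#' @param path output file path.
#' @export
write_kernel_csv <- function(K, path) {
  stopifnot(inherits(K, "kernel_matrix"))
  df <- data.frame(line_id = K$line_ids,
                   matrix(sprintf("%.17g", K$K), nrow = nrow(K$K)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("line_id", K$line_ids)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import a kernel from CSV
#'
#' @param path file written by [write_kernel_csv()] (or of the same shape).
#' @param method kernel method label to attach, `"GB"` or `"GK"`.
#' @return A `kernel_matrix`.
#' @export
read_kernel_csv <- function(path, method = c("GB", "GK")) {
  method <- match.arg(method)
  df <- utils::read.table(path, header = TRUE, sep = ",", row.names = 1,
                          check.names = FALSE)
  kernel_matrix(as.matrix(df), method = method)
}
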