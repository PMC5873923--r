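#' Multi-environment trial data
#'
#' Long-format line-by-environment adjusted means (stage-1 BLUEs): one record
#' per observed (line, environment) cell. Records are stored in the canonical
#' environment-major, line-minor order; all design and covariance structures
#' in the package share that ordering, which makes the per-environment block
#' structure of the model covariances directly visible.
#'
#' @param records data.frame with columns `line`, `env`, `value` (or vectors
#'   via `line`, `env`, `value`).
#' @param line,env,value alternative vector interface.
#' @param env_order optional explicit environment ordering; default is the
#'   sorted unique environment ids.
#' @return An object of class `trial_data`: list with `records` (data.frame,
#'   canonical order), `line_ids`, `env_ids`, `n` (lines), `m` (environments),
#'   `N` (records).
#' @export
trial_data <- function(records = NULL, line = NULL, env = NULL, value = NULL,
                       env_order = NULL) {
  if (is.null(records)) {
    records <- data.frame(line = line, env = env, value = value,
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("line", "env", "value") %in% names(records)))
  records <- data.frame(line = as.character(records$line),
                        env = as.character(records$env),
                        value = as.numeric(records$value),
                        stringsAsFactors = FALSE)
  if (nrow(records) == 0) stop("trial has no records")
  key <- paste(records$line, records$env, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), , drop = FALSE]
    stop("duplicate (line, env) records, e.g. line '", dup$line[1],
         "' in env '", dup$env[1], "'")
  }
  env_ids <- if (is.null(env_order)) sort(unique(records$env)) else as.character(env_order)
  if (!all(records$env %in% env_ids)) stop("env_order does not cover all environments")
  line_ids <- sort(unique(records$line))
  ord <- order(match(records$env, env_ids), match(records$line, line_ids))
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  out <- list(records = records, line_ids = line_ids, env_ids = env_ids,
              n = length(line_ids), m = length(env_ids), N = nrow(records))
  class(out) <- "trial_data"
  out
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("trial_data: %d records, %d lines x %d environments\n",
              x$N, x$n, x$m))
  cnt <- table(factor(x$records$env, levels = x$env_ids))
  cat("records per environment:\n")
  print(cnt)
  invisible(x)
}

#' Read trial phenotypes from CSV
#'
#' Expects the header `line,env,value`.
#'
#' @param path file path.
#' @param env_order optional explicit environment order.
#' @return A `trial_data`.
#' @export
read_trial_csv <- function(path, env_order = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  trial_data(df, env_order = env_order)
}

#' Write trial phenotypes to CSV
#'
#' @param trial a `trial_data`.
#' @param path output path.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "trial_data"))
  utils::write.csv(trial$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pivot a trial to the wide lines x environments matrix
#'
#' Unobserved cells are `NA`. The pivot is lossless: [to_long()] restores the
#' original records on observed cells.
#'
#' @param trial a `trial_data`.
#' @return numeric n x m matrix, rows named by line, columns by environment.
#' @export
to_wide <- function(trial) {
  stopifnot(inherits(trial, "trial_data"))
  W <- matrix(NA_real_, trial$n, trial$m,
              dimnames = list(trial$line_ids, trial$env_ids))
  i <- match(trial$records$line, trial$line_ids)
  j <- match(trial$records$env, trial$env_ids)
  W[cbind(i, j)] <- trial$records$value
  W
}

#' Pivot a wide phenotype matrix back to long format
#'
#' @param W numeric matrix with line row names and environment column names;
#'   `NA` cells are dropped.
#' @return A `trial_data`.
#' @export
to_long <- function(W) {
  stopifnot(is.matrix(W), !is.null(rownames(W)), !is.null(colnames(W)))
  obs <- which(!is.na(W), arr.ind = TRUE)
  if (nrow(obs) == 0) stop("wide matrix has no observed cells")
  trial_data(line = rownames(W)[obs[, 1]], env = colnames(W)[obs[, 2]],
             value = W[obs], env_order = colnames(W))
}
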