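#' Random cross-validation partitions (CV1 / CV2)
#'
#' CV1 mimics prediction of untested lines: a fraction of the lines is drawn
#' into the test set and all their records are masked jointly. CV2 mimics
#' sparse testing: individual records are masked, so a line can be in training
#' in one environment and in test in another. Partitions are repeated random
#' 80/20 sub-samples by default; disjoint k-fold splits are available via
#' `method = "kfold"`.
#'
#' @param trial a `trial_data`.
#' @param scheme `"CV1"` or `"CV2"`.
#' @param n_partitions number of random partitions, default 50.
#' @param fraction_train fraction assigned to training, default 0.8.
#' @param seed RNG seed; the same seed reproduces the same partitions.
#' @param stratify_env CV2 only: sample test records within each environment
#'   instead of uniformly over records. Default `FALSE`.
#' @param method `"subsample"` (repeated random splits, default) or `"kfold"`
#'   (disjoint folds; `n_partitions` is then the number of folds).
#' @return An object of class `partition_set`: list with `scheme`,
#'   `partitions` (each `list(train, test)` of record indices), `n_partitions`,
#'   `fraction_train`, `seed`, and `n_resampled` (partitions redrawn because
#'   an environment kept fewer than 2 test or 1 training records).
#' @export
make_partitions <- function(trial, scheme = c("CV1", "CV2"), n_partitions = 50,
                            fraction_train = 0.8, seed = 1,
                            stratify_env = FALSE,
                            method = c("subsample", "kfold")) {
  scheme <- match.arg(scheme)
  method <- match.arg(method)
  stopifnot(inherits(trial, "trial_data"),
            fraction_train > 0, fraction_train < 1)
  env_idx <- match(trial$records$env, trial$env_ids)
  line_of <- trial$records$line
  n_test_lines <- max(1L, round((1 - fraction_train) * trial$n))
  n_test_rec <- max(1L, round((1 - fraction_train) * trial$N))
  if (scheme == "CV1" && n_test_lines >= trial$n) stop("too few lines to split")
  if (scheme == "CV2" && n_test_rec >= trial$N) stop("too few records to split")

  valid <- function(test) {
    tt <- tabulate(env_idx[test], nbins = trial$m)
    tr <- tabulate(env_idx[-test], nbins = trial$m)
    all(tt >= 2) && all(tr >= 1)
  }
  draw_one <- function() {
    if (scheme == "CV1") {
      tl <- sample(trial$line_ids, n_test_lines)
      which(line_of %in% tl)
    } else if (stratify_env) {
      unlist(lapply(seq_len(trial$m), function(j) {
        idx <- which(env_idx == j)
        sample(idx, max(1L, round((1 - fraction_train) * length(idx))))
      }))
    } else {
      sample(trial$N, n_test_rec)
    }
  }

  set.seed(seed)
  n_resampled <- 0L
  partitions <- vector("list", n_partitions)
  if (method == "kfold") {
    if (scheme == "CV1") {
      fold_of <- sample(rep_len(seq_len(n_partitions), trial$n))
      for (k in seq_len(n_partitions)) {
        test <- which(line_of %in% trial$line_ids[fold_of == k])
        partitions[[k]] <- list(train = setdiff(seq_len(trial$N), test),
                                test = test)
      }
    } else {
      fold_of <- sample(rep_len(seq_len(n_partitions), trial$N))
      for (k in seq_len(n_partitions)) {
        test <- which(fold_of == k)
        partitions[[k]] <- list(train = setdiff(seq_len(trial$N), test),
                                test = test)
      }
    }
  } else {
    for (k in seq_len(n_partitions)) {
      test <- draw_one()
      tries <- 0L
      while (!valid(test) && tries < 100L) {
        test <- draw_one()
        tries <- tries + 1L
        n_resampled <- n_resampled + 1L
      }
      if (!valid(test)) {
        stop("could not find a partition leaving >= 2 test and >= 1 training ",
             "records in every environment")
      }
      test <- sort(test)
      partitions[[k]] <- list(train = setdiff(seq_len(trial$N), test),
                              test = test)
    }
  }
  structure(list(scheme = scheme, partitions = partitions,
                 n_partitions = n_partitions, fraction_train = fraction_train,
                 seed = seed, n_resampled = n_resampled),
            class = "partition_set")
}

#' @export
print.partition_set <- function(x, ...) {
  cat(sprintf("partition_set: %s, %d partitions, %.0f%% train (seed %d)\n",
              x$scheme, x$n_partitions, 100 * x$fraction_train, x$seed))
  invisible(x)
}

#' Serialize partitions to JSON (for exact reuse across engines)
#' @param ps a `partition_set`.
#' @param path output path.
#' @export
write_partitions_json <- function(ps, path) {
  jsonlite::write_json(unclass(ps), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read partitions back from JSON
#' @param path file written by [write_partitions_json()].
#' @return A `partition_set`.
#' @export
read_partitions_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  x$partitions <- lapply(x$partitions, function(p) {
    list(train = vapply(p$train, as.integer, 0L),
         test = vapply(p$test, as.integer, 0L))
  })
  x$n_partitions <- as.integer(x$n_partitions)
  x$fraction_train <- as.numeric(x$fraction_train)
  x$seed <- as.integer(x$seed)
  class(x) <- "partition_set"
  x
}

fit_any <- function(trial, model, kernel_method, kernels, cfg, mask,
                    priors = NULL) {
  K <- kernels[[kernel_method]]
  if (is.null(K)) stop("no kernel for method ", kernel_method)
  if (model %in% kronecker_models) {
    fit_muc(trial, K, with_f = (model == "MUCf"),
            priors = priors, cfg = cfg, mask = mask)
  } else {
    fit_gp(trial, model, K, priors = priors, cfg = cfg, mask = mask)
  }
}

#' Cross-validated prediction accuracy of a set of models
#'
#' For every partition, masks the test records, fits each model on the
#' training records, predicts the masked cells, and computes the Pearson
#' correlation between observed and predicted values per environment over that
#' environment's test records. All models see identical masks, making the
#' accuracies directly comparable.
#'
#' @param trial a `trial_data`.
#' @param models data.frame with columns `model` (e.g. `"MDs"`) and `kernel`
#'   (`"GB"` or `"GK"`), or a character vector like `"MDs-GK"`.
#' @param kernels named list with elements `GB` and/or `GK` (each a
#'   `kernel_matrix`).
#' @param partitions a `partition_set` from [make_partitions()].
#' @param cfg an [mcmc_config()]; its seed is offset per partition so chains
#'   differ across partitions but the whole evaluation is reproducible.
#' @return An object of class `accuracy_table`: data.frame with columns
#'   `model`, `kernel`, `env`, `mean`, `sd` (over partitions), `n_partitions`
#'   (partitions where the correlation was defined), plus attribute
#'   `n_skipped` counting (env, partition) cells skipped for having fewer than
#'   2 usable test records.
#' @export
evaluate_cv <- function(trial, models, kernels, partitions,
                        cfg = mcmc_config()) {
  stopifnot(inherits(partitions, "partition_set"))
  if (is.character(models)) {
    parts <- strsplit(models, "-", fixed = TRUE)
    models <- data.frame(model = vapply(parts, `[`, "", 1),
                         kernel = vapply(parts, `[`, "", 2),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(models$model %in% all_models()),
            all(models$kernel %in% c("GB", "GK")))
  env_idx <- match(trial$records$env, trial$env_ids)
  y <- trial$records$value
  n_skipped <- 0L
  acc <- array(NA_real_, c(nrow(models), trial$m, partitions$n_partitions))
  for (p in seq_len(partitions$n_partitions)) {
    test <- partitions$partitions[[p]]$test
    pcfg <- mcmc_config(cfg$n_iter, cfg$burn_in, cfg$thin,
                        seed = cfg$seed + 1000L * p)
    for (mi in seq_len(nrow(models))) {
      fit <- fit_any(trial, models$model[mi], models$kernel[mi], kernels,
                     pcfg, mask = test)
      for (j in seq_len(trial$m)) {
        tj <- test[env_idx[test] == j]
        if (length(tj) < 2 || stats::sd(y[tj]) == 0 ||
            stats::sd(fit$predictions[tj]) == 0) {
          n_skipped <- n_skipped + 1L
          next
        }
        acc[mi, j, p] <- stats::cor(y[tj], fit$predictions[tj])
      }
    }
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(models)), function(mi) {
    do.call(rbind, lapply(seq_len(trial$m), function(j) {
      r <- acc[mi, j, ]
      data.frame(model = models$model[mi], kernel = models$kernel[mi],
                 env = trial$env_ids[j],
                 mean = mean(r, na.rm = TRUE),
                 sd = stats::sd(r[!is.na(r)]),
                 n_partitions = sum(!is.na(r)), stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  attr(rows, "n_skipped") <- n_skipped
  attr(rows, "per_partition") <- acc
  class(rows) <- c("accuracy_table", "data.frame")
  rows
}

#' Write an accuracy table as environments x model-method CSV
#'
#' Rows are environments, columns the model-kernel combinations, cells
#' formatted `"mean (sd)"` — the shape of published multi-environment
#' accuracy tables.
#'
#' @param tab an `accuracy_table`.
#' @param path output path.
#' @export
write_accuracy_csv <- function(tab, path) {
  key <- paste(tab$model, tab$kernel, sep = "-")
  envs <- unique(tab$env)
  cols <- unique(key)
  M <- matrix("", length(envs), length(cols), dimnames = list(envs, cols))
  M[cbind(match(tab$env, envs), match(key, cols))] <-
    sprintf("%.3f (%.3f)", tab$mean, tab$sd)
  utils::write.csv(data.frame(env = envs, M, check.names = FALSE), path,
                   row.names = FALSE)
  invisible(path)
}
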