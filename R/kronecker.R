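#' Default priors for the unstructured-covariance models
#'
#' Inverse-Wishart priors for the between-environment genetic covariance UE
#' (and FE when the intercept term f is included) with df = m + 2 and scale
#' 0.5 * diag(per-environment phenotypic variance): weakly informative,
#' centred on half the phenotypic variance with no between-environment
#' covariance. Each residual variance gets a scaled-inverse-chi-square prior
#' (nu = 5) with mode at half the environment's phenotypic variance.
#'
#' @param trial a `trial_data`.
#' @param nu residual prior degrees of freedom, default 5.
#' @return list with `ue = list(df, scale)`, `fe = list(df, scale)`,
#'   `sigma = list(nu, S)` (`S` a per-environment vector).
#' @export
default_priors_muc <- function(trial, nu = 5) {
  W <- to_wide(trial)
  vj <- apply(W, 2, stats::var, na.rm = TRUE)
  vj[!is.finite(vj) | vj <= 0] <- 1
  m <- trial$m
  list(ue = list(df = m + 2, scale = diag(0.5 * vj, m)),
       fe = list(df = m + 2, scale = diag(0.5 * vj, m)),
       sigma = list(nu = nu, S = 0.5 * vj * (nu + 2) / nu))
}

riwish <- function(df, Psi) {
  # X ~ IW(Psi, df)  <=>  X^-1 ~ Wishart(Psi^-1, df)
  W <- stats::rWishart(1, df, chol2inv(chol(Psi)))[, , 1]
  chol2inv(chol(W))
}

#' Fit the unstructured-covariance multi-environment model (MUC / MUCf)
#'
#' y = mu 1 + ZE betaE + u (+ f) + eps with u ~ N(0, UE (x) K),
#' f ~ N(0, FE (x) I) and eps ~ N(0, Sigma (x) I), Sigma diagonal with one
#' residual variance per environment. The Kronecker structure lets the
#' between-environment genetic covariances in UE take any sign, which the
#' Hadamard family cannot represent. Sampling rotates the line dimension into
#' the kernel eigenbasis, where rows decouple; unobserved and masked cells are
#' data-augmented so the algebra stays balanced.
#'
#' @param trial a `trial_data` with at least two environments.
#' @param K a `kernel_matrix` covering every trial line.
#' @param with_f include the intercept-level covariance term f (model MUCf).
#' @param priors list as from [default_priors_muc()].
#' @param cfg an [mcmc_config()].
#' @param mask optional record indices treated as missing and predicted.
#' @param fix_ue optional m x m matrix: hold UE fixed (update disabled).
#' @param fix_sigma optional length-m vector: hold the residual variances
#'   fixed.
#' @return An object of class `muc_fit`: posterior means `UE`, `FE` (`NULL`
#'   without f), `Sigma`, a `vc` summary table, `predictions` for every trial
#'   record (posterior mean of mu + ZE betaE + u (+ f)), `fitted_grid`,
#'   variance chains, `n_kept` and `n_jitter` (non-PD draws repaired, normally
#'   zero).
#' @export
fit_muc <- function(trial, K, with_f = FALSE, priors = NULL,
                    cfg = mcmc_config(), mask = NULL, fix_ue = NULL,
                    fix_sigma = NULL) {
  stopifnot(inherits(trial, "trial_data"), inherits(K, "kernel_matrix"),
            inherits(cfg, "mcmc_config"))
  n <- trial$n; m <- trial$m
  if (m < 2) stop("the unstructured model is undefined for a single environment")
  if (!is.null(mask)) {
    mask <- as.integer(mask)
    if (length(mask) == 0) mask <- NULL
    else stopifnot("mask indices out of range" = all(mask >= 1 & mask <= trial$N))
  }
  if (is.null(priors)) {
    obs_records <- if (is.null(mask)) trial$records else trial$records[-mask, ]
    priors <- default_priors_muc(trial_data(obs_records,
                                            env_order = trial$env_ids))
  }

  line_idx <- match(trial$records$line, trial$line_ids)
  env_idx <- match(trial$records$env, trial$env_ids)
  O <- matrix(FALSE, n, m)
  O[cbind(line_idx, env_idx)] <- TRUE
  O[cbind(line_idx[mask], env_idx[mask])] <- FALSE
  if (any(colSums(O) == 0)) stop("environment without observed records")
  Y <- matrix(NA_real_, n, m)
  Y[cbind(line_idx, env_idx)] <- trial$records$value
  Y[cbind(line_idx[mask], env_idx[mask])] <- NA_real_
  env_means <- vapply(seq_len(m), function(j) mean(Y[O[, j], j]), 0)
  miss <- which(!O)
  n_miss <- length(miss)
  miss_col <- ((miss - 1L) %/% n) + 1L
  Y[miss] <- env_means[miss_col]

  # full orthogonal eigenbasis of K; rows with negligible eigenvalue carry no
  # genetic signal and their u-coordinates stay at zero
  e <- eigen(subset_kernel(K, trial$line_ids), symmetric = TRUE)
  U <- e$vectors
  d <- pmax(e$values, 0)
  keep <- d > 1e-10 * max(d)
  q <- sum(keep)
  dk <- d[keep]

  UE <- if (is.null(fix_ue)) priors$ue$scale else as.matrix(fix_ue)
  FE <- if (with_f) priors$fe$scale else NULL
  Sigma <- if (is.null(fix_sigma)) priors$sigma$S else as.numeric(fix_sigma)
  eta <- env_means
  A <- matrix(0, n, m)     # rotated u-coordinates
  Ft <- if (with_f) matrix(0, n, m) else NULL  # rotated f-coordinates
  n_jitter <- 0L

  ut <- utri_names(trial$env_ids)
  vc_names <- c(ut$ue, if (with_f) ut$fe, paste0("sigma2_", trial$env_ids))
  n_kept_max <- length(seq(cfg$burn_in + 1L, cfg$n_iter))
  n_kept_max <- ceiling(n_kept_max / cfg$thin)
  chains <- matrix(NA_real_, n_kept_max, length(vc_names),
                   dimnames = list(NULL, vc_names))
  pred_sum <- matrix(0, n, m)
  UE_sum <- matrix(0, m, m)
  FE_sum <- if (with_f) matrix(0, m, m) else NULL
  Sigma_sum <- numeric(m)
  eta_sum <- numeric(m)
  n_kept <- 0L

  safe_chol <- function(M) {
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) {
      n_jitter <<- n_jitter + 1L
      ch <- chol(M + diag(1e-8 * mean(diag(M)), nrow(M)))
    }
    ch
  }

  set.seed(cfg$seed)
  for (it in seq_len(cfg$n_iter)) {
    u_mat <- U[, keep, drop = FALSE] %*% A[keep, , drop = FALSE]
    f_mat <- if (with_f) U %*% Ft else 0
    Fit <- matrix(eta, n, m, byrow = TRUE) + u_mat + f_mat
    if (n_miss > 0) {
      Y[miss] <- Fit[miss] +
        stats::rnorm(n_miss, sd = sqrt(Sigma[miss_col]))
    }
    # environment means
    Rm <- Y - u_mat - f_mat
    eta <- colMeans(Rm) + stats::rnorm(m, sd = sqrt(Sigma / n))
    Yc <- crossprod(U, Y - matrix(eta, n, m, byrow = TRUE))
    # u: rows decouple; whiten by Sigma and diagonalize the UE^-1 pencil so
    # the update is fully vectorized across rows
    UEinv <- chol2inv(safe_chol(UE))
    sS <- sqrt(Sigma)
    B <- (UEinv * sS) * rep(sS, each = m)    # diag(sS) %*% UEinv %*% diag(sS)
    eb <- eigen((B + t(B)) / 2, symmetric = TRUE)
    Rr <- Yc[keep, , drop = FALSE]
    if (with_f) Rr <- Rr - Ft[keep, , drop = FALSE]
    W <- (Rr * rep(1 / sS, each = q)) %*% eb$vectors
    denom <- 1 + outer(1 / dk, eb$values)
    Cc <- W / denom + matrix(stats::rnorm(q * m), q, m) / sqrt(denom)
    A[keep, ] <- (Cc %*% t(eb$vectors)) * rep(sS, each = q)
    # f: iid rows, same whitening with unit prior row scale
    if (with_f) {
      FEinv <- chol2inv(safe_chol(FE))
      Bf <- (FEinv * sS) * rep(sS, each = m)
      ef <- eigen((Bf + t(Bf)) / 2, symmetric = TRUE)
      Rf <- Yc
      Rf[keep, ] <- Rf[keep, ] - A[keep, ]
      Wf <- (Rf * rep(1 / sS, each = n)) %*% ef$vectors
      denf <- rep(1 + ef$values, each = n)
      Cf <- Wf / denf + matrix(stats::rnorm(n * m), n, m) / sqrt(denf)
      Ft <- (Cf %*% t(ef$vectors)) * rep(sS, each = n)
    }
    # covariance updates
    if (is.null(fix_ue)) {
      Psi <- priors$ue$scale + crossprod(A[keep, , drop = FALSE] / sqrt(dk))
      UE <- riwish(priors$ue$df + q, Psi)
    }
    if (with_f) {
      Psi <- priors$fe$scale + crossprod(Ft)
      FE <- riwish(priors$fe$df + n, Psi)
    }
    u_mat <- U[, keep, drop = FALSE] %*% A[keep, , drop = FALSE]
    f_mat <- if (with_f) U %*% Ft else 0
    Fit <- matrix(eta, n, m, byrow = TRUE) + u_mat + f_mat
    if (is.null(fix_sigma)) {
      sse <- colSums((Y - Fit)^2)
      df <- priors$sigma$nu + n
      Sigma <- vapply(seq_len(m), function(j) {
        rinvchisq(1, df, (priors$sigma$nu * priors$sigma$S[j] + sse[j]) / df)
      }, 0)
    }
    if (it %% 250L == 0L && (anyNA(Fit) || any(!is.finite(Sigma)))) {
      stop("Gibbs sampler diverged at iteration ", it)
    }
    if (it > cfg$burn_in && (it - cfg$burn_in - 1L) %% cfg$thin == 0L) {
      n_kept <- n_kept + 1L
      chains[n_kept, ] <- c(UE[upper.tri(UE, diag = TRUE)],
                            if (with_f) FE[upper.tri(FE, diag = TRUE)],
                            Sigma)
      pred_sum <- pred_sum + Fit
      UE_sum <- UE_sum + UE
      if (with_f) FE_sum <- FE_sum + FE
      Sigma_sum <- Sigma_sum + Sigma
      eta_sum <- eta_sum + eta
    }
  }

  chains <- chains[seq_len(n_kept), , drop = FALSE]
  fitted_grid <- pred_sum / n_kept
  dimnames(fitted_grid) <- list(trial$line_ids, trial$env_ids)
  UE_mean <- UE_sum / n_kept
  dimnames(UE_mean) <- list(trial$env_ids, trial$env_ids)
  FE_mean <- if (with_f) {
    FEm <- FE_sum / n_kept
    dimnames(FEm) <- list(trial$env_ids, trial$env_ids)
    FEm
  } else NULL
  Sigma_mean <- stats::setNames(Sigma_sum / n_kept, trial$env_ids)
  eta_mean <- eta_sum / n_kept
  mu <- mean(eta_mean)
  vc <- data.frame(component = vc_names, mean = colMeans(chains),
                   sd = apply(chains, 2, stats::sd), stringsAsFactors = FALSE)
  rownames(vc) <- NULL
  out <- list(model = if (with_f) "MUCf" else "MUC", kernel_method = K$method,
              UE = UE_mean, FE = FE_mean, Sigma = Sigma_mean, vc = vc,
              fixed = list(mu = mu,
                           betaE = stats::setNames(eta_mean - mu, trial$env_ids)),
              predictions = fitted_grid[cbind(line_idx, env_idx)],
              fitted_grid = fitted_grid, chains = chains, n_kept = n_kept,
              n_jitter = n_jitter, mask = mask, trial = trial, cfg = cfg)
  class(out) <- c("muc_fit", "gp_fit")
  out
}

utri_names <- function(env_ids) {
  m <- length(env_ids)
  idx <- which(upper.tri(diag(m), diag = TRUE), arr.ind = TRUE)
  mk <- function(pre) {
    vapply(seq_len(nrow(idx)), function(k) {
      i <- idx[k, 1]; j <- idx[k, 2]
      if (i == j) paste0(pre, "_var_", env_ids[i])
      else paste0(pre, "_cov_", env_ids[i], "_", env_ids[j])
    }, "")
  }
  list(ue = mk("UE"), fe = mk("FE"))
}

#' @export
print.muc_fit <- function(x, ...) {
  cat(sprintf("muc_fit: model %s-%s, %d kept samples (%d jittered draws)\n",
              x$model, x$kernel_method, x$n_kept, x$n_jitter))
  cat("posterior mean UE:\n"); print(x$UE, digits = 4)
  if (!is.null(x$FE)) { cat("posterior mean FE:\n"); print(x$FE, digits = 4) }
  cat("posterior mean residual variances:\n"); print(x$Sigma, digits = 4)
  invisible(x)
}

#' Between-environment genetic correlations
#'
#' Converts the unstructured genetic covariance UE to a correlation matrix
#' r[j, j'] = cov[j, j'] / sqrt(var[j] var[j']).
#'
#' @param E a `muc_fit` or an m x m positive-definite covariance matrix.
#' @return m x m correlation matrix with unit diagonal.
#' @export
env_correlations <- function(E) {
  UE <- if (inherits(E, "muc_fit")) E$UE else as.matrix(E)
  if (any(diag(UE) <= 0)) stop("UE must have positive diagonal")
  stats::cov2cor(UE)
}

#' Export the posterior mean environment covariance matrices to CSV
#'
#' @param fit a `muc_fit`.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
export_env_covariances <- function(fit, dir) {
  stopifnot(inherits(fit, "muc_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(dir, "UE.csv")
  utils::write.csv(fit$UE, f)
  files <- c(files, f)
  if (!is.null(fit$FE)) {
    f <- file.path(dir, "FE.csv")
    utils::write.csv(fit$FE, f)
    files <- c(files, f)
  }
  f <- file.path(dir, "Sigma.csv")
  utils::write.csv(data.frame(env = names(fit$Sigma), sigma2 = fit$Sigma), f,
                   row.names = FALSE)
  invisible(c(files, f))
}
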