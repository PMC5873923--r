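#' MCMC configuration
#'
#' @param n_iter total Gibbs iterations. Default 12000.
#' @param burn_in iterations discarded before summarizing. Default 2000.
#' @param thin keep every `thin`-th post-burn-in draw. Default 5.
#' @param seed integer seed; every fit is bit-reproducible under it.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 12000, burn_in = 2000, thin = 5, seed = 1) {
  stopifnot(burn_in < n_iter, thin >= 1, n_iter >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Scaled-inverse-chi-square draws
#'
#' sigma2 ~ nu * S / chisq(nu); the conjugate prior/full-conditional family of
#' every scalar variance component in the package. Mean S*nu/(nu-2) for nu > 2.
#'
#' @param n number of draws.
#' @param nu degrees of freedom (> 0).
#' @param S scale (> 0).
#' @return numeric vector of draws.
#' @export
rinvchisq <- function(n, nu, S) {
  stopifnot(nu > 0, S > 0)
  nu * S / stats::rchisq(n, df = nu)
}

#' Default variance-component priors
#'
#' Scaled-inverse-chi-square priors with nu = 5 for each model-wide component.
#' Scales are set so the prior mode of each non-residual component equals
#' var(y) * R2 / k (R2 = 0.5 split equally over the k non-residual model
#' terms) and the residual mode equals var(y) * (1 - R2). The mode of a
#' scaled-inverse-chi-square is nu * S / (nu + 2).
#'
#' Environment-specific G x E variances are informed by a single environment's
#' records only; a nu = 5 prior with the full term mode measurably inflates
#' their posterior means in that data-poor setting. They therefore get a
#' lighter prior: nu = 3 with the deviation-term mode split across the m
#' environments.
#'
#' @param trial a `trial_data` (only the phenotypic variance is used).
#' @param model model name (any of the eight).
#' @param nu prior degrees of freedom, default 5.
#' @param r2 prior fraction of variance assigned to the genetic terms,
#'   default 0.5.
#' @return named list mapping each variance symbol (`sigma_g2`, `sigma_ge2`,
#'   `sigma_gE2`, `sigma_l2`, `sigma2`) to `list(nu, S)`.
#' @export
default_priors <- function(trial, model = "MDs", nu = 5, r2 = 0.5) {
  vy <- stats::var(trial$records$value)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  comps <- if (model %in% kronecker_models) c("g") else model_components(model)
  k <- length(comps)
  mode_to_S <- function(mode) mode * (nu + 2) / nu
  pri <- list(sigma2 = list(nu = nu, S = mode_to_S(vy * (1 - r2))))
  term_mode <- vy * r2 / k
  for (cm in comps) {
    sym <- switch(cm, g = "sigma_g2", ge = "sigma_ge2", gE = "sigma_gE2",
                  l = "sigma_l2")
    if (cm == "gE") {
      nu_gE <- 3
      pri[[sym]] <- list(nu = nu_gE,
                         S = (term_mode / trial$m) * (nu_gE + 2) / nu_gE)
    } else {
      pri[[sym]] <- list(nu = nu, S = mode_to_S(term_mode))
    }
  }
  pri
}

#' Eigen-rotation of a PSD covariance structure
#'
#' Decomposes C = U D U' and drops eigenvalues below `tol * max(eigenvalue)`.
#' Effects with covariance sigma^2 C are then sampled as U b with independent
#' prior variances sigma^2 * D, which makes every Gibbs full conditional
#' diagonal.
#'
#' @param C symmetric PSD matrix.
#' @param tol relative truncation tolerance, default 1e-10.
#' @return list with `U` (n x q eigenvectors), `d` (q retained eigenvalues),
#'   `rank` (q), and `n`.
#' @export
eigen_rotate <- function(C, tol = 1e-10) {
  C <- as.matrix(C)
  if (max(abs(C - t(C))) > 1e-10) stop("structure is not symmetric")
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lmax <- max(e$values, 0)
  if (min(e$values) < -1e-8 * max(lmax, .Machine$double.eps)) {
    stop(sprintf("structure is not numerically PSD (min eigenvalue %.3e)",
                 min(e$values)))
  }
  keep <- e$values > tol * lmax
  if (!any(keep)) stop("structure has no retained eigenvalues")
  list(U = e$vectors[, keep, drop = FALSE], d = e$values[keep],
       rank = sum(keep), n = nrow(C))
}

#' Prior predictive check of the variance-component priors
#'
#' Draws each variance component from its prior with the likelihood disabled
#' (the Geweke-style degenerate Gibbs step: with no data contribution the full
#' conditional is the prior itself) and reports sample moments next to the
#' closed-form prior mean S * nu / (nu - 2).
#'
#' @param priors named list as returned by [default_priors()].
#' @param n_draws number of prior draws per component, default 10000.
#' @param seed RNG seed.
#' @return data.frame with columns `component`, `nu`, `S`, `sample_mean`,
#'   `sample_sd`, `prior_mean` (`NA` when nu <= 2, where the mean is
#'   undefined).
#' @export
prior_sanity <- function(priors, n_draws = 10000, seed = 1) {
  set.seed(seed)
  rows <- lapply(names(priors), function(nm) {
    p <- priors[[nm]]
    x <- rinvchisq(n_draws, p$nu, p$S)
    data.frame(component = nm, nu = p$nu, S = p$S,
               sample_mean = mean(x), sample_sd = stats::sd(x),
               prior_mean = if (p$nu > 2) p$S * p$nu / (p$nu - 2) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## ---------------------------------------------------------------------------
## Gibbs sampler for the Hadamard family, on the complete line x environment
## grid. Structurally unobserved cells and CV-masked records are latent and
## re-imputed from the model every iteration (data augmentation), which keeps
## every full conditional diagonal in the kernel eigenbasis and guarantees
## that masked phenotypes never enter any likelihood term.
## ---------------------------------------------------------------------------

#' Fit a Hadamard-family multi-environment model by Gibbs sampling
#'
#' Models MM, MMl, MDs, MDsl, MDe, MDel: y = mu 1 + ZE betaE + Zg g
#' (+ ge or gE) (+ Zg l) + eps, with g ~ N(0, sigma_g2 K), the G x E
#' deviations kernel-structured within environment, l ~ N(0, sigma_l2 I) and
#' homogeneous residual variance. Fixed effects get a flat prior; every
#' variance a scaled-inverse-chi-square prior.
#'
#' @param trial a `trial_data`.
#' @param model one of `"MM"`, `"MMl"`, `"MDs"`, `"MDsl"`, `"MDe"`, `"MDel"`.
#' @param K a `kernel_matrix` covering every trial line.
#' @param priors named prior list, default [default_priors()].
#' @param cfg an [mcmc_config()].
#' @param mask optional integer indices of trial records to treat as missing
#'   (cross-validation test set); they are excluded from every likelihood term
#'   and predicted.
#' @param fix_variances optional named numeric vector of variance components
#'   to hold fixed (their Gibbs updates are disabled), e.g.
#'   `c(sigma_g2 = 0.5, sigma2 = 1)`. Environment-specific variances use
#'   `sigma_gE2_<env>` names.
#' @return An object of class `gp_fit` with elements `vc` (posterior mean and
#'   SD per variance component), `fixed` (`mu`, `betaE` under the sum-to-zero
#'   parameterization), `predictions` (posterior mean of mu + ZE betaE + all
#'   random effects for every trial record, canonical order; residual
#'   excluded), `fitted_grid` (n x m posterior-mean surface), `chains` (kept
#'   variance-component draws), `n_kept`, and bookkeeping fields.
#' @export
fit_gp <- function(trial, model, K, priors = NULL, cfg = mcmc_config(),
                   mask = NULL, fix_variances = NULL) {
  stopifnot(inherits(trial, "trial_data"), inherits(K, "kernel_matrix"),
            inherits(cfg, "mcmc_config"))
  model <- match.arg(model, hadamard_models)
  comps <- model_components(model)
  has_ge <- "ge" %in% comps
  has_gE <- "gE" %in% comps
  has_l <- "l" %in% comps
  if (!is.null(mask)) {
    mask <- as.integer(mask)
    if (length(mask) == 0) mask <- NULL
    else stopifnot("mask indices out of range" = all(mask >= 1 & mask <= trial$N))
  }
  if (is.null(priors)) {
    # priors are set from the training records only, so masked phenotypes
    # cannot influence the fit through the prior scales
    obs_records <- if (is.null(mask)) trial$records else trial$records[-mask, ]
    priors <- default_priors(trial_data(obs_records, env_order = trial$env_ids),
                             model)
  }

  n <- trial$n; m <- trial$m
  line_idx <- match(trial$records$line, trial$line_ids)
  env_idx <- match(trial$records$env, trial$env_ids)
  O <- matrix(FALSE, n, m)
  O[cbind(line_idx, env_idx)] <- TRUE
  O[cbind(line_idx[mask], env_idx[mask])] <- FALSE
  obs_per_env <- colSums(O)
  if (any(obs_per_env == 0)) {
    stop("environment(s) without any observed record: ",
         paste(trial$env_ids[obs_per_env == 0], collapse = ", "))
  }

  Y <- matrix(NA_real_, n, m)
  Y[cbind(line_idx, env_idx)] <- trial$records$value
  Y[cbind(line_idx[mask], env_idx[mask])] <- NA_real_
  env_means <- vapply(seq_len(m), function(j) mean(Y[O[, j], j]), 0)
  miss <- which(!O)
  n_miss <- length(miss)
  miss_col <- ((miss - 1L) %/% n) + 1L
  Y[miss] <- env_means[miss_col]

  eig <- eigen_rotate(subset_kernel(K, trial$line_ids))
  U <- eig$U; d <- eig$d; q <- eig$rank

  nuS <- function(sym, fallback) {
    p <- priors[[sym]]
    if (is.null(p)) p <- priors[[fallback]]
    if (is.null(p)) stop("no prior for component ", sym)
    p
  }
  fixed_vc <- function(sym) !is.null(fix_variances) && sym %in% names(fix_variances)
  init_vc <- function(sym, fallback = sym) {
    if (fixed_vc(sym)) unname(fix_variances[[sym]]) else nuS(sym, fallback)$S
  }

  sigma2 <- init_vc("sigma2")
  sigma_g2 <- init_vc("sigma_g2")
  sigma_ge2 <- if (has_ge) init_vc("sigma_ge2") else NULL
  gE_syms <- if (has_gE) paste0("sigma_gE2_", trial$env_ids) else character(0)
  sigma_gE2 <- if (has_gE) {
    vapply(gE_syms, function(s) init_vc(s, "sigma_gE2"), 0)
  } else NULL
  sigma_l2 <- if (has_l) init_vc("sigma_l2") else NULL

  eta <- env_means
  a_g <- numeric(q)
  g_vec <- numeric(n)
  A_ge <- if (has_ge || has_gE) matrix(0, q, m) else NULL
  GE <- if (has_ge || has_gE) matrix(0, n, m) else NULL
  l_vec <- if (has_l) numeric(n) else NULL

  vc_names <- c("sigma2", "sigma_g2",
                if (has_ge) "sigma_ge2", if (has_gE) gE_syms,
                if (has_l) "sigma_l2")
  kept_iters <- seq(cfg$burn_in + 1L, cfg$n_iter)
  kept_iters <- kept_iters[(seq_along(kept_iters) - 1L) %% cfg$thin == 0L]
  chains <- matrix(NA_real_, length(kept_iters), length(vc_names),
                   dimnames = list(NULL, vc_names))
  pred_sum <- matrix(0, n, m)
  eta_sum <- numeric(m)
  n_kept <- 0L

  set.seed(cfg$seed)
  for (it in seq_len(cfg$n_iter)) {
    Fit <- matrix(eta, n, m, byrow = TRUE) + g_vec
    if (!is.null(GE)) Fit <- Fit + GE
    if (has_l) Fit <- Fit + l_vec
    # impute latent cells from the current model state
    if (n_miss > 0) {
      Y[miss] <- Fit[miss] + stats::rnorm(n_miss, sd = sqrt(sigma2))
    }
    # environment means (flat prior)
    R <- Y - g_vec
    if (!is.null(GE)) R <- R - GE
    if (has_l) R <- R - l_vec
    eta <- colMeans(R) + stats::rnorm(m, sd = sqrt(sigma2 / n))
    # kernel main effect, rotated coordinates
    Rg <- Y - matrix(eta, n, m, byrow = TRUE)
    if (!is.null(GE)) Rg <- Rg - GE
    if (has_l) Rg <- Rg - l_vec
    v <- 1 / (m / sigma2 + 1 / (sigma_g2 * d))
    a_g <- v * (crossprod(U, rowSums(Rg)) / sigma2) + sqrt(v) * stats::rnorm(q)
    a_g <- drop(a_g)
    g_vec <- drop(U %*% a_g)
    # G x E deviations
    if (has_ge || has_gE) {
      Rge <- Y - matrix(eta, n, m, byrow = TRUE) - g_vec
      if (has_l) Rge <- Rge - l_vec
      Tt <- crossprod(U, Rge)
      if (has_ge) {
        v <- 1 / (1 / sigma2 + 1 / (sigma_ge2 * d))
        A_ge <- v * Tt / sigma2 + sqrt(v) * matrix(stats::rnorm(q * m), q, m)
      } else {
        for (j in seq_len(m)) {
          v <- 1 / (1 / sigma2 + 1 / (sigma_gE2[j] * d))
          A_ge[, j] <- v * Tt[, j] / sigma2 + sqrt(v) * stats::rnorm(q)
        }
      }
      GE <- U %*% A_ge
    }
    # iid line intercept
    if (has_l) {
      Rl <- Y - matrix(eta, n, m, byrow = TRUE) - g_vec
      if (!is.null(GE)) Rl <- Rl - GE
      v <- 1 / (m / sigma2 + 1 / sigma_l2)
      l_vec <- v * rowSums(Rl) / sigma2 + sqrt(v) * stats::rnorm(n)
    }
    # variance components
    if (!fixed_vc("sigma_g2")) {
      p <- nuS("sigma_g2", "sigma_g2")
      df <- p$nu + q
      sigma_g2 <- rinvchisq(1, df, (p$nu * p$S + sum(a_g^2 / d)) / df)
    }
    if (has_ge && !fixed_vc("sigma_ge2")) {
      p <- nuS("sigma_ge2", "sigma_ge2")
      df <- p$nu + q * m
      sigma_ge2 <- rinvchisq(1, df, (p$nu * p$S + sum(A_ge^2 / d)) / df)
    }
    if (has_gE) {
      for (j in seq_len(m)) {
        if (fixed_vc(gE_syms[j])) next
        p <- nuS(gE_syms[j], "sigma_gE2")
        df <- p$nu + q
        sigma_gE2[j] <- rinvchisq(1, df, (p$nu * p$S + sum(A_ge[, j]^2 / d)) / df)
      }
    }
    if (has_l && !fixed_vc("sigma_l2")) {
      p <- nuS("sigma_l2", "sigma_l2")
      df <- p$nu + n
      sigma_l2 <- rinvchisq(1, df, (p$nu * p$S + sum(l_vec^2)) / df)
    }
    Fit <- matrix(eta, n, m, byrow = TRUE) + g_vec
    if (!is.null(GE)) Fit <- Fit + GE
    if (has_l) Fit <- Fit + l_vec
    if (!fixed_vc("sigma2")) {
      p <- nuS("sigma2", "sigma2")
      df <- p$nu + n * m
      sigma2 <- rinvchisq(1, df, (p$nu * p$S + sum((Y - Fit)^2)) / df)
    }
    if (it %% 250L == 0L && (!is.finite(sigma2) || anyNA(Fit))) {
      stop("Gibbs sampler diverged at iteration ", it)
    }
    # accumulate kept draws
    if (it > cfg$burn_in && (it - cfg$burn_in - 1L) %% cfg$thin == 0L) {
      n_kept <- n_kept + 1L
      chains[n_kept, ] <- c(sigma2, sigma_g2,
                            if (has_ge) sigma_ge2, if (has_gE) sigma_gE2,
                            if (has_l) sigma_l2)
      pred_sum <- pred_sum + Fit
      eta_sum <- eta_sum + eta
    }
  }

  fitted_grid <- pred_sum / n_kept
  dimnames(fitted_grid) <- list(trial$line_ids, trial$env_ids)
  eta_mean <- eta_sum / n_kept
  mu <- mean(eta_mean)
  betaE <- stats::setNames(eta_mean - mu, trial$env_ids)
  vc <- data.frame(component = vc_names,
                   mean = colMeans(chains),
                   sd = apply(chains, 2, stats::sd),
                   stringsAsFactors = FALSE)
  rownames(vc) <- NULL
  out <- list(model = model, kernel_method = K$method, vc = vc,
              fixed = list(mu = mu, betaE = betaE),
              predictions = fitted_grid[cbind(line_idx, env_idx)],
              fitted_grid = fitted_grid, chains = chains, n_kept = n_kept,
              mask = mask, trial = trial, cfg = cfg)
  class(out) <- "gp_fit"
  out
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("gp_fit: model %s-%s, %d kept samples\n",
              x$model, x$kernel_method, x$n_kept))
  print(x$vc, digits = 4)
  invisible(x)
}

#' Posterior-mean variance components of a fit
#'
#' @param fit a `gp_fit` or `muc_fit`.
#' @return named numeric vector of posterior means.
#' @export
variance_components <- function(fit) {
  stats::setNames(fit$vc$mean, fit$vc$component)
}

#' Export variance-component chains to CSV
#'
#' One row per kept iteration, one column per component; for convergence
#' diagnostics in external tools.
#'
#' @param fit a `gp_fit` or `muc_fit`.
#' @param path output path.
#' @export
export_chains <- function(fit, path) {
  utils::write.csv(as.data.frame(fit$chains), path, row.names = FALSE)
  invisible(path)
}

#' Export a posterior summary to JSON
#'
#' @param fit a `gp_fit` or `muc_fit`.
#' @param path output path.
#' @export
export_summary <- function(fit, path) {
  s <- list(model = fit$model, kernel = fit$kernel_method,
            n_kept = fit$n_kept,
            variance_components = stats::setNames(
              lapply(seq_len(nrow(fit$vc)),
                     function(i) list(mean = fit$vc$mean[i], sd = fit$vc$sd[i])),
              fit$vc$component))
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
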