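# Independent oracles used across test files. These are deliberately naive:
# dense GLS / mixed-model-equation solves and brute-force simulation, never
# the package's samplers.

# GLS fitted values (environment fixed effects + BLUP of all random effects)
# for a Hadamard-family model at KNOWN variance components, built from the
# dense covariance structures.
gls_oracle <- function(trial, model, K, variances) {
  D <- build_incidence(trial)
  V <- model_covariance(trial, model, K, variances)
  X <- D$ZE
  y <- trial$records$value
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  G <- V - diag(variances$sigma2, trial$N)   # covariance of all random effects
  drop(X %*% beta + G %*% Vi %*% (y - X %*% beta))
}

# Brute-force draws from the generative law of a Hadamard-family model, at the
# record level, using incidence maps and Cholesky factors of K (plus a small
# ridge for rank-deficient kernels); independent of the eigenbasis route the
# package uses both to simulate and to fit.
brute_force_draws <- function(trial, model, K, variances, n_draws) {
  D <- build_incidence(trial)
  comps <- model_components(model)
  n <- trial$n; m <- trial$m; N <- trial$N
  Ksub <- K$K[trial$line_ids, trial$line_ids]
  L <- t(chol(Ksub + diag(1e-10, n)))
  Y <- matrix(0, n_draws, N)
  if ("g" %in% comps) {
    g <- t(L %*% matrix(rnorm(n * n_draws), n)) * sqrt(variances$sigma_g2)
    Y <- Y + g[, D$line_idx, drop = FALSE]
  }
  if ("ge" %in% comps || "gE" %in% comps) {
    for (j in seq_len(m)) {
      s2 <- if ("ge" %in% comps) variances$sigma_ge2 else
        variances[[paste0("sigma_gE2_", trial$env_ids[j])]]
      gj <- t(L %*% matrix(rnorm(n * n_draws), n)) * sqrt(s2)
      rec <- which(D$env_idx == j)
      Y[, rec] <- Y[, rec] + gj[, D$line_idx[rec], drop = FALSE]
    }
  }
  if ("l" %in% comps) {
    l <- matrix(rnorm(n * n_draws, sd = sqrt(variances$sigma_l2)), n_draws, n)
    Y <- Y + l[, D$line_idx, drop = FALSE]
  }
  Y + matrix(rnorm(N * n_draws, sd = sqrt(variances$sigma2)), n_draws, N)
}

# small simulated data set shared by several test files
quick_sim <- function(model = "MDs", n = 60, m = 3, p = 120, families = 12,
                      variances = list(sigma_g2 = 0.6, sigma_ge2 = 0.4,
                                       sigma_l2 = 0.3, sigma2 = 1),
                      seed = 1, ...) {
  spec <- sim_spec(model = model, n_lines = n, n_markers = p, m = m,
                   n_families = families, variances = variances, seed = seed,
                   ...)
  simulate_trial(spec)
}

quick_cfg <- function(n_iter = 600, burn_in = 200, thin = 2, seed = 99) {
  mcmc_config(n_iter, burn_in, thin, seed)
}
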