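#' Simulate a marker dosage matrix
#'
#' Dosages are Binomial(2, q_k) counts with per-marker allele frequencies q_k
#' uniform on `maf_range`. With `n_families > 1`, lines are grouped into
#' families and each family draws its own allele frequency around q_k from a
#' Balding-Nichols Beta distribution with differentiation `fst`; this induces
#' the family relatedness structure typical of breeding populations, without
#' which the realized genomic relationship matrix is numerically close to the
#' identity and the kernel main effect cannot be distinguished from an iid
#' line intercept.
#'
#' @param n number of lines.
#' @param p number of markers (independent loci; no linkage).
#' @param maf_range allele-frequency range, subset of (0, 0.5].
#' @param n_families number of equally sized families; 1 = unrelated lines.
#' @param fst between-family differentiation in (0, 1); ignored when
#'   `n_families = 1`. Default 0.15 when families are requested.
#' @param seed RNG seed.
#' @return A raw `marker_matrix` in 0/1/2 coding with line ids `L0001`, ...
#' @export
simulate_markers <- function(n, p, maf_range = c(0.05, 0.5), n_families = 1,
                             fst = 0.15, seed = 1) {
  stopifnot(n >= 2, p >= 1, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  set.seed(seed)
  q <- stats::runif(p, maf_range[1], maf_range[2])
  if (n_families > 1) {
    stopifnot(fst > 0, fst < 1)
    fam <- rep_len(seq_len(n_families), n)
    a <- q * (1 - fst) / fst
    b <- (1 - q) * (1 - fst) / fst
    X <- matrix(0, n, p)
    for (f in seq_len(n_families)) {
      qf <- stats::rbeta(p, a, b)
      rows <- which(fam == f)
      X[rows, ] <- matrix(stats::rbinom(length(rows) * p, 2, rep(qf, each = length(rows))),
                          length(rows), p)
    }
  } else {
    X <- matrix(stats::rbinom(n * p, 2, rep(q, each = n)), n, p)
  }
  ids <- sprintf("L%04d", seq_len(n))
  colnames(X) <- sprintf("M%05d", seq_len(p))
  M <- marker_matrix(X, line_ids = ids, coding = "012")
  attr(M, "true_maf") <- q
  M
}

#' Specification of a synthetic multi-environment trial
#'
#' Collects the generative model, its variance components, the trial geometry
#' and the unbalance pattern. Defaults describe a mid-size trial with moderate
#' heritability.
#'
#' @param model generative model, one of the eight model names.
#' @param n_lines,n_markers,maf_range,n_families,fst marker/population
#'   geometry, see [simulate_markers()].
#' @param m number of environments.
#' @param variances named list: `sigma_g2`, `sigma_ge2`, `sigma_gE2` (length-m
#'   vector), `sigma_l2`, `sigma2` as the generative model requires; for MUC /
#'   MUCf instead `UE` (m x m), optionally `FE` (m x m), and `Sigma` (length-m
#'   residual variances).
#' @param mu overall mean.
#' @param beta_env environment effects (length m, sum need not be zero).
#' @param env_counts optional per-environment number of observed lines
#'   (unbalance by deletion); `NULL` = balanced.
#' @param epistasis_fraction share of the kernel-structured genetic signal
#'   drawn with covariance proportional to the elementwise square K o K
#'   (pairwise-interaction signal a Gaussian kernel captures better than the
#'   linear kernel). Default 0.
#' @param seed RNG seed.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(model = "MDs", n_lines = 300, n_markers = 600,
                     maf_range = c(0.05, 0.5), n_families = 30, fst = 0.15,
                     m = 4, variances = list(sigma_g2 = 0.6, sigma_ge2 = 0.4,
                                             sigma_l2 = 0.3, sigma2 = 1.0),
                     mu = 5, beta_env = NULL, env_counts = NULL,
                     epistasis_fraction = 0, seed = 1) {
  model <- match.arg(model, all_models())
  if (is.null(beta_env)) beta_env <- seq(-0.5, 0.5, length.out = m)
  stopifnot(length(beta_env) == m,
            epistasis_fraction >= 0, epistasis_fraction <= 1)
  if (!is.null(env_counts)) {
    stopifnot(length(env_counts) == m, all(env_counts <= n_lines),
              all(env_counts >= 1))
  }
  structure(list(model = model, n_lines = n_lines, n_markers = n_markers,
                 maf_range = maf_range, n_families = n_families, fst = fst,
                 m = m, variances = variances, mu = mu, beta_env = beta_env,
                 env_counts = env_counts,
                 epistasis_fraction = epistasis_fraction, seed = seed),
            class = "sim_spec")
}

# draw n-vector(s) with covariance s2 * K, exactly, in the kernel eigenbasis
draw_kernel_effect <- function(eig, s2, ncol = 1) {
  Z <- matrix(stats::rnorm(eig$rank * ncol), eig$rank, ncol)
  eig$U %*% (sqrt(s2 * eig$d) * Z)
}

#' Simulate a multi-environment trial from a generative model
#'
#' Draws every random component from its stated normal law using the linear
#' kernel built from `M` (true effects are drawn in the kernel eigenbasis, so
#' Var(g) = sigma_g2 K holds by construction, not just in expectation over
#' marker sampling). A nonzero `epistasis_fraction` replaces that share of the
#' kernel-structured variance with a component whose covariance is the
#' normalized elementwise square of K. Unbalance is applied by deleting cells.
#'
#' @param spec a [sim_spec()].
#' @param M optional `marker_matrix`; simulated from the spec when omitted.
#' @return list with `trial` (a `trial_data`), `truth` (true effect vectors,
#'   true per-cell genetic values `genetic_grid`, the variance parameters and
#'   the generating kernel), and `markers`.
#' @export
simulate_trial <- function(spec, M = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (is.null(M)) {
    M <- simulate_markers(spec$n_lines, spec$n_markers, spec$maf_range,
                          spec$n_families, spec$fst, seed = spec$seed)
  }
  n <- nrow(M$X); m <- spec$m
  stopifnot(n == spec$n_lines)
  K <- linear_kernel(filter_markers(M, maf_min = 0.01, max_missing = 0))
  eig <- eigen_rotate(K$K)
  phi <- spec$epistasis_fraction
  eig2 <- NULL
  if (phi > 0) {
    K2 <- K$K * K$K
    K2 <- K2 / mean(diag(K2))   # unit average diagonal, same scale as K
    eig2 <- eigen_rotate(K2)
  }
  v <- spec$variances
  set.seed(spec$seed + 1L)

  draw_genetic <- function(s2, ncol = 1) {
    out <- draw_kernel_effect(eig, s2 * (1 - phi), ncol)
    if (phi > 0) out <- out + draw_kernel_effect(eig2, s2 * phi, ncol)
    out
  }

  env_ids <- sprintf("E%d", seq_len(m))
  line_ids <- M$line_ids
  truth <- list(variances = v, model = spec$model, kernel = K,
                epistasis_fraction = phi)
  Gen <- matrix(spec$mu, n, m, byrow = TRUE) +
    matrix(spec$beta_env, n, m, byrow = TRUE)

  if (spec$model %in% kronecker_models) {
    UE <- as.matrix(v$UE)
    stopifnot(nrow(UE) == m)
    # u ~ N(0, UE (x) K): rows in kernel eigenbasis, columns mixed by chol(UE)
    Zu <- draw_genetic(1, ncol = m)
    u <- Zu %*% chol(UE)
    Gen <- Gen + u
    truth$u <- u
    if (spec$model == "MUCf") {
      FE <- as.matrix(v$FE)
      f <- matrix(stats::rnorm(n * m), n, m) %*% chol(FE)
      Gen <- Gen + f
      truth$f <- f
    }
    Sigma <- as.numeric(v$Sigma)
    E <- matrix(stats::rnorm(n * m), n, m) * rep(sqrt(Sigma), each = n)
  } else {
    comps <- model_components(spec$model)
    g <- drop(draw_genetic(v$sigma_g2))
    Gen <- Gen + g
    truth$g <- g
    if ("ge" %in% comps) {
      ge <- draw_genetic(v$sigma_ge2, ncol = m)
      Gen <- Gen + ge
      truth$ge <- ge
    }
    if ("gE" %in% comps) {
      sgE <- v$sigma_gE2
      stopifnot(length(sgE) == m)
      gE <- vapply(seq_len(m), function(j) drop(draw_genetic(sgE[j])), numeric(n))
      Gen <- Gen + gE
      truth$gE <- gE
    }
    if ("l" %in% comps) {
      l <- stats::rnorm(n, sd = sqrt(v$sigma_l2))
      Gen <- Gen + l
      truth$l <- l
    }
    E <- matrix(stats::rnorm(n * m, sd = sqrt(v$sigma2)), n, m)
  }
  Y <- Gen + E
  dimnames(Y) <- list(line_ids, env_ids)
  dimnames(Gen) <- dimnames(Y)
  truth$genetic_grid <- Gen

  if (!is.null(spec$env_counts)) {
    for (j in seq_len(m)) {
      drop_n <- n - spec$env_counts[j]
      if (drop_n > 0) Y[sample(n, drop_n), j] <- NA_real_
    }
  }
  list(trial = to_long(Y), truth = truth, markers = M)
}

#' Scenario presets mimicking published multi-environment data sets
#'
#' Returns a `sim_spec` whose geometry (lines, environments, unbalance) and
#' variance-component magnitudes are borrowed scales from published
#' multi-environment maize and wheat trials: `HEL_like` (5 sites, strongly
#' unbalanced, positive between-environment correlations), `USP_like` (4
#' artificial environments, mild unbalance, weak G x E), `WHE1_like` (4
#' mega-environments, one negatively correlated with the rest, unstructured
#' covariance generative model), `WHE5_like` (5 environments, balanced,
#' dominant G x E). These are scenario calibrations, not reproduction targets.
#'
#' @param name one of `"HEL_like"`, `"USP_like"`, `"WHE1_like"`, `"WHE5_like"`.
#' @param seed RNG seed stored in the spec.
#' @return A `sim_spec`.
#' @export
preset <- function(name = c("HEL_like", "USP_like", "WHE1_like", "WHE5_like"),
                   seed = 1) {
  name <- match.arg(name)
  switch(name,
    HEL_like = sim_spec(
      model = "MDsl", n_lines = 452, n_markers = 1500, n_families = 45,
      m = 5,
      variances = list(sigma_g2 = 0.938, sigma_ge2 = 0.525, sigma_l2 = 0.013,
                       sigma2 = 0.278),
      mu = 6, beta_env = c(-0.6, -0.2, 0, 0.3, 0.5),
      env_counts = c(247, 330, 452, 367, 330), seed = seed),
    USP_like = sim_spec(
      model = "MDsl", n_lines = 739, n_markers = 1500, n_families = 70,
      m = 4,
      variances = list(sigma_g2 = 0.343, sigma_ge2 = 0.091, sigma_l2 = 0.296,
                       sigma2 = 0.49),
      mu = 5, beta_env = c(-0.4, 0.1, -0.1, 0.4),
      env_counts = c(731, 732, 731, 737), seed = seed),
    WHE1_like = {
      # one environment negatively correlated with the other three
      r <- matrix(0.5, 4, 4); diag(r) <- 1
      r[1, 2:4] <- r[2:4, 1] <- -0.3
      sd_u <- sqrt(c(1.0, 0.55, 0.55, 0.7))
      sim_spec(
        model = "MUC", n_lines = 599, n_markers = 1300, n_families = 60,
        m = 4,
        variances = list(UE = r * (sd_u %o% sd_u),
                         Sigma = rep(0.46, 4)),
        mu = 5, beta_env = c(-0.3, 0, 0.1, 0.2), seed = seed)
    },
    WHE5_like = sim_spec(
      model = "MDs", n_lines = 807, n_markers = 1400, n_families = 80,
      m = 5,
      variances = list(sigma_g2 = 0.16, sigma_ge2 = 1.482, sigma2 = 0.3),
      mu = 5, beta_env = seq(-0.5, 0.5, length.out = 5), seed = seed))
}

#' Write simulation ground truth to JSON
#'
#' @param truth the `truth` element of [simulate_trial()] output.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  out <- list(model = truth$model,
              variances = truth$variances,
              epistasis_fraction = truth$epistasis_fraction,
              genetic_grid = truth$genetic_grid)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
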