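test_that("eigen rotation: identity, rank-1, and reconstruction of random PSD", {
  e1 <- eigen_rotate(diag(4))
  expect_equal(e1$d, rep(1, 4))
  expect_equal(e1$U %*% diag(e1$d) %*% t(e1$U), diag(4), tolerance = 1e-12)

  N <- 7
  e2 <- eigen_rotate(matrix(1, N, N))
  expect_equal(e2$rank, 1L)
  expect_equal(e2$d, N, tolerance = 1e-10)

  set.seed(21)
  for (r in 1:20) {
    A <- matrix(rnorm(36), 6)
    C <- crossprod(A)
    e <- eigen_rotate(C)
    rec <- e$U %*% (e$d * t(e$U))
    expect_lt(norm(rec - C, "F") / norm(C, "F"), 1e-8)
  }
  expect_error(eigen_rotate(diag(c(1, -1))), "PSD")
})

test_that("prior sanity: scaled-inverse-chi-square moments match closed form", {
  pri <- list(sigma_g2 = list(nu = 5, S = 1),
              sigma2 = list(nu = 5, S = 0.3),
              wide = list(nu = 2, S = 1))
  ps <- prior_sanity(pri, n_draws = 200000, seed = 4)
  expect_equal(ps$prior_mean[ps$component == "sigma_g2"], 5 / 3)
  expect_equal(ps$sample_mean[ps$component == "sigma_g2"], 5 / 3,
               tolerance = 0.02)
  expect_equal(ps$prior_mean[ps$component == "sigma2"], 0.5)
  expect_equal(ps$sample_mean[ps$component == "sigma2"], 0.5, tolerance = 0.02)
  expect_true(is.na(ps$prior_mean[ps$component == "wide"]))
  # scale family: doubling S doubles the mean
  ps2 <- prior_sanity(list(a = list(nu = 5, S = 2)), n_draws = 200000, seed = 4)
  expect_equal(ps2$sample_mean / ps$sample_mean[1], 2, tolerance = 0.03)
})

test_that("with all genetic variances pinned at zero the fit is the env means", {
  sim <- quick_sim(model = "MDsl", n = 40, m = 3, p = 80, families = 8,
                   seed = 6)
  tr <- sim$trial
  fit <- fit_gp(tr, "MDsl", sim$truth$kernel,
                cfg = mcmc_config(3000, 500, 1, seed = 2),
                fix_variances = c(sigma_g2 = 1e-10, sigma_ge2 = 1e-10,
                                  sigma_l2 = 1e-10, sigma2 = 1))
  env_means <- tapply(tr$records$value, tr$records$env, mean)
  pred_by_env <- tapply(fit$predictions, tr$records$env, mean)
  expect_equal(unname(pred_by_env[names(env_means)]), unname(env_means),
               tolerance = 0.02)
  expect_lt(max(tapply(fit$predictions, tr$records$env, sd)), 0.01)
})

test_that("identical seed and config replay bit-identical chains", {
  sim <- quick_sim(n = 30, m = 2, p = 60, families = 6, seed = 3)
  cfg <- quick_cfg(seed = 123)
  f1 <- fit_gp(sim$trial, "MDs", sim$truth$kernel, cfg = cfg)
  f2 <- fit_gp(sim$trial, "MDs", sim$truth$kernel, cfg = cfg)
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$predictions, f2$predictions)
  f3 <- fit_gp(sim$trial, "MDs", sim$truth$kernel,
               cfg = quick_cfg(seed = 124))
  expect_false(identical(f1$chains, f3$chains))
})

test_that("posterior means are invariant to the input record order", {
  sim <- quick_sim(n = 30, m = 3, p = 60, families = 6, seed = 9)
  recs <- sim$trial$records
  set.seed(1)
  tr_shuffled <- trial_data(recs[sample(nrow(recs)), ])
  cfg <- quick_cfg(seed = 55)
  f1 <- fit_gp(sim$trial, "MMl", sim$truth$kernel, cfg = cfg)
  f2 <- fit_gp(tr_shuffled, "MMl", sim$truth$kernel, cfg = cfg)
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$predictions, f2$predictions)
})

test_that("MM is nested in MDs: zero GxE data gives small sigma_ge2 and near-identical predictions", {
  ge_hat <- numeric(10)
  cors <- numeric(10)
  for (s in 1:10) {
    sim <- quick_sim(model = "MM", n = 240, m = 4, p = 120, families = 24,
                     fst = 0.2,
                     variances = list(sigma_g2 = 0.8, sigma2 = 0.5), seed = 100 + s)
    cfg <- mcmc_config(1200, 400, 2, seed = s)
    fmds <- fit_gp(sim$trial, "MDs", sim$truth$kernel, cfg = cfg)
    fmm <- fit_gp(sim$trial, "MM", sim$truth$kernel, cfg = cfg)
    ge_hat[s] <- variance_components(fmds)["sigma_ge2"]
    cors[s] <- cor(fmds$predictions, fmm$predictions)
  }
  expect_lt(mean(ge_hat), 0.1)
  expect_gt(mean(cors), 0.99)
})

test_that("an l-model's sigma_g2 + sigma_l2 covers what the plain model absorbs into sigma_g2", {
  tot_l <- numeric(5); tot_plain <- numeric(5)
  for (s in 1:5) {
    sim <- quick_sim(model = "MMl", n = 150, m = 3, p = 100, families = 15,
                     variances = list(sigma_g2 = 0.5, sigma_l2 = 0.5, sigma2 = 0.8),
                     seed = 200 + s)
    cfg <- mcmc_config(900, 300, 2, seed = s)
    vl <- variance_components(fit_gp(sim$trial, "MMl", sim$truth$kernel, cfg = cfg))
    vp <- variance_components(fit_gp(sim$trial, "MM", sim$truth$kernel, cfg = cfg))
    tot_l[s] <- vl["sigma_g2"] + vl["sigma_l2"]
    tot_plain[s] <- vp["sigma_g2"]
  }
  expect_gte(mean(tot_l), mean(tot_plain) - 0.05)
  # and the summed line-level variance tracks the generative total 1.0
  expect_equal(mean(tot_l), 1.0, tolerance = 0.3)
})

test_that("fitting a model misspecified without GxE inflates the residual by ~ the GxE variance", {
  sim <- quick_sim(model = "MDs", n = 300, m = 4, p = 500, families = 30,
                   variances = list(sigma_g2 = 0.5, sigma_ge2 = 0.6, sigma2 = 0.8),
                   seed = 10)
  fmm <- fit_gp(sim$trial, "MM", sim$truth$kernel,
                cfg = mcmc_config(1200, 400, 2, seed = 2))
  inflation <- variance_components(fmm)["sigma2"] - 0.8
  expected <- 0.6 * mean(diag(sim$truth$kernel$K))
  expect_gt(inflation, 0.5 * expected)
  expect_lt(inflation, 1.15 * expected)
})

test_that("empty environments and bad masks are rejected", {
  sim <- quick_sim(n = 20, m = 2, p = 40, families = 4)
  tr <- sim$trial
  mask_all_e1 <- which(tr$records$env == tr$env_ids[1])
  expect_error(fit_gp(tr, "MM", sim$truth$kernel, cfg = quick_cfg(),
                      mask = mask_all_e1), "environment")
  expect_error(fit_gp(tr, "MM", sim$truth$kernel, cfg = quick_cfg(),
                      mask = c(0L)), "mask")
})
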