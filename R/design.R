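#' Incidence matrices of a trial
#'
#' Realizes the environment incidence ZE (N x m) and the line incidence Zg
#' (N x n) for the records of a trial, in the canonical environment-major
#' record order. Each row of each matrix carries exactly one 1.
#'
#' @param trial a `trial_data`.
#' @return list with `ZE`, `Zg`, and the integer cell indices `env_idx`,
#'   `line_idx` of each record.
#' @export
build_incidence <- function(trial) {
  stopifnot(inherits(trial, "trial_data"))
  env_idx <- match(trial$records$env, trial$env_ids)
  line_idx <- match(trial$records$line, trial$line_ids)
  ZE <- matrix(0, trial$N, trial$m, dimnames = list(NULL, trial$env_ids))
  ZE[cbind(seq_len(trial$N), env_idx)] <- 1
  Zg <- matrix(0, trial$N, trial$n, dimnames = list(NULL, trial$line_ids))
  Zg[cbind(seq_len(trial$N), line_idx)] <- 1
  list(ZE = ZE, Zg = Zg, env_idx = env_idx, line_idx = line_idx)
}

subset_kernel <- function(K, line_ids) {
  stopifnot(inherits(K, "kernel_matrix"))
  missing <- setdiff(line_ids, K$line_ids)
  if (length(missing) > 0) {
    stop("lines absent from the kernel: ", paste(missing, collapse = ", "))
  }
  K$K[line_ids, line_ids, drop = FALSE]
}

new_structure <- function(name, C, variance_symbol) {
  structure(list(name = name, C = C, variance_symbol = variance_symbol),
            class = "component_structure")
}

#' @export
print.component_structure <- function(x, ...) {
  cat(sprintf("component_structure '%s' (%s): %d x %d\n",
              x$name, x$variance_symbol, nrow(x$C), ncol(x$C)))
  invisible(x)
}

#' Covariance structure of the main genetic effect
#'
#' Dense realization C = Zg K Zg'. In environment-major order this is a block
#' matrix whose (j, j') block holds the kernel entries for the lines observed
#' in environment j crossed with those observed in j'; the off-diagonal blocks
#' are what exchange information between environments, which is effective only
#' when between-environment correlations are positive (the single multiplier
#' is the genetic variance).
#'
#' @param D incidence list from [build_incidence()].
#' @param K a `kernel_matrix` covering every trial line.
#' @param trial the `trial_data` the incidence was built from.
#' @return A `component_structure` named `"g"`.
#' @export
main_effect_structure <- function(D, K, trial) {
  Ksub <- subset_kernel(K, trial$line_ids)
  C <- Ksub[D$line_idx, D$line_idx, drop = FALSE]
  dimnames(C) <- NULL
  new_structure("g", C, "sigma_g2")
}

#' Covariance structure of the single-variance G x E deviation
#'
#' C = (Zg K Zg') o (ZE ZE'): the Hadamard product with the environment
#' incidence zeroes every between-environment block, leaving the kernel
#' pattern block-diagonal by environment.
#'
#' @inheritParams main_effect_structure
#' @return A `component_structure` named `"ge"`.
#' @export
gxe_single_structure <- function(D, K, trial) {
  g <- main_effect_structure(D, K, trial)
  same_env <- outer(D$env_idx, D$env_idx, "==")
  new_structure("ge", g$C * same_env, "sigma_ge2")
}

#' Environment-specific G x E covariance structures
#'
#' One structure per environment: the kernel pattern masked to that
#' environment's diagonal block, zero elsewhere. Their sum equals the
#' single-variance structure exactly (a partition of the block diagonal),
#' but each carries its own variance component.
#'
#' @inheritParams main_effect_structure
#' @return list of `component_structure`, named `"gE_<env>"`, one per
#'   environment in trial order.
#' @export
gxe_env_specific_structures <- function(D, K, trial) {
  g <- main_effect_structure(D, K, trial)
  out <- lapply(seq_along(trial$env_ids), function(j) {
    mask <- outer(D$env_idx == j, D$env_idx == j, "&")
    new_structure(paste0("gE_", trial$env_ids[j]), g$C * mask,
                  paste0("sigma_gE2_", trial$env_ids[j]))
  })
  names(out) <- trial$env_ids
  out
}

#' Covariance structure of the iid per-line random intercept
#'
#' C = Zg Zg': records of the same line covary with unit pattern regardless of
#' environment; distinct lines are independent. Under an l-model the
#' between-environment covariance of one line's records becomes
#' sigma_g2 * K[i, i] + sigma_l2.
#'
#' @param D incidence list from [build_incidence()].
#' @return A `component_structure` named `"l"`.
#' @export
intercept_structure <- function(D) {
  C <- outer(D$line_idx, D$line_idx, "==") * 1
  new_structure("l", C, "sigma_l2")
}

#' Random components of each Hadamard-family model
#'
#' @param model one of `"MM"`, `"MMl"`, `"MDs"`, `"MDsl"`, `"MDe"`, `"MDel"`.
#' @return character vector of component names among `"g"`, `"ge"`, `"gE"`,
#'   `"l"` (the residual is implicit in every model).
#' @export
model_components <- function(model) {
  switch(model,
         MM = "g",
         MMl = c("g", "l"),
         MDs = c("g", "ge"),
         MDsl = c("g", "ge", "l"),
         MDe = c("g", "gE"),
         MDel = c("g", "gE", "l"),
         stop("unknown model '", model, "' (expected MM, MMl, MDs, MDsl, MDe or MDel)"))
}

hadamard_models <- c("MM", "MMl", "MDs", "MDsl", "MDe", "MDel")
kronecker_models <- c("MUC", "MUCf")

#' All model names of the two families
#' @return character vector of the eight model names.
#' @export
all_models <- function() c(hadamard_models, kronecker_models)

#' Assemble the marginal phenotype covariance of a Hadamard-family model
#'
#' Var(y) = sum_k sigma_k^2 C_k + sigma^2 I over the model's components, using
#' the dense structures. Intended for desk-scale verification; the fitting
#' engine never forms these N x N matrices.
#'
#' @param trial a `trial_data`.
#' @param model model name, see [model_components()].
#' @param K a `kernel_matrix`.
#' @param variances named list/vector: `sigma_g2`, `sigma_ge2`, `sigma_l2`,
#'   `sigma2`, and/or per-environment `sigma_gE2_<env>`.
#' @return N x N covariance matrix in canonical record order.
#' @export
model_covariance <- function(trial, model, K, variances) {
  D <- build_incidence(trial)
  comps <- model_components(model)
  v <- as.list(variances)
  V <- diag(v$sigma2, trial$N)
  if ("g" %in% comps) {
    V <- V + v$sigma_g2 * main_effect_structure(D, K, trial)$C
  }
  if ("ge" %in% comps) {
    V <- V + v$sigma_ge2 * gxe_single_structure(D, K, trial)$C
  }
  if ("gE" %in% comps) {
    for (s in gxe_env_specific_structures(D, K, trial)) {
      V <- V + v[[s$variance_symbol]] * s$C
    }
  }
  if ("l" %in% comps) {
    V <- V + v$sigma_l2 * intercept_structure(D)$C
  }
  V
}
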