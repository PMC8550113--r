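# The five Fisher Scoring fitting algorithms (FS, FFS, SFS, FSFS, CSFS)
# with shared initialisation, step-size policy, PSD projection and
# convergence control.

#' Control parameters for the scoring algorithms
#'
#' @param tol Convergence threshold on the change in the (restricted)
#'   log-likelihood between successive iterations.
#' @param max_iter Iteration cap; hitting it returns `converged = FALSE`.
#' @param max_halvings Number of times the unit step is halved before the
#'   zero step is accepted (with a warning).
#' @param psd_project Project each `D_k` onto the PSD cone after every
#'   update (not used by CSFS, whose parameterisation is PSD by
#'   construction).
#' @return A list of class `lmm_control`.
#' @export
lmm_control <- function(tol = 1e-6, max_iter = 200L, max_halvings = 10L,
                        psd_project = TRUE) {
  stopifnot(tol > 0, max_iter >= 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 max_halvings = as.integer(max_halvings),
                 psd_project = isTRUE(psd_project)),
            class = "lmm_control")
}

#' Project a symmetric matrix onto the PSD cone
#'
#' Eigendecomposes, clips negative eigenvalues to zero and reconstructs.
#' This is the Frobenius-nearest PSD matrix; PSD input is returned
#' unchanged.
#'
#' @param Dk Symmetric numeric matrix.
#' @return A symmetric positive semi-definite matrix.
#' @export
project_psd <- function(Dk) {
  Dk <- (Dk + t(Dk)) / 2
  ev <- eigen(Dk, symmetric = TRUE)
  if (min(ev$values) >= 0) return(Dk)
  M <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
  (M + t(M)) / 2
}

#' Initial parameter values for scoring
#'
#' OLS starting values `beta0 = (X'X)^-1 X'Y`, `sigma2_0 = e0'e0 / n`, and
#' per-factor covariance starting blocks obtained by substituting `V = I` in
#' the full-representation update rule:
#' `vec(D_k0) = (sum_j U_(k,j) (x) U_(k,j))^-1 vec(sum_j Z'_(k,j)(e0 e0'/sigma2_0 - I) Z_(k,j))`,
#' contracted through the product forms, symmetrised and PSD-projected. A
#' singular per-factor system falls back to `D_k0 = 0` with a warning.
#'
#' @param pf A [product_forms()] object.
#' @return A list with `beta`, `sigma2`, `D` and `warnings`.
#' @export
initial_values <- function(pf) {
  fs <- pf$fs
  warnings <- character()
  beta0 <- tryCatch(as.numeric(solve(pf$P, pf$Q)),
                    error = function(e)
                      stop("X'X is singular: X must have full column rank",
                           call. = FALSE))
  s20 <- as.numeric(pf$S - 2 * sum(beta0 * pf$Q) +
                      sum(beta0 * (pf$P %*% beta0))) / pf$n
  if (s20 < 1e-10) {
    s20 <- 1e-10
    warnings <- c(warnings, "sigma2 floored at initialisation (exact fit)")
  }
  Zte0 <- as.numeric(t(pf$T)) - as.numeric(crossprod(pf$R, beta0))
  D0 <- vector("list", fs$r)
  for (k in seq_len(fs$r)) {
    qk <- fs$q[k]; lk <- fs$l[k]
    idx <- factor_cols(fs, k)
    Uk <- pf$U[idx, idx, drop = FALSE]
    gram_blocks <- stack_diag_blocks(Uk, qk, lk)
    Gram <- kron_sum_stacked(gram_blocks, gram_blocks, qk)
    M <- factor_vec_mat(Zte0, fs, k)
    rhs <- vec(tcrossprod(M) / s20 - sum_diag_blocks(Uk, qk, lk))
    vk <- tryCatch(solve(Gram, rhs), error = function(e) NULL)
    if (is.null(vk)) {
      warnings <- c(warnings,
                    sprintf("singular initial-value system for factor %d; starting from D_%d = 0",
                            k, k))
      D0[[k]] <- matrix(0, qk, qk)
    } else {
      Dk <- matrix(vk, qk, qk)
      D0[[k]] <- project_psd((Dk + t(Dk)) / 2)
    }
  }
  list(beta = beta0, sigma2 = s20, D = D0, warnings = warnings)
}

#' One generalised least squares update of (beta, sigma2)
#'
#' `beta_new = (X'V^-1X)^-1 X'V^-1 Y` and
#' `sigma2_new = e_new' V^-1 e_new / n` (denominator `n - p` under ReML,
#' matching the restricted-likelihood stationarity condition), with `V`
#' evaluated at the current parameters.
#'
#' @inheritParams core_solves
#' @param criterion `"ML"` or `"ReML"`.
#' @return A list with `beta` and `sigma2`.
#' @export
gls_update <- function(pf, params, criterion = c("ML", "ReML"), vf = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(vf)) vf <- vfactor(pf, params)
  beta_new <- as.numeric(solve(vf$XtVinvX, vf$XtVinvY))
  quad <- as.numeric(vf$YtVinvY - 2 * sum(beta_new * vf$XtVinvY) +
                       sum(beta_new * (vf$XtVinvX %*% beta_new)))
  denom <- if (criterion == "ReML") pf$n - pf$p else pf$n
  list(beta = beta_new, sigma2 = max(quad / denom, 1e-10))
}

# solve M x = b, falling back to the Moore-Penrose pseudo-inverse with a
# relative singular-value cutoff of 1e-12
pinv_solve <- function(M, b, note_env = NULL) {
  x <- tryCatch(solve(M, b), error = function(e) NULL)
  if (!is.null(x) && all(is.finite(x))) return(as.numeric(x))
  sv <- svd(M)
  keep <- sv$d > 1e-12 * max(sv$d)
  if (!is.null(note_env))
    note_env$warnings <- c(note_env$warnings,
                           sprintf("singular information block (rank %d/%d): pseudo-inverse used",
                                   sum(keep), length(sv$d)))
  as.numeric(sv$v[, keep, drop = FALSE] %*%
               ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep]))
}

#' Fit a crossed-factor linear mixed model by Fisher Scoring
#'
#' Estimates `(beta, sigma2, {D_k})` for the model
#' `Y = X beta + Z b + e`, `b ~ N(0, sigma2 D)`, `e ~ N(0, sigma2 I)` by one
#' of five scoring algorithms:
#' \describe{
#'   \item{FS}{joint update of `(beta, sigma2, vech(D_k))` with the full
#'     half-representation information matrix.}
#'   \item{FFS}{joint update of `(beta, sigma2, vec(D_k))` with the
#'     scoring-matrix surrogate `F(theta^f)` (equivalent to pseudo-inverse
#'     scoring on the rank-deficient full-representation information).}
#'   \item{SFS}{per-iteration GLS for `(beta, sigma2)` then per-factor
#'     scoring updates of `vech(D_k)`.}
#'   \item{FSFS}{GLS plus per-factor updates of `vec(D_k)` using
#'     `F_vec(D_k)`.}
#'   \item{CSFS}{GLS plus per-factor updates of `vech(Lambda_k)` where
#'     `D_k = Lambda_k Lambda_k'`; PSD by construction.}
#' }
#' Each proposed step starts at unit length and is halved until the
#' criterion increases; `D_k` blocks are PSD-projected after every accepted
#' update (FS/FFS/SFS/FSFS). Convergence is declared when the criterion
#' changes by less than `control$tol` between iterations.
#'
#' @param object An [lmm_design()] or [product_forms()] object.
#' @param method One of `"FS"`, `"FFS"`, `"SFS"`, `"FSFS"`, `"CSFS"`.
#' @param criterion `"ML"` or `"ReML"`.
#' @param control An [lmm_control()].
#' @return An object of class `lmm_fit` with elements `beta`, `sigma2`, `D`,
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`, `warnings`, `method`,
#'   `criterion` and the product forms used.
#' @export
lmm_fit <- function(object, method = c("FS", "FFS", "SFS", "FSFS", "CSFS"),
                    criterion = c("ML", "ReML"), control = lmm_control()) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  pf <- as_product_forms(object)
  fs <- pf$fs
  env <- new.env(parent = emptyenv())
  env$warnings <- character()

  init <- initial_values(pf)
  env$warnings <- c(env$warnings, init$warnings)
  beta <- init$beta
  params <- lmm_params(init$sigma2, init$D)

  Lambda <- NULL
  if (method == "CSFS") {
    Lambda <- lapply(params$D, function(Dk) {
      L <- chol_factor(project_psd(Dk))
      if (isTRUE(attr(L, "deficient")))
        env$warnings <- c(env$warnings,
                          "rank-deficient initial block: eigendecomposition square root used")
      matrix(as.numeric(L), nrow(L), ncol(L))
    })
  }

  joint <- method %in% c("FS", "FFS")
  rep_tag <- switch(method, FS = "half", FFS = "full", SFS = "half",
                    FSFS = "full", CSFS = "half")
  vf <- vfactor(pf, params)
  ll <- log_likelihood(pf, params, beta, criterion,
                       cs = core_solves(pf, params, beta, vf))
  trace <- ll
  converged <- FALSE
  n_iter <- 0L

  for (s in seq_len(control$max_iter)) {
    n_iter <- s
    if (joint) {
      st <- fs_joint_step(pf, params, beta, vf, ll, method, criterion,
                          rep_tag, control, env)
    } else {
      st <- fs_simplified_step(pf, params, beta, vf, ll, method, criterion,
                               control, env, Lambda)
      Lambda <- st$Lambda
    }
    beta <- st$beta; params <- st$params; vf <- st$vf
    ll_new <- st$ll
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < control$tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  if (!converged)
    env$warnings <- c(env$warnings, "maximum iterations reached")

  # one final GLS pass so the reported (beta, sigma2) are stationary given D
  if (method %in% c("SFS", "FSFS", "CSFS")) {
    g <- gls_update(pf, params, criterion, vf)
    beta <- g$beta
    params <- lmm_params(g$sigma2, params$D)
    ll <- log_likelihood(pf, params, beta, criterion,
                         cs = core_solves(pf, params, beta, vf))
  }
  if (params$sigma2 <= 1e-10)
    env$warnings <- c(env$warnings, "sigma2 at floor in final estimate")

  structure(
    list(beta = beta, sigma2 = params$sigma2, D = params$D,
         loglik = ll, loglik_trace = trace, n_iter = n_iter,
         converged = converged, warnings = unique(env$warnings),
         method = method, criterion = criterion, pf = pf),
    class = "lmm_fit")
}

# rebuild (beta, params) from a joint theta proposal, applying safeguards
rebuild_joint <- function(theta, pf, rep_tag, control, env) {
  fs <- pf$fs
  p <- pf$p
  beta <- theta[seq_len(p)]
  s2 <- theta[p + 1L]
  if (s2 < 1e-10) {
    s2 <- 1e-10
    env$warnings <- c(env$warnings, "sigma2 floored during update")
  }
  covv <- theta[-seq_len(p + 1L)]
  params <- unflatten_cov(covv, fs$q, from = rep_tag, sigma2 = s2)
  if (control$psd_project)
    params <- lmm_params(s2, lapply(params$D, project_psd))
  list(beta = beta, params = params)
}

fs_joint_step <- function(pf, params, beta, vf, ll, method, criterion,
                          rep_tag, control, env) {
  cs <- core_solves(pf, params, beta, vf)
  sc <- score(pf, params, beta, representation = rep_tag,
              criterion = criterion, cs = cs)
  Fi <- fisher_information(pf, params, representation = rep_tag,
                           scoring_matrix = (method == "FFS"), cs = cs)
  dir <- pinv_solve(Fi$matrix, sc$vector, env)
  theta0 <- c(beta, params$sigma2, flatten_cov(params, rep_tag))

  alpha <- 1
  for (h in 0:control$max_halvings) {
    cand <- rebuild_joint(theta0 + alpha * dir, pf, rep_tag, control, env)
    vf_new <- tryCatch(vfactor(pf, cand$params), error = function(e) NULL)
    if (!is.null(vf_new)) {
      ll_new <- log_likelihood(pf, cand$params, cand$beta, criterion,
                               cs = core_solves(pf, cand$params, cand$beta,
                                                vf_new))
      if (is.finite(ll_new) && ll_new > ll)
        return(list(beta = cand$beta, params = cand$params, vf = vf_new,
                    ll = ll_new))
    }
    alpha <- alpha / 2
  }
  env$warnings <- c(env$warnings, "no increasing step found; zero step accepted")
  list(beta = beta, params = params, vf = vf, ll = ll)
}

fs_simplified_step <- function(pf, params, beta, vf, ll, method, criterion,
                               control, env, Lambda) {
  fs <- pf$fs
  # GLS update of (beta, sigma2) at current V
  g <- gls_update(pf, params, criterion, vf)
  beta <- g$beta
  params <- lmm_params(g$sigma2, params$D)
  cs <- core_solves(pf, params, beta, vf)
  # GLS maximises the criterion over (beta, sigma2) at fixed V, so the
  # D-step is judged against the post-GLS criterion value
  ll_gls <- log_likelihood(pf, params, beta, criterion, cs = cs)

  rep_tag <- switch(method, SFS = "half", FSFS = "full", CSFS = "half")
  sc <- score(pf, params, beta, representation = rep_tag,
              criterion = criterion, cs = cs)
  Fi <- fisher_information(pf, params, representation = rep_tag,
                           scoring_matrix = (method == "FSFS"), cs = cs)

  # per-factor update directions
  dirs <- vector("list", fs$r)
  for (k in seq_len(fs$r)) {
    blk <- Fi$matrix[Fi$idx$cov[[k]], Fi$idx$cov[[k]], drop = FALSE]
    gk <- sc$d_cov[[k]]
    if (method == "CSFS") {
      J <- chol_jacobian(Lambda[[k]])
      blk <- J %*% blk %*% t(J)
      gk <- as.numeric(J %*% gk)
    }
    dirs[[k]] <- pinv_solve(blk, gk, env)
  }

  cur_flat <- if (method == "CSFS")
    lapply(Lambda, vech)
  else if (method == "FSFS")
    lapply(params$D, vec)
  else
    lapply(params$D, vech)

  alpha <- 1
  for (h in 0:control$max_halvings) {
    Dnew <- vector("list", fs$r)
    Lnew <- Lambda
    for (k in seq_len(fs$r)) {
      qk <- fs$q[k]
      v <- cur_flat[[k]] + alpha * dirs[[k]]
      if (method == "CSFS") {
        Lnew[[k]] <- unvech_lower(v, qk)
        Dnew[[k]] <- tcrossprod(Lnew[[k]])
      } else if (method == "FSFS") {
        M <- matrix(v, qk, qk)
        Dnew[[k]] <- (M + t(M)) / 2
      } else {
        Dnew[[k]] <- unvech(v, qk)
      }
      if (method != "CSFS" && control$psd_project)
        Dnew[[k]] <- project_psd(Dnew[[k]])
    }
    cand <- lmm_params(params$sigma2, Dnew)
    vf_new <- tryCatch(vfactor(pf, cand), error = function(e) NULL)
    if (!is.null(vf_new)) {
      ll_new <- log_likelihood(pf, cand, beta, criterion,
                               cs = core_solves(pf, cand, beta, vf_new))
      if (is.finite(ll_new) && ll_new > ll_gls)
        return(list(beta = beta, params = cand, vf = vf_new, ll = ll_new,
                    Lambda = Lnew))
    }
    alpha <- alpha / 2
  }
  env$warnings <- c(env$warnings, "no increasing step found; zero step accepted")
  # keep the GLS-updated beta/sigma2 even when the D step is rejected
  list(beta = beta, params = params, vf = vf, ll = ll_gls, Lambda = Lambda)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Crossed-factor LMM fit (%s, %s)\n", x$method, x$criterion))
  cat(sprintf("  log-likelihood: %.6f  (%d iterations, %s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  cat("  beta:  ", paste(sprintf("%.4f", x$beta), collapse = "  "), "\n")
  cat(sprintf("  sigma2: %.4f\n", x$sigma2))
  for (k in seq_along(x$D)) {
    cat(sprintf("  sigma2 * D_%d:\n", k))
    print(round(x$sigma2 * x$D[[k]], 4))
  }
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
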