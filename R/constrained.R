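# Constrained random-effects covariance optimisation via constraint
# (Jacobian) matrices C_k = d vec(D_k) / d vecu(D_k), including the
# shared-parameter ACE twin model.

#' Constraint specification for covariance blocks
#'
#' Two modes are supported. `"per_factor"` constrains each `D_k`
#' independently through a map `vecu(D_k) -> vec(D_k)` with Jacobian `C_k`;
#' `"shared"` expresses every block through one common parameter vector
#' `rho` with stacked Jacobian `C = d [vec(D_1)', ..., vec(D_r)']' / d rho`.
#' Jacobians may depend on the current parameter point, in which case they
#' are re-evaluated each iteration (functions of the parameter vector).
#'
#' @param mode `"per_factor"` or `"shared"`.
#' @param factors For `per_factor`: a list (one per factor) of entries as
#'   returned by [builtin_constraints()], i.e. lists with `n_par`,
#'   `jacobian(u)` (returns the `n_par x q_k^2` matrix `C_k`),
#'   `reconstruct(u)` (returns `D_k`) and `extract(Dk)` (returns `u`).
#' @param shared For `shared`: a list with `n_par`, `jacobian(rho)`
#'   (`n_par x sum(q_k^2)`), `reconstruct(rho)` (list of `D_k`) and
#'   `init(params)` (starting `rho` from unconstrained starting blocks).
#' @return An object of class `constraint_spec`.
#' @export
constraint_spec <- function(mode = c("per_factor", "shared"),
                            factors = NULL, shared = NULL) {
  mode <- match.arg(mode)
  if (mode == "per_factor" && is.null(factors))
    stop("per-factor mode needs `factors`", call. = FALSE)
  if (mode == "shared" && is.null(shared))
    stop("shared mode needs `shared`", call. = FALSE)
  structure(list(mode = mode, factors = factors, shared = shared),
            class = "constraint_spec")
}

#' Built-in per-factor covariance structures
#'
#' Returns a per-factor constraint entry for use in [constraint_spec()]:
#' \describe{
#'   \item{diagonal}{`q_k` free variances, zero covariances.}
#'   \item{compound_symmetry}{two parameters: a common variance `v` on the
#'     diagonal and a common covariance `c` off it.}
#'   \item{identity_scaled}{one parameter `v`, `D_k = v I`.}
#'   \item{unstructured}{`q_k(q_k+1)/2` parameters, `vecu = vech(D_k)`; the
#'     Jacobian is the transposed duplication-matrix map, so the constrained
#'     machinery reproduces the half-representation updates.}
#' }
#'
#' @param name Structure name.
#' @param q_k Block dimension.
#' @return A constraint entry (list of `n_par`, `jacobian`, `reconstruct`,
#'   `extract`).
#' @export
builtin_constraints <- function(name = c("diagonal", "compound_symmetry",
                                         "identity_scaled", "unstructured"),
                                q_k) {
  name <- match.arg(name)
  q_k <- .check_dim(q_k)
  switch(name,
    diagonal = {
      Ck <- matrix(0, q_k, q_k * q_k)
      for (i in seq_len(q_k)) Ck[i, (i - 1) * q_k + i] <- 1
      list(n_par = q_k,
           jacobian = function(u) Ck,
           reconstruct = function(u) diag(u, nrow = q_k),
           extract = function(Dk) diag(as.matrix(Dk)))
    },
    compound_symmetry = {
      Ev <- diag(q_k)
      Ec <- matrix(1, q_k, q_k) - diag(q_k)
      Ck <- rbind(vec(Ev), vec(Ec))
      list(n_par = 2L,
           jacobian = function(u) Ck,
           reconstruct = function(u) u[1] * Ev + u[2] * Ec,
           extract = function(Dk) {
             Dk <- as.matrix(Dk)
             c(mean(diag(Dk)),
               if (q_k > 1) mean(Dk[upper.tri(Dk)]) else 0)
           })
    },
    identity_scaled = {
      Ck <- matrix(vec(diag(q_k)), nrow = 1)
      list(n_par = 1L,
           jacobian = function(u) Ck,
           reconstruct = function(u) diag(u, nrow = q_k),
           extract = function(Dk) mean(diag(as.matrix(Dk))))
    },
    unstructured = {
      Ck <- t(duplication_matrix(q_k))
      list(n_par = q_k * (q_k + 1) / 2,
           jacobian = function(u) Ck,
           reconstruct = function(u) unvech(u, q_k),
           extract = function(Dk) vech(as.matrix(Dk)))
    })
}

#' Explicit linear per-factor constraint from a dense Jacobian
#'
#' Builds a per-factor constraint entry for a linear structure
#' `vec(D_k) = C_k' u` from its dense Jacobian `C_k` (`n_par x q_k^2`).
#' The extraction map is the least-squares inverse
#' `u = (C_k C_k')^-1 C_k vec(D_k)`.
#'
#' @param Ck Dense Jacobian matrix, rows indexing the free parameters.
#' @return A constraint entry for [constraint_spec()].
#' @export
linear_constraint <- function(Ck) {
  Ck <- as.matrix(Ck)
  q_k <- sqrt(ncol(Ck))
  if (q_k != round(q_k))
    stop("ncol(Ck) must be a square number (q_k^2)", call. = FALSE)
  q_k <- as.integer(q_k)
  G <- tcrossprod(Ck)
  list(n_par = nrow(Ck),
       jacobian = function(u) Ck,
       reconstruct = function(u) {
         M <- matrix(as.numeric(crossprod(Ck, u)), q_k, q_k)
         (M + t(M)) / 2
       },
       extract = function(Dk) as.numeric(solve(G, Ck %*% vec(as.matrix(Dk)))))
}

#' Constraint (Jacobian) matrix of the ACE twin model
#'
#' For the ACE model the covariance blocks are
#' `D_k = tau_a^2 K^a_k + tau_c^2 K^c_k` with `tau_a = sigma_a/sigma_e`,
#' `tau_c = sigma_c/sigma_e`. The Jacobian mapping full-representation
#' covariance derivatives to `(tau_a, tau_c)` derivatives is
#' `C = (1_(1,r) (x) diag(2 tau_a, 2 tau_c)) %*% directsum_k [vec(K^a_k)'; vec(K^c_k)']`.
#'
#' @param tau_a,tau_c Standardised genetic / common-environment scales.
#' @param Ka_list,Kc_list Per-factor kinship and shared-environment
#'   matrices (symmetric, `q_k x q_k`).
#' @return The `2 x sum(q_k^2)` constraint matrix.
#' @export
ace_constraint_matrix <- function(tau_a, tau_c, Ka_list, Kc_list) {
  r <- length(Ka_list)
  if (length(Kc_list) != r)
    stop("need one K^a and one K^c per factor", call. = FALSE)
  blocks <- lapply(seq_len(r), function(k)
    rbind(vec(as.matrix(Ka_list[[k]])), vec(as.matrix(Kc_list[[k]]))))
  q2 <- vapply(blocks, ncol, 1L)
  C0 <- matrix(0, 2 * r, sum(q2))
  off <- 0L
  for (k in seq_len(r)) {
    C0[(2 * k - 1):(2 * k), off + seq_len(q2[k])] <- blocks[[k]]
    off <- off + q2[k]
  }
  scale <- kronecker(matrix(1, 1, r), diag(c(2 * tau_a, 2 * tau_c)))
  scale %*% C0
}

#' Shared-parameter constraint entry for the ACE model
#'
#' Builds the `shared` entry of a [constraint_spec()] for the ACE model:
#' `rho = (tau_a, tau_c)` with `D_k = tau_a^2 K^a_k + tau_c^2 K^c_k`.
#'
#' @inheritParams ace_constraint_matrix
#' @return A [constraint_spec()] in shared mode.
#' @export
ace_constraints <- function(Ka_list, Kc_list) {
  r <- length(Ka_list)
  Ka_list <- lapply(Ka_list, as.matrix)
  Kc_list <- lapply(Kc_list, as.matrix)
  constraint_spec(
    mode = "shared",
    shared = list(
      n_par = 2L,
      names = c("tau_a", "tau_c"),
      jacobian = function(rho)
        ace_constraint_matrix(rho[1], rho[2], Ka_list, Kc_list),
      reconstruct = function(rho)
        lapply(seq_len(r), function(k)
          rho[1]^2 * Ka_list[[k]] + rho[2]^2 * Kc_list[[k]]),
      init = function(params) {
        # moment-match the unconstrained starting blocks onto the two
        # kinship directions (non-negative least squares via clipping)
        num_a <- sum(vapply(seq_len(r), function(k)
          sum(Ka_list[[k]] * params$D[[k]]), 1))
        den_a <- sum(vapply(Ka_list, function(K) sum(K * K), 1))
        num_c <- sum(vapply(seq_len(r), function(k)
          sum(Kc_list[[k]] * params$D[[k]]), 1))
        den_c <- sum(vapply(Kc_list, function(K) sum(K * K), 1))
        c(sqrt(max(num_a / den_a, 0.05)), sqrt(max(num_c / den_c, 0.05)))
      }))
}

#' Constrained score and information
#'
#' Maps the full-representation score and Fisher Information onto the
#' constrained parameters: `score_u = C_k d l/d vec(D_k)` per factor and
#' `I_u[k1,k2] = C_k1 I^f_vec(D_k1),vec(D_k2) C_k2'` (stacked `C` in shared
#' mode).
#'
#' @inheritParams score
#' @param spec A [constraint_spec()].
#' @param u Current constrained parameter values (list per factor, or the
#'   shared `rho`), at which parameter-dependent Jacobians are evaluated.
#' @return A list with `score` (vector over the constrained covariance
#'   parameters) and `fim` (its information matrix).
#' @export
constrained_score_fim <- function(pf, params, beta, spec, u,
                                  criterion = c("ML", "ReML"), cs = NULL) {
  criterion <- match.arg(criterion)
  fs <- pf$fs
  if (is.null(cs)) cs <- core_solves(pf, params, beta)
  sc <- score(pf, params, beta, representation = "full",
              criterion = criterion, cs = cs)
  Fi <- fisher_information(pf, params, representation = "full",
                           scoring_matrix = TRUE, cs = cs)
  full_score <- unlist(sc$d_cov)
  ncov <- sum(fs$q^2)
  Ffull <- matrix(0, ncov, ncov)
  off <- c(0, cumsum(fs$q^2))
  for (k1 in seq_len(fs$r)) for (k2 in seq_len(fs$r)) {
    Ffull[off[k1] + seq_len(fs$q[k1]^2), off[k2] + seq_len(fs$q[k2]^2)] <-
      Fi$matrix[Fi$idx$cov[[k1]], Fi$idx$cov[[k2]]]
  }
  if (spec$mode == "shared") {
    C <- spec$shared$jacobian(u)
    list(score = as.numeric(C %*% full_score),
         fim = C %*% Ffull %*% t(C))
  } else {
    Cs <- lapply(seq_len(fs$r), function(k)
      spec$factors[[k]]$jacobian(u[[k]]))
    Cbig <- matrix(0, sum(vapply(Cs, nrow, 1L)), ncov)
    roff <- 0L
    for (k in seq_len(fs$r)) {
      Cbig[roff + seq_len(nrow(Cs[[k]])), off[k] + seq_len(fs$q[k]^2)] <- Cs[[k]]
      roff <- roff + nrow(Cs[[k]])
    }
    list(score = as.numeric(Cbig %*% full_score),
         fim = Cbig %*% Ffull %*% t(Cbig))
  }
}

#' Fit an LMM with a constrained covariance structure
#'
#' GLS updates for `(beta, sigma2)` alternate with Fisher Scoring updates of
#' the constrained covariance parameters, using the constraint-mapped score
#' and information. ReML is supported through the same restricted-likelihood
#' score adjustments, mapped through the constraint Jacobian.
#'
#' @inheritParams lmm_fit
#' @param spec A [constraint_spec()].
#' @return An `lmm_fit` object with an extra `constrained` element holding
#'   the estimated constrained parameters.
#' @export
lmm_fit_constrained <- function(object, spec,
                                criterion = c("ML", "ReML"),
                                control = lmm_control()) {
  criterion <- match.arg(criterion)
  pf <- as_product_forms(object)
  fs <- pf$fs
  env <- new.env(parent = emptyenv())
  env$warnings <- character()

  init <- initial_values(pf)
  env$warnings <- c(env$warnings, init$warnings)
  beta <- init$beta

  if (spec$mode == "shared") {
    u <- spec$shared$init(lmm_params(init$sigma2, init$D))
    D <- spec$shared$reconstruct(u)
  } else {
    u <- lapply(seq_len(fs$r), function(k)
      spec$factors[[k]]$extract(project_psd(init$D[[k]])))
    D <- lapply(seq_len(fs$r), function(k)
      spec$factors[[k]]$reconstruct(u[[k]]))
  }
  params <- lmm_params(init$sigma2, D)

  vf <- vfactor(pf, params)
  ll <- log_likelihood(pf, params, beta, criterion,
                       cs = core_solves(pf, params, beta, vf))
  trace <- ll
  converged <- FALSE
  n_iter <- 0L

  for (s in seq_len(control$max_iter)) {
    n_iter <- s
    g <- gls_update(pf, params, criterion, vf)
    beta <- g$beta
    params <- lmm_params(g$sigma2, params$D)
    cs <- core_solves(pf, params, beta, vf)
    ll_gls <- log_likelihood(pf, params, beta, criterion, cs = cs)

    sf <- constrained_score_fim(pf, params, beta, spec, u, criterion, cs)
    dir <- pinv_solve(sf$fim, sf$score, env)

    u_flat <- if (spec$mode == "shared") u else unlist(u)
    alpha <- 1
    accepted <- FALSE
    for (h in 0:control$max_halvings) {
      u_new_flat <- u_flat + alpha * dir
      if (spec$mode == "shared") {
        u_new <- u_new_flat
        Dnew <- spec$shared$reconstruct(u_new)
      } else {
        u_new <- vector("list", fs$r)
        pos <- 0L
        Dnew <- vector("list", fs$r)
        for (k in seq_len(fs$r)) {
          np <- spec$factors[[k]]$n_par
          u_new[[k]] <- u_new_flat[pos + seq_len(np)]
          pos <- pos + np
          Dnew[[k]] <- spec$factors[[k]]$reconstruct(u_new[[k]])
        }
      }
      cand <- lmm_params(params$sigma2, Dnew)
      vf_new <- tryCatch(vfactor(pf, cand), error = function(e) NULL)
      if (!is.null(vf_new)) {
        ll_new <- log_likelihood(pf, cand, beta, criterion,
                                 cs = core_solves(pf, cand, beta, vf_new))
        if (is.finite(ll_new) && ll_new > ll_gls) {
          u <- u_new; params <- cand; vf <- vf_new
          ll_iter <- ll_new
          accepted <- TRUE
          break
        }
      }
      alpha <- alpha / 2
    }
    if (!accepted) {
      env$warnings <- c(env$warnings,
                        "no increasing constrained step found; zero step accepted")
      ll_iter <- ll_gls
    }
    trace <- c(trace, ll_iter)
    if (abs(ll_iter - ll) < control$tol) {
      ll <- ll_iter
      converged <- TRUE
      break
    }
    ll <- ll_iter
  }
  if (!converged)
    env$warnings <- c(env$warnings, "maximum iterations reached")

  g <- gls_update(pf, params, criterion, vf)
  beta <- g$beta
  params <- lmm_params(g$sigma2, params$D)
  ll <- log_likelihood(pf, params, beta, criterion,
                       cs = core_solves(pf, params, beta, vf))

  out <- structure(
    list(beta = beta, sigma2 = params$sigma2, D = params$D,
         loglik = ll, loglik_trace = trace, n_iter = n_iter,
         converged = converged, warnings = unique(env$warnings),
         method = "constrained-SFS", criterion = criterion, pf = pf,
         constrained = list(spec = spec, u = u)),
    class = "lmm_fit")
  out
}

#' Variance components of a fitted ACE model
#'
#' Converts a constrained ACE fit's `(tau_a, tau_c, sigma2)` into the
#' additive-genetic, common-environment and residual variance components
#' `sigma_a^2 = tau_a^2 sigma_e^2`, `sigma_c^2 = tau_c^2 sigma_e^2`,
#' `sigma_e^2 = sigma2`.
#'
#' @param fit A fit from [lmm_fit_constrained()] with an ACE spec.
#' @return A tibble with one row per component.
#' @export
ace_components <- function(fit) {
  stopifnot(!is.null(fit$constrained))
  rho <- fit$constrained$u
  se2 <- fit$sigma2
  tibble::tibble(
    component = c("sigma_a2", "sigma_c2", "sigma_e2"),
    estimate = c(rho[1]^2 * se2, rho[2]^2 * se2, se2))
}
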