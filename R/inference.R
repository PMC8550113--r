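# Approximate t-tests for fixed-effect contrasts with Satterthwaite degrees
# of freedom computed directly from the score-based variance derivatives —
# no numeric differentiation and no n-sized objects.

# d S2 / d (sigma2, vech(D_1), ..., vech(D_r)) for S2 = sigma2 L (X'V^-1X)^-1 L'.
# The covariance-block derivative collapses to sigma2 * sum_j b_(k,j) (x) b_(k,j)
# with b = Z'V^-1 X (X'V^-1X)^-1 L', summed per level by a reshape.
s2_derivatives <- function(pf, params, L, cs) {
  fs <- pf$fs
  s2 <- params$sigma2
  XtVinvX_inv_Lt <- solve(cs$XtVinvX, L)
  d_s2 <- sum(L * XtVinvX_inv_Lt)                    # L (X'V^-1X)^-1 L'
  b <- as.numeric(cs$ZtVinvX %*% XtVinvX_inv_Lt)     # q_total vector
  d_cov <- lapply(seq_len(fs$r), function(k) {
    bk <- factor_vec_mat(b, fs, k)                   # q_k x l_k
    full <- s2 * vec(tcrossprod(bk))                 # sigma2 sum_j b b'
    as.numeric(crossprod(duplication_matrix(fs$q[k]), full))
  })
  list(d_sigma2 = d_s2, d_cov = d_cov,
       vector = c(d_s2, unlist(d_cov)),
       S2 = s2 * d_s2)
}

# constrained counterpart: derivatives with respect to the constrained
# covariance parameters, obtained by mapping the full-representation
# derivative through the constraint Jacobian.
s2_derivative_constrained <- function(pf, params, L, cs, spec, u) {
  fs <- pf$fs
  s2 <- params$sigma2
  XtVinvX_inv_Lt <- solve(cs$XtVinvX, L)
  d_s2 <- sum(L * XtVinvX_inv_Lt)
  b <- as.numeric(cs$ZtVinvX %*% XtVinvX_inv_Lt)
  full <- unlist(lapply(seq_len(fs$r), function(k)
    s2 * vec(tcrossprod(factor_vec_mat(b, fs, k)))))
  d_u <- if (spec$mode == "shared") {
    as.numeric(spec$shared$jacobian(u) %*% full)
  } else {
    off <- c(0, cumsum(fs$q^2))
    unlist(lapply(seq_len(fs$r), function(k)
      as.numeric(spec$factors[[k]]$jacobian(u[[k]]) %*%
                   full[off[k] + seq_len(fs$q[k]^2)])))
  }
  list(d_sigma2 = d_s2, d_u = d_u, S2 = s2 * d_s2)
}

#' Approximate t-test with Satterthwaite degrees of freedom
#'
#' Tests `H0: L beta = 0` for a single contrast vector `L` using
#' `T = L beta-hat / sqrt(S2)` with `S2 = sigma2-hat L (X'V-hat^-1 X)^-1 L'`.
#' The degrees of freedom are the Satterthwaite moment-match
#' `v = 2 (S2)^2 / Var(S2)`, where `Var(S2)` is the delta-method variance
#' `grad(S2)' I(theta)^-1 grad(S2)` over the variance parameters
#' `(sigma2, vech(D_1), ..., vech(D_r))`, with closed-form derivatives and
#' the Fisher Information evaluated at the estimates.
#'
#' For ReML fits the information is evaluated in its restricted (residual)
#' form, so in the fixed-effects-plus-noise limit (`D = 0`) the degrees of
#' freedom collapse to exactly `n - p`. For ML fits the ordinary information
#' is used and a note records that ML variance estimates are not
#' bias-corrected for fixed-effect estimation.
#'
#' Constrained fits (from [lmm_fit_constrained()]) use derivatives and
#' information mapped through the constraint Jacobian.
#'
#' @param fit An `lmm_fit` object.
#' @param L Numeric contrast vector of length `p`, or a single column index.
#' @param variance_params `"all"` (default) treats
#'   `(sigma2, vech(D_1), ...)` as the estimated variance parameters;
#'   `"sigma2_only"` restricts the uncertainty accounting to `sigma2`,
#'   holding the covariance blocks fixed (the fixed-variance limit in which
#'   a ReML fit with `D = 0` gives exactly `n - p` degrees of freedom).
#' @return A one-row tibble: `estimate`, `se`, `statistic`, `df`, `p.value`.
#' @export
approx_t <- function(fit, L, variance_params = c("all", "sigma2_only")) {
  variance_params <- match.arg(variance_params)
  pf <- fit$pf
  if (length(L) == 1 && L == round(L) && L >= 1 && L <= pf$p) {
    Lv <- numeric(pf$p); Lv[L] <- 1; L <- Lv
  }
  L <- as.numeric(L)
  if (length(L) != pf$p)
    stop("contrast must have length p = ", pf$p, call. = FALSE)
  if (all(L == 0))
    stop("contrast must be nonzero", call. = FALSE)
  if (!isTRUE(fit$converged))
    warning("fit did not converge; the test is computed at the last iterate",
            call. = FALSE)
  if (fit$criterion == "ML")
    warning("ML variance estimates are biased downward; ReML fits are recommended for testing",
            call. = FALSE)

  params <- lmm_params(fit$sigma2, fit$D)
  cs <- core_solves(pf, params, fit$beta)
  est <- sum(L * fit$beta)
  residual <- fit$criterion == "ReML"

  if (!is.null(fit$constrained)) {
    spec <- fit$constrained$spec
    u <- fit$constrained$u
    d <- s2_derivative_constrained(pf, params, L, cs, spec, u)
    S2 <- d$S2
    sf <- constrained_score_fim(pf, params, fit$beta, spec, u,
                                criterion = fit$criterion, cs = cs)
    # variance-parameter information: sigma2 and constrained covariance
    Fi <- fisher_information(pf, params, representation = "full",
                             residual = residual, cs = cs)
    nu <- length(d$d_u)
    Iv <- matrix(0, 1 + nu, 1 + nu)
    Iv[1, 1] <- Fi$matrix[Fi$idx$sigma2, Fi$idx$sigma2]
    C <- if (spec$mode == "shared") spec$shared$jacobian(u) else NULL
    full_cross <- unlist(lapply(seq_len(pf$fs$r), function(k)
      Fi$matrix[Fi$idx$sigma2, Fi$idx$cov[[k]]]))
    ncov <- sum(pf$fs$q^2)
    Ffull <- matrix(0, ncov, ncov)
    off <- c(0, cumsum(pf$fs$q^2))
    for (k1 in seq_len(pf$fs$r)) for (k2 in seq_len(pf$fs$r)) {
      Ffull[off[k1] + seq_len(pf$fs$q[k1]^2),
            off[k2] + seq_len(pf$fs$q[k2]^2)] <-
        Fi$matrix[Fi$idx$cov[[k1]], Fi$idx$cov[[k2]]]
    }
    if (spec$mode == "shared") {
      Iv[1, -1] <- as.numeric(C %*% full_cross)
      Iv[-1, 1] <- Iv[1, -1]
      Iv[-1, -1] <- C %*% Ffull %*% t(C)
    } else {
      Cbig <- matrix(0, nu, ncov)
      roff <- 0L
      for (k in seq_len(pf$fs$r)) {
        Ck <- spec$factors[[k]]$jacobian(u[[k]])
        Cbig[roff + seq_len(nrow(Ck)), off[k] + seq_len(pf$fs$q[k]^2)] <- Ck
        roff <- roff + nrow(Ck)
      }
      Iv[1, -1] <- as.numeric(Cbig %*% full_cross)
      Iv[-1, 1] <- Iv[1, -1]
      Iv[-1, -1] <- Cbig %*% Ffull %*% t(Cbig)
    }
    grad <- c(d$d_sigma2, d$d_u)
  } else {
    d <- s2_derivatives(pf, params, L, cs)
    S2 <- d$S2
    Fi <- fisher_information(pf, params, representation = "half",
                             residual = residual, cs = cs)
    vidx <- c(Fi$idx$sigma2, unlist(Fi$idx$cov))
    Iv <- Fi$matrix[vidx, vidx, drop = FALSE]
    grad <- d$vector
  }
  if (variance_params == "sigma2_only") {
    Iv <- Iv[1, 1, drop = FALSE]
    grad <- grad[1]
  }

  env <- new.env(parent = emptyenv()); env$warnings <- character()
  var_S2 <- sum(grad * pinv_solve(Iv, grad, env))
  df <- if (var_S2 > 0) 2 * S2^2 / var_S2 else Inf
  if (is.finite(df) && df < 1) {
    df <- 1
    warning("Satterthwaite degrees of freedom below 1; clamped", call. = FALSE)
  }
  se <- sqrt(S2)
  stat <- est / se
  tibble::tibble(
    estimate = est, se = se, statistic = stat, df = df,
    p.value = 2 * stats::pt(-abs(stat), df = df))
}
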