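# Closed-form score vectors and Fisher Information matrices for the half,
# full and Cholesky representations, with ReML adjustments.

# per-factor pieces shared by score and information:
#  S1[[k]] = sum_j (Z'V^-1 e)_(k,j) (Z'V^-1 e)_(k,j)'      (qk x qk)
#  S2[[k]] = sum_j (Z'V^-1 Z)_[(k,j),(k,j)]                (qk x qk)
score_pieces <- function(pf, params, cs) {
  fs <- pf$fs
  lapply(seq_len(fs$r), function(k) {
    idx <- factor_cols(fs, k)
    uk <- factor_vec_mat(cs$ZtVinv_e, fs, k)
    list(S1 = tcrossprod(uk),
         S2 = sum_diag_blocks(cs$ZtVinvZ[idx, idx, drop = FALSE],
                              fs$q[k], fs$l[k]))
  })
}

# sum_j diagonal blocks of Z' P Z for the ReML score adjustment, with
# P = V^-1 - V^-1 X (X'V^-1X)^-1 X'V^-1 applied through product forms
reml_adjust_blocks <- function(pf, cs) {
  fs <- pf$fs
  W <- cs$ZtVinvX %*% solve(cs$XtVinvX, t(cs$ZtVinvX))
  lapply(seq_len(fs$r), function(k) {
    idx <- factor_cols(fs, k)
    sum_diag_blocks(W[idx, idx, drop = FALSE], fs$q[k], fs$l[k])
  })
}

#' Score vector of the crossed-factor LMM
#'
#' Closed-form derivative of the (restricted) log-likelihood with respect to
#' `beta`, `sigma2` and the covariance blocks in the requested
#' representation. The residual outer product `ee'` is never formed: the
#' covariance-block summands collapse to
#' `sum_j u_(k,j) u_(k,j)'/sigma2 - sum_j (Z'V^-1Z)_(k,j),(k,j)` with
#' `u = Z'V^-1 e` taken from [core_solves()].
#'
#' @inheritParams core_solves
#' @param representation `"half"` (`vech(D_k)`), `"full"` (`vec(D_k)`) or
#'   `"chol"` (`vech(Lambda_k)`).
#' @param criterion `"ML"` or `"ReML"` (adds the restricted-likelihood
#'   adjustment terms to the `sigma2` and covariance blocks).
#' @param cs Optional precomputed [core_solves()].
#' @return A list with `d_beta`, `d_sigma2`, `d_cov` (list over factors) and
#'   the concatenated `vector`.
#' @export
score <- function(pf, params, beta, representation = c("half", "full", "chol"),
                  criterion = c("ML", "ReML"), cs = NULL) {
  representation <- match.arg(representation)
  criterion <- match.arg(criterion)
  fs <- pf$fs
  s2 <- max(params$sigma2, 1e-10)
  if (is.null(cs)) cs <- core_solves(pf, params, beta)
  pieces <- score_pieces(pf, params, cs)
  d_beta <- cs$XtVinv_e / s2
  d_sigma2 <- -pf$n / (2 * s2) + cs$etVinv_e / (2 * s2^2)
  adj <- if (criterion == "ReML") reml_adjust_blocks(pf, cs) else NULL
  if (criterion == "ReML") d_sigma2 <- d_sigma2 + pf$p / (2 * s2)

  d_cov <- vector("list", fs$r)
  for (k in seq_len(fs$r)) {
    qk <- fs$q[k]
    Mk <- 0.5 * (pieces[[k]]$S1 / s2 - pieces[[k]]$S2)
    if (criterion == "ReML") Mk <- Mk + 0.5 * adj[[k]]
    d_cov[[k]] <- switch(representation,
      full = vec(Mk),
      half = as.numeric(crossprod(duplication_matrix(qk), vec(Mk))),
      chol = {
        J <- chol_jacobian(chol_factor(params$D[[k]]))
        half <- as.numeric(crossprod(duplication_matrix(qk), vec(Mk)))
        as.numeric(J %*% half)
      })
  }
  list(d_beta = d_beta, d_sigma2 = d_sigma2, d_cov = d_cov,
       vector = c(d_beta, d_sigma2, unlist(d_cov)))
}

#' Fisher Information matrix of the crossed-factor LMM
#'
#' Builds the expected information over `(beta, sigma2, covariance blocks)`
#' in the half, full or Cholesky representation. All factor-pair blocks
#' `sum_i sum_j (Z'V^-1Z)_(k1,i),(k2,j) (x) (same)` are evaluated with the
#' reshape-and-permute Kronecker-sum identity over the `(k1,k2)` block grid
#' of `Z'V^-1Z`, never by looping over levels.
#'
#' With `scoring_matrix = TRUE` (full representation only) the covariance
#' blocks are the scoring-matrix surrogate `F(theta^f)` — the same sums
#' without the symmetrizer factor — whose plain inverse reproduces the
#' pseudo-inverse update.
#'
#' With `residual = TRUE` the variance-parameter blocks are evaluated in
#' their exact restricted form, replacing `V^-1` by
#' `P = V^-1 - V^-1X(X'V^-1X)^-1X'V^-1` and `n` by `n - p`; this is the
#' information used for ReML-based Satterthwaite variances, where the
#' sigma2-only limit must give `Var(sigma2-hat) = 2 sigma^4/(n-p)`.
#'
#' @inheritParams score
#' @param scoring_matrix Use the `F(theta^f)` surrogate covariance blocks.
#' @param residual Evaluate variance blocks in restricted (ReML) form.
#' @return A list with the full symmetric `matrix` and an `idx` list giving
#'   the row/column ranges of `beta`, `sigma2` and each covariance block.
#' @export
fisher_information <- function(pf, params,
                               representation = c("half", "full", "chol"),
                               scoring_matrix = FALSE, residual = FALSE,
                               cs = NULL, beta = NULL) {
  representation <- match.arg(representation)
  fs <- pf$fs
  s2 <- max(params$sigma2, 1e-10)
  if (is.null(cs)) {
    if (is.null(beta)) beta <- rep(0, pf$p)  # FIM does not depend on beta
    cs <- core_solves(pf, params, beta)
  }
  if (scoring_matrix && representation != "full")
    stop("the scoring-matrix surrogate is defined for the full representation",
         call. = FALSE)

  # effective Z' (.) Z matrix for the variance blocks
  ZWZ <- cs$ZtVinvZ
  n_eff <- pf$n
  if (residual) {
    ZWZ <- ZWZ - cs$ZtVinvX %*% solve(cs$XtVinvX, t(cs$ZtVinvX))
    ZWZ <- (ZWZ + t(ZWZ)) / 2
    n_eff <- pf$n - pf$p
  }

  r <- fs$r
  covlen <- vapply(seq_len(r), function(k) {
    if (representation == "full") fs$q[k]^2 else fs$q[k] * (fs$q[k] + 1) / 2
  }, 1)
  p <- pf$p
  tot <- p + 1 + sum(covlen)
  Im <- matrix(0, tot, tot)
  idx_beta <- seq_len(p)
  idx_s2 <- p + 1L
  off <- p + 1L
  idx_cov <- vector("list", r)
  for (k in seq_len(r)) {
    idx_cov[[k]] <- off + seq_len(covlen[k])
    off <- off + covlen[k]
  }

  Im[idx_beta, idx_beta] <- cs$XtVinvX / s2
  Im[idx_s2, idx_s2] <- n_eff / (2 * s2^2)

  Jc <- NULL
  if (representation == "chol")
    Jc <- lapply(params$D, function(Dk) chol_jacobian(chol_factor(Dk)))

  for (k in seq_len(r)) {
    qk <- fs$q[k]
    idxk <- factor_cols(fs, k)
    s2blk <- sum_diag_blocks(ZWZ[idxk, idxk, drop = FALSE], qk, fs$l[k])
    rowv <- vec(s2blk) / (2 * s2)            # full-rep sigma2 cross block
    v <- switch(representation,
      full = rowv,
      half = as.numeric(crossprod(duplication_matrix(qk), rowv)),
      chol = as.numeric(Jc[[k]] %*%
                          crossprod(duplication_matrix(qk), rowv)))
    Im[idx_s2, idx_cov[[k]]] <- v
    Im[idx_cov[[k]], idx_s2] <- v
  }

  for (k1 in seq_len(r)) {
    for (k2 in k1:r) {
      q1 <- fs$q[k1]; q2 <- fs$q[k2]
      Gsub <- ZWZ[factor_cols(fs, k1), factor_cols(fs, k2), drop = FALSE]
      KS <- 0.5 * kron_sum_vectorized(Gsub, Gsub, q1, q2)   # q1^2 x q2^2
      blk <- switch(representation,
        full = if (scoring_matrix) KS else
          symmetrizer_matrix(q1) %*% KS,
        half = crossprod(duplication_matrix(q1), KS) %*% duplication_matrix(q2),
        chol = Jc[[k1]] %*% crossprod(duplication_matrix(q1), KS) %*%
          duplication_matrix(q2) %*% t(Jc[[k2]]))
      Im[idx_cov[[k1]], idx_cov[[k2]]] <- blk
      if (k2 > k1) Im[idx_cov[[k2]], idx_cov[[k1]]] <- t(blk)
    }
  }

  list(matrix = Im,
       idx = list(beta = idx_beta, sigma2 = idx_s2, cov = idx_cov),
       representation = representation, scoring_matrix = scoring_matrix,
       residual = residual)
}

#' Jacobian of the Cholesky parameterisation
#'
#' The mapping with rows indexed by `vech(Lambda_k)` and columns by
#' `vech(D_k)` for `D_k = Lambda_k Lambda_k'` with `Lambda_k` lower
#' triangular: `L_q (Lambda' (x) I_q)(I_{q^2} + K_{q,q}) L_q'`. Applied on
#' the left of the `vech(D_k)` score it yields the `vech(Lambda_k)` score.
#'
#' @param Lambda_k Lower-triangular matrix.
#' @return A square matrix of dimension `q(q+1)/2`.
#' @export
chol_jacobian <- function(Lambda_k) {
  Lambda_k <- as.matrix(Lambda_k)
  q <- nrow(Lambda_k)
  if (any(abs(Lambda_k[upper.tri(Lambda_k)]) > 1e-12))
    stop("Lambda_k must be lower triangular", call. = FALSE)
  elimination_matrix(q) %*% (kronecker(t(Lambda_k), diag(q))) %*%
    (diag(q * q) + commutation_matrix(q, q)) %*% t(elimination_matrix(q))
}
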