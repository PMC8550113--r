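# V-involving quantities computed solely from the product forms. The only
# inversion anywhere is of the (q_total x q_total) matrix (I + DU); nothing
# here allocates an object with an n-sized dimension.

# D %*% M applied blockwise: D = direct-sum_k (I_{l_k} (x) D_k). M has
# q_total rows ordered factor-major, level-major, effect-minor.
apply_D_left <- function(M, params, fs) {
  M <- as.matrix(M)
  out <- matrix(0, nrow(M), ncol(M))
  for (k in seq_len(fs$r)) {
    idx <- factor_cols(fs, k)
    qk <- fs$q[k]; lk <- fs$l[k]
    blk <- M[idx, , drop = FALSE]                       # (qk*lk) x m
    res <- params$D[[k]] %*% matrix(blk, qk, lk * ncol(M))
    out[idx, ] <- matrix(res, qk * lk, ncol(M))
  }
  out
}

# sum over j of the diagonal blocks M[(k,j),(k,j)] of a square matrix whose
# rows/cols are factor k's random-effect columns; returns qk x qk.
sum_diag_blocks <- function(M, qk, lk) {
  a <- array(M, dim = c(qk, lk, qk, lk))
  a2 <- aperm(a, c(1, 3, 2, 4))                 # (qk, qk, lk, lk)
  m2 <- matrix(a2, qk * qk, lk * lk)
  matrix(rowSums(m2[, (seq_len(lk) - 1L) * lk + seq_len(lk), drop = FALSE]),
         qk, qk)
}

# the l_k diagonal blocks M[(k,j),(k,j)] stacked vertically: (lk*qk) x qk
stack_diag_blocks <- function(M, qk, lk) {
  a <- array(M, dim = c(qk, lk, qk, lk))
  out <- matrix(0, lk * qk, qk)
  for (j in seq_len(lk)) {
    out[(j - 1L) * qk + seq_len(qk), ] <- a[, j, , j]
  }
  out
}

# reshape a q_total-long vector's factor-k part into a (qk x lk) matrix whose
# columns are the per-level sub-vectors
factor_vec_mat <- function(v, fs, k) {
  matrix(v[factor_cols(fs, k)], fs$q[k], fs$l[k])
}

# D-dependent factorisation, shared by every beta evaluated at the same
# covariance parameters. Solves with A = I_q + DU once; everything the
# e-dependent quantities need is then linear in beta.
vfactor <- function(pf, params) {
  fs <- pf$fs
  DU <- apply_D_left(pf$U, params, fs)
  A <- DU
  diag(A) <- diag(A) + 1                        # A = I_q + DU
  qrA <- qr(A, LAPACK = TRUE)
  if (qrA$rank < ncol(A) || any(abs(diag(qrA$qr)) <
                                1e-14 * max(abs(diag(qrA$qr)))))
    stop("singular (I + DU): covariance blow-up", call. = FALSE)

  rhs <- cbind(apply_D_left(t(pf$R), params, fs),       # D R'
               apply_D_left(t(pf$T), params, fs),       # D T'
               DU)                                      # D U
  sol <- solve(qrA, rhs)
  p <- pf$p
  AinvDRt <- sol[, seq_len(p), drop = FALSE]
  AinvDTt <- sol[, p + 1L]
  AinvDU <- sol[, -seq_len(p + 1L), drop = FALSE]

  XtVinvX <- pf$P - pf$R %*% AinvDRt
  XtVinvX <- (XtVinvX + t(XtVinvX)) / 2
  XtVinvY <- as.numeric(pf$Q) - as.numeric(pf$R %*% AinvDTt)
  YtVinvY <- pf$S - as.numeric(pf$T %*% AinvDTt)
  ZtVinvZ <- pf$U - pf$U %*% AinvDU
  ZtVinvZ <- (ZtVinvZ + t(ZtVinvZ)) / 2
  ZtVinvX <- t(pf$R) - pf$U %*% AinvDRt
  ZtVinvY <- as.numeric(t(pf$T)) - as.numeric(pf$U %*% AinvDTt)

  d <- diag(qrA$qr)
  logdetV <- sum(log(abs(d)))
  if (!is.finite(logdetV))
    stop("log|V| undefined: (I + DU) numerically degenerate", call. = FALSE)

  list(XtVinvX = XtVinvX, XtVinvY = XtVinvY, YtVinvY = YtVinvY,
       ZtVinvZ = ZtVinvZ, ZtVinvX = ZtVinvX, ZtVinvY = ZtVinvY,
       logdetV = logdetV)
}

#' Core V-inverse quantities from product forms
#'
#' Evaluates every quantity involving `V = I_n + Z D Z'` that the scoring
#' algorithms and inference need — `Z'V^-1Z`, `Z'V^-1e`, `X'V^-1X`,
#' `X'V^-1e`, `X'V^-1Y`, `Z'V^-1X`, `e'V^-1e` and `log|V|` — using the
#' product-form identities: the Woodbury inverse of `I_n + ZDZ'` and the
#' determinant identity `log|V| = log|I_q + DU|`, with `D` applied as a
#' per-factor block operator. `e = Y - X beta`.
#'
#' @param pf A [product_forms()] object.
#' @param params An [lmm_params()].
#' @param beta Fixed-effects vector.
#' @param vf Optional precomputed D-dependent factorisation (internal reuse).
#' @return A list of the named quantities.
#' @export
core_solves <- function(pf, params, beta, vf = NULL) {
  beta <- as.numeric(beta)
  if (is.null(vf)) vf <- vfactor(pf, params)
  Xb <- as.numeric(vf$XtVinvX %*% beta)
  c(vf,
    list(
      ZtVinv_e = vf$ZtVinvY - as.numeric(vf$ZtVinvX %*% beta),
      XtVinv_e = vf$XtVinvY - Xb,
      etVinv_e = as.numeric(vf$YtVinvY - 2 * sum(beta * vf$XtVinvY) +
                              sum(beta * Xb))))
}

#' Log-likelihood of the crossed-factor LMM from product forms
#'
#' ML: `l = -1/2 { n log sigma2 + sigma^-2 e'V^-1 e + log|V| }` (additive
#' constants dropped, so values differ from fully normalised log-likelihoods
#' by the usual `n log(2 pi)/2`-type terms). ReML subtracts
#' `1/2 ( -p log sigma2 + log|X'V^-1X| )`. The value is invariant to the
#' covariance-parameter representation.
#'
#' @inheritParams core_solves
#' @param criterion `"ML"` or `"ReML"`.
#' @param cs Optional precomputed [core_solves()] result.
#' @return Scalar log-likelihood (additive constants dropped).
#' @export
log_likelihood <- function(pf, params, beta, criterion = c("ML", "ReML"),
                           cs = NULL) {
  criterion <- match.arg(criterion)
  s2 <- max(params$sigma2, 1e-10)
  if (is.null(cs)) cs <- core_solves(pf, params, beta)
  l <- -0.5 * (pf$n * log(s2) + cs$etVinv_e / s2 + cs$logdetV)
  if (criterion == "ReML") {
    ldx <- determinant(cs$XtVinvX, logarithm = TRUE)
    l <- l - 0.5 * (-pf$p * log(s2) + as.numeric(ldx$modulus))
  }
  l
}
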