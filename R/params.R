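# Parameter containers and the half / full / Cholesky flattenings.

#' Covariance parameters of the crossed-factor LMM
#'
#' Holds the scalar variance `sigma2` and the per-factor within-factor
#' covariance blocks `D_k` (`q_k x q_k`, symmetric). The full random-effects
#' covariance `D = direct-sum_k (I_{l_k} (x) D_k)` is never materialised;
#' everything applies the blocks directly.
#'
#' @param sigma2 Positive scalar variance.
#' @param D A list of symmetric `q_k x q_k` matrices, one per factor.
#' @return An object of class `lmm_params`.
#' @export
lmm_params <- function(sigma2, D) {
  sigma2 <- as.numeric(sigma2)
  if (length(sigma2) != 1 || !is.finite(sigma2))
    stop("sigma2 must be a finite scalar", call. = FALSE)
  D <- lapply(D, function(Dk) {
    Dk <- as.matrix(Dk)
    if (nrow(Dk) != ncol(Dk)) stop("D blocks must be square", call. = FALSE)
    (Dk + t(Dk)) / 2
  })
  structure(list(sigma2 = sigma2, D = D), class = "lmm_params")
}

# theta flattenings ----------------------------------------------------------

#' Convert between parameter representations
#'
#' Flattens the covariance blocks of an [lmm_params()] into the `"half"`
#' (`vech(D_k)`), `"full"` (`vec(D_k)`) or `"chol"` (`vech(Lambda_k)` with
#' `D_k = Lambda_k Lambda_k'`, `Lambda_k` lower triangular) representation,
#' and rebuilds parameters from any of them. Asymmetric full-representation
#' input is symmetrised as `(A + A')/2` before conversion. Conversion to
#' `"chol"` requires each block to be positive semi-definite; rank-deficient
#' blocks use the eigendecomposition square root re-triangularised by LQ.
#'
#' @param params An [lmm_params()].
#' @param to One of `"half"`, `"full"`, `"chol"`.
#' @return For `flatten_cov()`: a numeric vector (blocks concatenated in
#'   factor order). For `unflatten_cov()`: an [lmm_params()].
#' @export
flatten_cov <- function(params, to = c("half", "full", "chol")) {
  to <- match.arg(to)
  unlist(lapply(params$D, function(Dk) {
    switch(to,
      half = vech(Dk),
      full = vec(Dk),
      chol = vech(chol_factor(Dk)))
  }), use.names = FALSE)
}

#' @rdname flatten_cov
#' @param theta Numeric vector of flattened covariance parameters.
#' @param q Integer vector of per-factor block dimensions.
#' @param from Representation the vector is in.
#' @param sigma2 Scalar variance to attach to the rebuilt parameters.
#' @export
unflatten_cov <- function(theta, q, from = c("half", "full", "chol"),
                          sigma2 = 1) {
  from <- match.arg(from)
  D <- vector("list", length(q))
  pos <- 0L
  for (k in seq_along(q)) {
    qk <- q[k]
    len <- if (from == "full") qk * qk else qk * (qk + 1) / 2
    v <- theta[pos + seq_len(len)]
    pos <- pos + len
    D[[k]] <- switch(from,
      half = unvech(v, qk),
      full = {
        M <- matrix(v, qk, qk)
        (M + t(M)) / 2
      },
      chol = {
        L <- unvech_lower(v, qk)
        tcrossprod(L)
      })
  }
  lmm_params(sigma2, D)
}

# Lower-triangular factor with D = L L'. Uses pivoted-free chol when PD;
# falls back to an eigendecomposition square root re-triangularised via the
# LQ decomposition when the block is only PSD (flagged by attribute).
chol_factor <- function(Dk) {
  Dk <- (Dk + t(Dk)) / 2
  ev <- eigen(Dk, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1))
    stop("cannot Cholesky-factor an indefinite block", call. = FALSE)
  ok <- tryCatch({
    L <- t(chol(Dk))
    list(L = L, deficient = FALSE)
  }, error = function(e) NULL)
  if (is.null(ok)) {
    # square root via eigen, then L = (lq of sqrt): Dk = A A' with
    # A = V sqrt(diag); LQ: A' = QR => A = R' Q' ; R' lower triangular and
    # A A' = R' R = (R')(R')' since Q orthogonal.
    vals <- pmax(ev$values, 0)
    A <- ev$vectors %*% diag(sqrt(vals), nrow = length(vals))
    R <- qr.R(qr(t(A)))
    # flip row signs so the diagonal of L is non-negative; R'R is unchanged
    s <- sign(diag(R)); s[s == 0] <- 1
    L <- t(s * R)
    ok <- list(L = L, deficient = TRUE)
  }
  structure(ok$L, deficient = ok$deficient)
}

# total number of covariance parameters in a representation
n_cov_par <- function(q, rep) {
  if (rep == "full") sum(q^2) else sum(q * (q + 1) / 2)
}

# index ranges of factor k's block inside the flattened covariance vector
cov_block_idx <- function(q, rep, k) {
  lens <- if (rep == "full") q^2 else q * (q + 1) / 2
  off <- c(0, cumsum(lens))
  seq.int(off[k] + 1L, off[k + 1L])
}
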