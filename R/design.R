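# Model representation: crossed-factor layout, design matrices and the six
# n-free cross-products ("product forms") that all later computation uses.

#' Describe the crossed-factor layout of the random effects
#'
#' A factor structure records, for each of `r` random factors, how many
#' random effects it groups (`q_k`), how many levels it has (`l_k`) and the
#' observation-to-level assignment. Level indices are 1-based; `NA` marks an
#' observation not associated with that factor (its rows of the factor's
#' design block are zero — needed e.g. for family-structure-type factors in
#' twin models, which partition rather than cross the observations).
#'
#' @param levels A list with one integer vector per factor (length `n`),
#'   giving each observation's level of that factor (`NA` allowed).
#' @param q Integer vector of per-factor random-effect counts.
#' @param l Optional integer vector of per-factor level counts; defaults to
#'   the maximum observed level per factor. Every level `1..l_k` must have at
#'   least one observation, otherwise that factor's covariance block is
#'   unidentifiable and an error is raised.
#' @return An object of class `factor_structure` with fields `r`, `q`, `l`,
#'   `level_of` and `q_total`.
#' @export
factor_structure <- function(levels, q, l = NULL) {
  if (!is.list(levels) || length(levels) < 1)
    stop("`levels` must be a non-empty list of per-factor level vectors",
         call. = FALSE)
  r <- length(levels)
  q <- as.integer(q)
  if (length(q) != r || any(q < 1))
    stop("`q` must give a positive effect count for each factor", call. = FALSE)
  n <- length(levels[[1]])
  if (any(vapply(levels, length, 1L) != n))
    stop("all level vectors must have equal length", call. = FALSE)
  if (is.null(l)) l <- vapply(levels, function(x) max(x, na.rm = TRUE), 1)
  l <- as.integer(l)
  if (length(l) != r || any(l < 2))
    stop("each factor needs at least 2 levels", call. = FALSE)
  for (k in seq_len(r)) {
    lk <- levels[[k]]
    obs <- lk[!is.na(lk)]
    if (any(obs < 1 | obs > l[k] | obs != round(obs)))
      stop("level indices of factor ", k, " must lie in 1..", l[k],
           call. = FALSE)
    occ <- tabulate(obs, nbins = l[k])
    if (any(occ == 0))
      stop("factor ", k, " has empty levels: ",
           paste(which(occ == 0), collapse = ", "),
           " (covariance block unidentifiable)", call. = FALSE)
  }
  structure(
    list(r = r, q = q, l = l,
         level_of = lapply(levels, as.integer),
         q_total = sum(q * l), n = n),
    class = "factor_structure")
}

# column index range of Z for factor k (all levels)
factor_cols <- function(fs, k) {
  off <- c(0L, cumsum(fs$q * fs$l))
  seq.int(off[k] + 1L, off[k + 1L])
}

# column index range of Z for level j of factor k
level_cols <- function(fs, k, j) {
  off <- c(0L, cumsum(fs$q * fs$l))
  start <- off[k] + (j - 1L) * fs$q[k]
  seq.int(start + 1L, start + fs$q[k])
}

#' Assemble a linear mixed model design
#'
#' Builds the response/design triple (Y, X, Z) for a crossed-factor LMM. The
#' random-effects design `Z` is stored per factor as the raw `n x q_k`
#' covariate matrix plus the level assignment; its fully expanded column
#' order is factors in declaration order, within factor by level, within
#' level by effect, with `Z_(k,j)` zero on every row outside level `j`.
#'
#' @param Y Numeric response vector (length `n`).
#' @param X Numeric fixed-effects design matrix (`n x p`).
#' @param factors A list with one entry per factor, each a list with
#'   elements `levels` (length-`n` level assignment, `NA` allowed) and
#'   `covariates` (`n x q_k` matrix of raw random-effect covariates, e.g. a
#'   column of ones for a random intercept).
#' @return An object of class `lmm_design` holding `Y`, `X`, the per-factor
#'   covariate blocks and the [factor_structure()].
#' @export
lmm_design <- function(Y, X, factors) {
  Y <- as.numeric(Y)
  X <- as.matrix(X)
  n <- length(Y)
  if (nrow(X) != n) stop("nrow(X) must equal length(Y)", call. = FALSE)
  covs <- lapply(factors, function(f) {
    cm <- as.matrix(f$covariates)
    if (nrow(cm) != n)
      stop("factor covariates must have n rows", call. = FALSE)
    if (ncol(cm) < 1) stop("each factor needs >= 1 random effect", call. = FALSE)
    cm
  })
  fs <- factor_structure(
    levels = lapply(factors, function(f) f$levels),
    q = vapply(covs, ncol, 1L),
    l = if (!is.null(factors[[1]][["l"]]))
      vapply(factors, function(f) f[["l"]], 1) else NULL)
  structure(list(Y = Y, X = X, covariates = covs, fs = fs, n = n),
            class = "lmm_design")
}

# Dense Z (n x q_total). Only used by the simulator, tests and IO; the
# estimation path never needs it.
expand_Z <- function(design) {
  fs <- design$fs
  n <- design$n
  Z <- matrix(0, n, fs$q_total)
  for (k in seq_len(fs$r)) {
    lev <- fs$level_of[[k]]
    cm <- design$covariates[[k]]
    ok <- which(!is.na(lev))
    cols_k <- factor_cols(fs, k)
    col0 <- cols_k[1] - 1L
    for (e in seq_len(fs$q[k])) {
      idx <- cbind(ok, col0 + (lev[ok] - 1L) * fs$q[k] + e)
      Z[idx] <- cm[ok, e]
    }
  }
  Z
}

#' Reduce a design to its product forms
#'
#' Computes the six cross-products `P = X'X`, `Q = X'Y`, `R = X'Z`,
#' `S = Y'Y`, `T = Y'Z` and `U = Z'Z`. None of these has a dimension that
#' scales with the number of observations, and every quantity the scoring
#' algorithms need is computed from them alone; `Y`, `X`, `Z` may be
#' discarded once they are built.
#'
#' @param design An [lmm_design()].
#' @return An object of class `product_forms` with the six matrices, `n`,
#'   `p` and the [factor_structure()].
#' @export
product_forms <- function(design) {
  stopifnot(inherits(design, "lmm_design"))
  Z <- expand_Z(design)
  X <- design$X
  Y <- design$Y
  structure(
    list(P = crossprod(X), Q = crossprod(X, Y), R = crossprod(X, Z),
         S = sum(Y * Y), T = matrix(crossprod(Y, Z), nrow = 1),
         U = crossprod(Z),
         n = design$n, p = ncol(X), fs = design$fs),
    class = "product_forms")
}

as_product_forms <- function(x) {
  if (inherits(x, "product_forms")) return(x)
  if (inherits(x, "lmm_design")) return(product_forms(x))
  stop("expected an lmm_design or product_forms object", call. = FALSE)
}
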