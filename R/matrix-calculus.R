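# Vectorisation operators and the structural matrices (duplication,
# elimination, commutation, symmetrizer) used throughout the scoring
# calculations, plus reshape-based evaluation of Kronecker-product sums.
#
# Convention (fixed package-wide): vec() stacks *columns*; vech() stacks the
# on-and-below-diagonal elements column-major.

# one cache environment per dimension/key; matrices are small (k <= max q_k)
# so dense 0/1 storage is deliberate. Permutations are kept as index vectors.
.struct_cache <- new.env(parent = emptyenv())

.cache_get <- function(key, build) {
  if (!is.null(.struct_cache[[key]])) return(.struct_cache[[key]])
  val <- build()
  assign(key, val, envir = .struct_cache)
  val
}

#' Vectorise a matrix column-major
#'
#' `vec()` stacks the columns of a matrix into a single column vector;
#' `vech()` stacks the on-and-below-diagonal elements of a square matrix.
#' These are the elementary operators relating a covariance block \eqn{D_k}
#' to its "full" (`vec`) and "half" (`vech`) parameter representations.
#'
#' @param A A numeric matrix (square for `vech()`).
#' @return A numeric column vector (plain numeric, not a matrix).
#' @examples
#' vec(matrix(1:4, 2))
#' vech(diag(3))
#' @export
vec <- function(A) {
  A <- as.matrix(A)
  as.numeric(A)
}

#' @rdname vec
#' @export
vech <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("vech() requires a square matrix", call. = FALSE)
  A[lower.tri(A, diag = TRUE)]
}

# inverse of vech for a symmetric k x k matrix
unvech <- function(v, k) {
  stopifnot(length(v) == k * (k + 1) / 2)
  M <- matrix(0, k, k)
  M[lower.tri(M, diag = TRUE)] <- v
  M <- M + t(M)
  diag(M) <- diag(M) / 2
  M
}

# inverse of vech for a lower-triangular k x k matrix
unvech_lower <- function(v, k) {
  stopifnot(length(v) == k * (k + 1) / 2)
  M <- matrix(0, k, k)
  M[lower.tri(M, diag = TRUE)] <- v
  M
}

.check_dim <- function(k) {
  if (length(k) != 1 || !is.finite(k) || k < 1 || k != round(k))
    stop("dimension must be a positive integer", call. = FALSE)
  as.integer(k)
}

#' Structural matrices of matrix differential calculus
#'
#' Dense constructors for the duplication matrix \eqn{\mathcal{D}_k}
#' (`vec(A) = D_k vech(A)` for symmetric `A`), the elimination matrix
#' \eqn{\mathcal{L}_k} (`vech(A) = L_k vec(A)`), the commutation matrix
#' \eqn{K_{m,n}} (`vec(A) = K_{m,n} vec(A')` for `A` of size m x n) and the
#' symmetrizer \eqn{N_k = (I + K_{k,k})/2}. Results are cached per dimension,
#' since the same small dimensions recur at every scoring iteration.
#'
#' @param k,m,n Positive integer dimensions.
#' @return A dense 0/1 (or 0/0.5/1 for the symmetrizer) matrix.
#' @examples
#' duplication_matrix(2) %*% c(1, 2, 3)  # vec of [[1,2],[2,3]]
#' @export
duplication_matrix <- function(k) {
  k <- .check_dim(k)
  .cache_get(paste0("dup", k), function() {
    nh <- k * (k + 1) / 2
    Dm <- matrix(0, k * k, nh)
    H <- matrix(0, k, k)
    H[lower.tri(H, diag = TRUE)] <- seq_len(nh)
    H <- H + t(H) - diag(diag(H))
    Dm[cbind(seq_len(k * k), as.integer(H))] <- 1
    Dm
  })
}

#' @rdname duplication_matrix
#' @export
elimination_matrix <- function(k) {
  k <- .check_dim(k)
  .cache_get(paste0("elim", k), function() {
    nh <- k * (k + 1) / 2
    L <- matrix(0, nh, k * k)
    idx <- which(as.logical(lower.tri(matrix(0, k, k), diag = TRUE)))
    L[cbind(seq_len(nh), idx)] <- 1
    L
  })
}

#' @rdname duplication_matrix
#' @export
commutation_matrix <- function(m, n) {
  m <- .check_dim(m); n <- .check_dim(n)
  .cache_get(paste0("comm", m, "_", n), function() {
    # vec(A) = K vec(A'): row (i-1) + (j-1)*m + 1 of vec(A) pulls element
    # (j-1) + (i-1)*n + 1 of vec(A')
    K <- matrix(0, m * n, m * n)
    i <- rep(seq_len(m), times = n)
    j <- rep(seq_len(n), each = m)
    K[cbind((j - 1) * m + i, (i - 1) * n + j)] <- 1
    K
  })
}

#' @rdname duplication_matrix
#' @export
symmetrizer_matrix <- function(k) {
  k <- .check_dim(k)
  .cache_get(paste0("sym", k), function() {
    (diag(k * k) + commutation_matrix(k, k)) / 2
  })
}

# Permutation (as an index vector p: y = x[p]) encoding the matrix
# (I_{n2} (x) K_{n1,n2} (x) I_{n1}) used in the Kronecker-sum identity.
kron_sum_perm <- function(n1, n2) {
  n1 <- .check_dim(n1); n2 <- .check_dim(n2)
  .cache_get(paste0("perm", n1, "_", n2), function() {
    P <- kronecker(diag(n2), kronecker(commutation_matrix(n1, n2), diag(n1)))
    # P x = x[p] with p[i] the column of the 1 in row i
    max.col(P, ties.method = "first")
  })
}

#' Generalised ("vec_m") vectorisation
#'
#' Splits a matrix `M` into horizontal partitions of `m` columns each,
#' transposes every partition, and stacks them vertically. With `A` and `B`
#' stacks of blocks, the crossproduct sum over blocks satisfies
#' `sum_i A_i B_i' = t(vec_m(t(A))) %*% vec_m(t(B))`, replacing a loop over
#' blocks with one reshape and one matrix product.
#'
#' @param M A numeric matrix whose column count is divisible by `m`.
#' @param m Number of columns per partition.
#' @return The stacked transposed partitions: an
#'   `(m * ncol(M)/m) x nrow(M)` matrix, i.e. `m` rows per partition.
#' @export
vec_m <- function(M, m) {
  M <- as.matrix(M)
  m <- .check_dim(m)
  if (ncol(M) %% m != 0)
    stop("column count of M is not divisible by m", call. = FALSE)
  cblocks <- ncol(M) / m
  # a[i, j, b] = M[i, (b-1)*m + j]
  a <- array(M, dim = c(nrow(M), m, cblocks))
  # output stacks t(M_b): rows (j within block b), columns i
  out <- aperm(a, c(2, 3, 1))
  matrix(out, nrow = m * cblocks, ncol = nrow(M))
}

#' Block-wise row vectorisation
#'
#' Partitions `M` into a grid of `block_rows` x `block_cols` blocks and
#' returns the matrix whose rows are `vec(block)'`, blocks ordered row-major
#' over the partition grid. This is the reshape that feeds the fast
#' Kronecker-sum identity.
#'
#' @param M Numeric matrix partitioning evenly into the given block size.
#' @param block_rows,block_cols Dimensions of each block.
#' @return A `(grid cells) x (block_rows*block_cols)` matrix.
#' @export
block_vec_tilde <- function(M, block_rows, block_cols) {
  M <- as.matrix(M)
  n1 <- .check_dim(block_rows); n2 <- .check_dim(block_cols)
  if (nrow(M) %% n1 != 0 || ncol(M) %% n2 != 0)
    stop("M does not partition evenly into the requested blocks", call. = FALSE)
  c1 <- nrow(M) / n1
  c2 <- ncol(M) / n2
  a <- array(M, dim = c(n1, c1, n2, c2))      # a[i1,i2,j1,j2]
  out <- aperm(a, c(1, 3, 4, 2))              # (n1, n2, c2, c1)
  t(matrix(out, nrow = n1 * n2, ncol = c1 * c2))
}

#' Fast evaluation of a sum of Kronecker products over a block grid
#'
#' Computes `sum_{i,j} G_{i,j} %x% H_{i,j}` where `G` and `H` are identically
#' partitioned into blocks of size `block_rows` x `block_cols`, using the
#' reshape identity `vec(sum) = P vec(t(H~) %*% G~)` with `P` a cached
#' permutation — no Kronecker products and no loop over blocks.
#'
#' @inheritParams block_vec_tilde
#' @param G,H Identically sized and partitioned numeric matrices.
#' @return The `(block_rows^2) x (block_cols^2)` summed Kronecker product.
#' @export
kron_sum_vectorized <- function(G, H, block_rows, block_cols) {
  G <- as.matrix(G); H <- as.matrix(H)
  if (!all(dim(G) == dim(H)))
    stop("G and H must have identical dimensions", call. = FALSE)
  n1 <- .check_dim(block_rows); n2 <- .check_dim(block_cols)
  Gt <- block_vec_tilde(G, n1, n2)
  Ht <- block_vec_tilde(H, n1, n2)
  v <- as.numeric(crossprod(Ht, Gt))   # vec(t(H~) %*% G~)
  p <- kron_sum_perm(n1, n2)
  matrix(v[p], nrow = n1 * n1, ncol = n2 * n2)
}

# Single-index variant: blocks stacked vertically (grid c1 x 1). Used for
# sums like sum_j U_(k,j) (x) U_(k,j) and sum_j B_(k,j) (x) B_(k,j).
kron_sum_stacked <- function(Gstack, Hstack, block_rows) {
  kron_sum_vectorized(Gstack, Hstack, block_rows, ncol(as.matrix(Gstack)))
}
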