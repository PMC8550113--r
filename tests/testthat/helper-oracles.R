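# Shared test helpers: small random designs and slow-but-independent
# dense/loop oracles against which the fast implementations are checked.

# a small random crossed design with parameters, all drawn from a seed
small_instance <- function(seed, n = 40, q = c(2L, 1L), l = c(4L, 3L),
                           p = 3, sigma2 = 0.8) {
  set.seed(seed)
  st <- sim_setting("custom", n = n, q = q, l = l,
                    beta = stats::runif(p, -1, 1), sigma2 = sigma2)
  ds <- generate_dataset(st)
  D <- lapply(q, function(qk) {
    A <- matrix(stats::rnorm(qk * qk), qk)
    crossprod(A) / qk + diag(qk) * 0.3
  })
  list(design = ds$design, pf = product_forms(ds$design),
       params = lmm_params(sigma2, D),
       beta = stats::runif(p, -1, 1), st = st)
}

# dense V = I + Z D Z' and its standard quantities, built by explicit
# matrix algebra (the oracle the product-form path must match)
dense_oracle <- function(design, params, beta) {
  Z <- fslmm:::expand_Z(design)
  fs <- design$fs
  Dfull <- matrix(0, ncol(Z), ncol(Z))
  for (k in seq_len(fs$r)) for (j in seq_len(fs$l[k])) {
    idx <- fslmm:::level_cols(fs, k, j)
    Dfull[idx, idx] <- params$D[[k]]
  }
  V <- diag(design$n) + Z %*% Dfull %*% t(Z)
  Vi <- solve(V)
  X <- design$X
  e <- design$Y - X %*% beta
  list(Z = Z, V = V, Vi = Vi,
       XtVinvX = t(X) %*% Vi %*% X,
       ZtVinvZ = t(Z) %*% Vi %*% Z,
       ZtVinvX = t(Z) %*% Vi %*% X,
       ZtVinv_e = as.numeric(t(Z) %*% Vi %*% e),
       XtVinv_e = as.numeric(t(X) %*% Vi %*% e),
       etVinv_e = as.numeric(t(e) %*% Vi %*% e),
       logdetV = as.numeric(determinant(V, logarithm = TRUE)$modulus))
}

# dense log-likelihood from the oracle quantities (constants dropped)
dense_loglik <- function(design, params, beta, criterion = "ML") {
  o <- dense_oracle(design, params, beta)
  s2 <- params$sigma2
  l <- -0.5 * (design$n * log(s2) + o$etVinv_e / s2 + o$logdetV)
  if (criterion == "ReML")
    l <- l - 0.5 * (-ncol(design$X) * log(s2) +
                      as.numeric(determinant(o$XtVinvX)$modulus))
  l
}

# numeric gradient of f at x (central differences)
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 1)
}

# flatten (beta, sigma2, cov) and the corresponding likelihood closure
theta_loglik <- function(pf, q, rep_tag, criterion) {
  p <- pf$p
  function(th) {
    beta <- th[seq_len(p)]
    params <- unflatten_cov(th[-seq_len(p + 1)], q, from = rep_tag,
                            sigma2 = th[p + 1])
    log_likelihood(pf, params, beta, criterion)
  }
}
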