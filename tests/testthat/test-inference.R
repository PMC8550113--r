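# Satterthwaite approximate t-tests: closed-form S^2 derivatives against
# finite differences and dense oracles, closed-form degrees-of-freedom
# limits, and agreement with a numerical Satterthwaite oracle.

# S^2(eta) = sigma2 * L (X'V^-1X)^-1 L' as a function of the variance
# parameters, for finite differencing
s2_of_eta <- function(pf, L, beta) {
  q <- pf$fs$q
  function(eta) {
    params <- unflatten_cov(eta[-1], q, from = "half", sigma2 = eta[1])
    cs <- core_solves(pf, params, beta)
    params$sigma2 * sum(L * solve(cs$XtVinvX, L))
  }
}

test_that("S^2 derivatives match finite differences", {
  inst <- small_instance(131)
  pf <- inst$pf
  L <- c(1, -0.5, 0.25)
  cs <- core_solves(pf, inst$params, inst$beta)
  d <- fslmm:::s2_derivatives(pf, inst$params, L, cs)
  f <- s2_of_eta(pf, L, inst$beta)
  eta0 <- c(inst$params$sigma2, flatten_cov(inst$params, "half"))
  expect_equal(d$vector, num_grad(f, eta0), tolerance = 1e-5)
  expect_equal(d$S2, f(eta0), tolerance = 1e-12)
})

test_that("D = 0 reduces dS^2/dsigma2 to the OLS form", {
  inst <- small_instance(133)
  pf <- inst$pf
  zero <- lmm_params(0.7, lapply(pf$fs$q, function(qk) matrix(0, qk, qk)))
  L <- c(0, 1, 0)
  cs <- core_solves(pf, zero, inst$beta)
  d <- fslmm:::s2_derivatives(pf, zero, L, cs)
  X <- inst$design$X
  expect_equal(d$d_sigma2, sum(L * solve(crossprod(X), L)), tolerance = 1e-10)
})

test_that("covariance-block derivatives match the dense B-block oracle", {
  inst <- small_instance(135)
  pf <- inst$pf
  L <- c(0.5, 1, -1)
  o <- dense_oracle(inst$design, inst$params, inst$beta)
  cs <- core_solves(pf, inst$params, inst$beta)
  d <- fslmm:::s2_derivatives(pf, inst$params, L, cs)
  X <- inst$design$X
  bdense <- as.numeric(t(o$Z) %*% o$Vi %*% X %*% solve(o$XtVinvX, L))
  fs <- pf$fs
  for (k in seq_len(fs$r)) {
    qk <- fs$q[k]
    acc <- numeric(qk * qk)
    for (j in seq_len(fs$l[k])) {
      bkj <- bdense[fslmm:::level_cols(fs, k, j)]
      acc <- acc + as.numeric(kronecker(bkj, bkj))
    }
    expect_equal(d$d_cov[[k]],
                 as.numeric(crossprod(duplication_matrix(qk),
                                      inst$params$sigma2 * acc)),
                 tolerance = 1e-9)
  }
})

test_that("the test is invariant to rescaling the contrast", {
  inst <- small_instance(137, n = 120)
  fit <- lmm_fit(inst$design, method = "FS", criterion = "ReML")
  L <- c(1, 2, -1)
  a <- approx_t(fit, L)
  b <- approx_t(fit, 3.7 * L)
  expect_equal(b$estimate, 3.7 * a$estimate)
  expect_equal(b$statistic, a$statistic, tolerance = 1e-10)
  expect_equal(b$df, a$df, tolerance = 1e-8)
  expect_equal(b$p.value, a$p.value, tolerance = 1e-10)
})

test_that("degrees of freedom match a numerical Satterthwaite oracle", {
  set.seed(139)
  seeds <- sample(1000:9999, 20)
  for (s in seeds) {
    inst <- small_instance(s, n = 80)
    fit <- suppressWarnings(lmm_fit(inst$design, method = "FS",
                                    criterion = "ReML"))
    L <- rnorm(3)
    res <- suppressWarnings(approx_t(fit, L))
    # numeric-gradient oracle with the same (residual-form) information
    pf <- fit$pf
    params <- lmm_params(fit$sigma2, fit$D)
    cs <- core_solves(pf, params, fit$beta)
    f <- s2_of_eta(pf, L, fit$beta)
    eta0 <- c(fit$sigma2, flatten_cov(params, "half"))
    g <- num_grad(f, eta0)
    Fi <- fisher_information(pf, params, "half", residual = TRUE, cs = cs)
    vidx <- c(Fi$idx$sigma2, unlist(Fi$idx$cov))
    Iv <- Fi$matrix[vidx, vidx]
    sv <- svd(Iv)
    keep <- sv$d > 1e-12 * max(sv$d)
    gi <- as.numeric(sv$v[, keep] %*% (crossprod(sv$u[, keep], g) / sv$d[keep]))
    v_num <- 2 * f(eta0)^2 / sum(g * gi)
    expect_equal(res$df, v_num, tolerance = 1e-3)
  }
})

test_that("sigma2-only ReML limit with D = 0 gives exactly n - p", {
  inst <- small_instance(141, n = 60)
  pf <- inst$pf
  zero <- lapply(pf$fs$q, function(qk) matrix(0, qk, qk))
  fit <- structure(
    list(beta = inst$beta, sigma2 = 0.9, D = zero, converged = TRUE,
         criterion = "ReML", pf = pf),
    class = "lmm_fit")
  res <- approx_t(fit, c(1, 0, 0), variance_params = "sigma2_only")
  expect_equal(res$df, pf$n - pf$p, tolerance = 1e-8)
})

test_that("ML variance estimates underestimate cluster-contrast dof", {
  # the downward ML bias in the variance estimates depresses the
  # Satterthwaite dof when both criteria are pushed through the same
  # (restricted-form) Var(S^2) expression; the effect concerns contrasts
  # whose variance is dominated by the random-effect variance, so it is
  # tested on the intercept (a cluster-level contrast) with a one-sided
  # sign test
  st <- sim_setting("custom", n = 80, q = c(1L), l = c(6L),
                    beta = c(1, 0.5, 0), sigma2 = 1,
                    D = list(matrix(0.4, 1, 1)))
  L <- c(1, 0, 0)
  v_of <- function(fit) {
    pf <- fit$pf
    params <- lmm_params(fit$sigma2, fit$D)
    cs <- core_solves(pf, params, fit$beta)
    d <- fslmm:::s2_derivatives(pf, params, L, cs)
    Fi <- fisher_information(pf, params, "half", residual = TRUE, cs = cs)
    vidx <- c(Fi$idx$sigma2, unlist(Fi$idx$cov))
    g <- d$vector
    2 * d$S2^2 / sum(g * solve(Fi$matrix[vidx, vidx], g))
  }
  wins <- 0L
  n_reps <- 100
  for (i in seq_len(n_reps)) {
    ds <- generate_dataset(st, seed = 600 + i)
    fm <- suppressWarnings(lmm_fit(ds$design, method = "SFS",
                                   criterion = "ML"))
    fr <- suppressWarnings(lmm_fit(ds$design, method = "SFS",
                                   criterion = "ReML"))
    if (v_of(fm) <= v_of(fr) + 1e-8) wins <- wins + 1L
  }
  expect_lt(stats::binom.test(wins, n_reps, 0.5, "greater")$p.value, 0.01)
})

test_that("constrained tests reduce to the unconstrained ones", {
  inst <- small_instance(143, n = 150)
  spec <- constraint_spec("per_factor",
                          factors = lapply(inst$pf$fs$q, function(qk)
                            builtin_constraints("unstructured", qk)))
  fu <- lmm_fit(inst$design, method = "SFS", criterion = "ReML")
  fc <- lmm_fit_constrained(inst$design, spec, criterion = "ReML")
  L <- c(1, -1, 0)
  a <- approx_t(fu, L)
  b <- approx_t(fc, L)
  expect_equal(b$statistic, a$statistic, tolerance = 1e-3)
  expect_equal(b$df, a$df, tolerance = 1e-2)
})

test_that("unstructured constrained S^2 derivative equals the vech form", {
  inst <- small_instance(145)
  pf <- inst$pf
  spec <- constraint_spec("per_factor",
                          factors = lapply(pf$fs$q, function(qk)
                            builtin_constraints("unstructured", qk)))
  u <- lapply(inst$params$D, vech)
  L <- c(1, 0.5, -0.5)
  cs <- core_solves(pf, inst$params, inst$beta)
  dc <- fslmm:::s2_derivative_constrained(pf, inst$params, L, cs, spec, u)
  d <- fslmm:::s2_derivatives(pf, inst$params, L, cs)
  expect_equal(dc$d_u, unlist(d$d_cov), tolerance = 1e-12)
  expect_equal(dc$S2, d$S2)
})

test_that("ACE S^2 derivative matches finite differences along rho", {
  ace <- generate_ace_dataset(30, seed = 147)
  pf <- product_forms(ace$design)
  rho <- c(0.7, 0.5)
  params <- lmm_params(1.2, ace$spec$shared$reconstruct(rho))
  beta <- c(0.3, -0.1)
  L <- c(0, 1)
  cs <- core_solves(pf, params, beta)
  dc <- fslmm:::s2_derivative_constrained(pf, params, L, cs, ace$spec, rho)
  expect_length(dc$d_u, 2)
  f <- function(v) {
    p2 <- lmm_params(params$sigma2, ace$spec$shared$reconstruct(v))
    cs2 <- core_solves(pf, p2, beta)
    p2$sigma2 * sum(L * solve(cs2$XtVinvX, L))
  }
  expect_equal(dc$d_u, num_grad(f, rho), tolerance = 1e-5)
})

test_that("orthogonal designs (Z'X = 0) zero the covariance derivatives", {
  set.seed(149)
  lv <- rep(1:4, each = 4)
  x <- as.numeric(scale(rnorm(16), scale = FALSE))
  x <- x - ave(x, lv)                      # centre within every level
  d <- lmm_design(Y = rnorm(16), X = matrix(x, 16, 1),
                  factors = list(list(levels = lv,
                                      covariates = matrix(1, 16, 1))))
  pf <- product_forms(d)
  params <- lmm_params(1, list(matrix(0.5, 1, 1)))
  cs <- core_solves(pf, params, beta = 0.2)
  dd <- fslmm:::s2_derivatives(pf, params, L = 1, cs)
  expect_equal(dd$d_cov[[1]], 0, tolerance = 1e-12)
})

test_that("approx_t validates contrasts and warns as documented", {
  inst <- small_instance(151, n = 80)
  fit <- lmm_fit(inst$design, method = "FS", criterion = "ReML")
  expect_error(approx_t(fit, c(1, 0)), "length p")
  expect_error(approx_t(fit, c(0, 0, 0)), "nonzero")
  # column-index convenience equals the explicit indicator contrast
  a <- approx_t(fit, 2)
  b <- approx_t(fit, c(0, 1, 0))
  expect_equal(a, b)
  expect_s3_class(a, "tbl_df")
  expect_gt(a$se, 0)
  expect_gt(a$df, 0)
  expect_equal(a$p.value, 2 * stats::pt(-abs(a$statistic), df = a$df))
  fml <- lmm_fit(inst$design, method = "FS", criterion = "ML")
  expect_warning(approx_t(fml, 2), "ReML")
  bad <- fit; bad$converged <- FALSE
  expect_warning(approx_t(bad, 2), "converge")
})

test_that("degrees of freedom are close to the reference implementation", {
  st <- sim_setting("custom", n = 300, q = c(2L, 1L), l = c(15L, 6L),
                    beta = c(0.5, -0.25, 0.75), sigma2 = 1,
                    D = list(matrix(c(0.6, 0.2, 0.2, 0.4), 2),
                             matrix(0.5, 1, 1)))
  ds <- generate_dataset(st, seed = 153)
  d <- ds$design
  df <- data.frame(y = d$Y, x1 = d$X[, 2], x2 = d$X[, 3],
                   f1 = factor(d$fs$level_of[[1]]),
                   z1 = d$covariates[[1]][, 2],
                   f2 = factor(d$fs$level_of[[2]]))
  ref <- lmerTest::lmer(y ~ x1 + x2 + (1 + z1 | f1) + (1 | f2), data = df)
  cf <- coef(summary(ref))
  fit <- lmm_fit(d, method = "FS", criterion = "ReML",
                 control = lmm_control(tol = 1e-8))
  for (j in 1:3) {
    res <- approx_t(fit, j)
    expect_equal(res$estimate, cf[j, "Estimate"], tolerance = 1e-4)
    expect_equal(res$se, cf[j, "Std. Error"], tolerance = 1e-3)
    expect_equal(res$df, cf[j, "df"], tolerance = 0.05)
    expect_equal(res$p.value, cf[j, "Pr(>|t|)"], tolerance = 0.02)
  }
})
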