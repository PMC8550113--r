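# The five scoring algorithms: initialisation, GLS, PSD projection and
# full fits, checked against hand computations, dense oracles, textbook
# closed forms and cross-method agreement.

test_that("initial values reproduce the hand OLS computation", {
  d <- lmm_design(Y = c(1, 2, 3), X = matrix(1, 3, 1),
                  factors = list(list(levels = c(1, 2, 1),
                                      covariates = matrix(1, 3, 1))))
  init <- initial_values(product_forms(d))
  expect_equal(init$beta, 2)
  expect_equal(init$sigma2, 2 / 3)
})

test_that("exact-fit designs floor sigma2 and flag it", {
  set.seed(81)
  X <- qr.Q(qr(matrix(rnorm(12), 4, 3)))
  Y <- as.numeric(X %*% c(1, -2, 3))          # Y exactly in the column space
  d <- lmm_design(Y = Y, X = X,
                  factors = list(list(levels = c(1, 2, 1, 2),
                                      covariates = matrix(1, 4, 1))))
  init <- initial_values(product_forms(d))
  expect_equal(init$sigma2, 1e-10)
  expect_true(any(grepl("floored", init$warnings)))
})

test_that("initial covariance blocks match the dense evaluation", {
  inst <- small_instance(83, n = 25)
  pf <- inst$pf
  init <- initial_values(pf)
  Z <- fslmm:::expand_Z(inst$design)
  X <- inst$design$X
  beta0 <- as.numeric(solve(crossprod(X), crossprod(X, inst$design$Y)))
  e0 <- inst$design$Y - X %*% beta0
  s20 <- sum(e0^2) / pf$n
  fs <- pf$fs
  M0 <- tcrossprod(e0) / s20 - diag(pf$n)
  for (k in seq_len(fs$r)) {
    qk <- fs$q[k]
    Gram <- matrix(0, qk^2, qk^2)
    rhs_mat <- matrix(0, qk, qk)
    for (j in seq_len(fs$l[k])) {
      Zkj <- Z[, fslmm:::level_cols(fs, k, j), drop = FALSE]
      Gram <- Gram + kronecker(crossprod(Zkj), crossprod(Zkj))
      rhs_mat <- rhs_mat + t(Zkj) %*% M0 %*% Zkj
    }
    Dk <- matrix(solve(Gram, vec(rhs_mat)), qk, qk)
    expect_equal(init$D[[k]], project_psd((Dk + t(Dk)) / 2),
                 tolerance = 1e-9)
  }
  expect_equal(init$beta, beta0, tolerance = 1e-10)
  expect_equal(init$sigma2, s20, tolerance = 1e-10)
})

test_that("gls_update reduces to OLS when D is zero", {
  inst <- small_instance(85)
  q <- inst$pf$fs$q
  zero <- lmm_params(1, lapply(q, function(qk) matrix(0, qk, qk)))
  g <- gls_update(inst$pf, zero, "ML")
  X <- inst$design$X
  beta_ols <- as.numeric(solve(crossprod(X), crossprod(X, inst$design$Y)))
  expect_equal(g$beta, beta_ols, tolerance = 1e-10)
  expect_equal(g$sigma2,
               sum((inst$design$Y - X %*% beta_ols)^2) / inst$pf$n,
               tolerance = 1e-10)
})

test_that("gls_update matches the dense GLS oracle", {
  for (s in c(87, 89)) {
    inst <- small_instance(s)
    o <- dense_oracle(inst$design, inst$params, inst$beta)
    X <- inst$design$X; Y <- inst$design$Y
    beta_gls <- as.numeric(solve(o$XtVinvX, t(X) %*% o$Vi %*% Y))
    e <- Y - X %*% beta_gls
    for (crit in c("ML", "ReML")) {
      g <- gls_update(inst$pf, inst$params, crit)
      denom <- if (crit == "ReML") inst$pf$n - inst$pf$p else inst$pf$n
      expect_equal(g$beta, beta_gls, tolerance = 1e-10)
      expect_equal(g$sigma2,
                   as.numeric(t(e) %*% o$Vi %*% e) / denom,
                   tolerance = 1e-10)
    }
  }
})

test_that("gls_update is idempotent at a converged fit", {
  inst <- small_instance(91, n = 120)
  fit <- lmm_fit(inst$design, method = "SFS", criterion = "ML")
  params_hat <- lmm_params(fit$sigma2, fit$D)
  g <- gls_update(fit$pf, params_hat, "ML")
  expect_lt(max(abs(g$beta - fit$beta)), 1e-10)
  expect_lt(abs(g$sigma2 - fit$sigma2), 1e-10)
})

test_that("project_psd clips eigenvalues and fixes PSD input", {
  expect_equal(project_psd(diag(c(1, -0.5))), diag(c(1, 0)))
  S <- matrix(c(2, 0.3, 0.3, 1), 2)
  expect_equal(project_psd(S), S)
  # Frobenius-nearest property against random PSD competitors
  set.seed(93)
  A <- matrix(rnorm(9), 3); A <- (A + t(A)) / 2
  P <- project_psd(A)
  expect_gte(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), 0)
  dP <- sqrt(sum((A - P)^2))
  for (trial in 1:200) {
    B <- matrix(rnorm(9), 3)
    Y <- crossprod(B) * runif(1, 0, 2)
    expect_gte(sqrt(sum((A - Y)^2)), dP - 1e-10)
  }
})

test_that("FS, FFS, SFS and FSFS agree on a two-factor dataset", {
  st <- sim_setting("custom", n = 400, q = c(2L, 1L), l = c(20L, 8L),
                    beta = c(0.5, -0.25, 0.75), sigma2 = 1,
                    D = list(matrix(c(0.6, 0.2, 0.2, 0.4), 2),
                             matrix(0.5, 1, 1)))
  ds <- generate_dataset(st, seed = 95)
  fits <- lapply(c("FS", "FFS", "SFS", "FSFS"), function(m)
    lmm_fit(ds$design, method = m, criterion = "ML"))
  lls <- vapply(fits, function(f) f$loglik, 1)
  expect_lt(max(lls) - min(lls), 1e-5)
  ref <- fits[[1]]
  ref_par <- c(ref$beta, ref$sigma2, unlist(lapply(ref$D, vech)))
  for (f in fits[-1]) {
    par <- c(f$beta, f$sigma2, unlist(lapply(f$D, vech)))
    expect_lt(max(abs(par - ref_par) / pmax(abs(ref_par), 1e-3)), 1e-4)
    expect_true(f$converged)
  }
})

test_that("balanced one-way layout matches the closed-form ANOVA estimators", {
  set.seed(97)
  l <- 12L; m <- 10L; n <- l * m
  mu <- 1.5; sa2 <- 1; se2 <- 0.8
  g <- rep(seq_len(l), each = m)
  Y <- mu + rnorm(l, sd = sqrt(sa2))[g] + rnorm(n, sd = sqrt(se2))
  d <- lmm_design(Y = Y, X = matrix(1, n, 1),
                  factors = list(list(levels = g,
                                      covariates = matrix(1, n, 1))))
  gbar <- tapply(Y, g, mean)
  SSW <- sum((Y - gbar[g])^2)
  SSB <- m * sum((gbar - mean(Y))^2)
  MSW <- SSW / (n - l)
  ctrl <- lmm_control(tol = 1e-10)
  # ML: sigma_e^2 = MSW, between-group variance lambda = SSB / l
  fml <- lmm_fit(d, method = "SFS", criterion = "ML", control = ctrl)
  expect_equal(fml$beta, mean(Y), tolerance = 1e-6)
  expect_equal(fml$sigma2, MSW, tolerance = 1e-5)
  expect_equal(fml$sigma2 * fml$D[[1]][1, 1], (SSB / l - MSW) / m,
               tolerance = 1e-4)
  # ReML: lambda = MSB = SSB / (l - 1)
  frm <- lmm_fit(d, method = "SFS", criterion = "ReML", control = ctrl)
  expect_equal(frm$sigma2, MSW, tolerance = 1e-5)
  expect_equal(frm$sigma2 * frm$D[[1]][1, 1], (SSB / (l - 1) - MSW) / m,
               tolerance = 1e-4)
})

test_that("estimates agree with the reference mixed-model implementation", {
  st <- sim_setting("custom", n = 300, q = c(2L, 1L), l = c(15L, 6L),
                    beta = c(0.5, -0.25, 0.75), sigma2 = 1,
                    D = list(matrix(c(0.6, 0.2, 0.2, 0.4), 2),
                             matrix(0.5, 1, 1)))
  ds <- generate_dataset(st, seed = 99)
  d <- ds$design
  df <- data.frame(y = d$Y, x1 = d$X[, 2], x2 = d$X[, 3],
                   f1 = factor(d$fs$level_of[[1]]),
                   z1 = d$covariates[[1]][, 2],
                   f2 = factor(d$fs$level_of[[2]]))
  for (crit in c("ML", "ReML")) {
    fit <- lmm_fit(d, method = "FS", criterion = crit,
                   control = lmm_control(tol = 1e-8))
    ref <- lme4::lmer(y ~ x1 + x2 + (1 + z1 | f1) + (1 | f2), data = df,
                      REML = (crit == "ReML"))
    expect_equal(fit$beta, unname(lme4::fixef(ref)), tolerance = 1e-4)
    expect_equal(fit$sigma2, sigma(ref)^2, tolerance = 1e-3)
    vc <- lme4::VarCorr(ref)
    expect_equal(fit$sigma2 * fit$D[[1]],
                 matrix(as.numeric(vc$f1), 2, 2), tolerance = 5e-3)
    expect_equal(fit$sigma2 * fit$D[[2]][1, 1],
                 as.numeric(vc$f2)[1], tolerance = 5e-3)
    # log-likelihoods differ by the dropped 2*pi constant only
    const <- if (crit == "ReML") (d$n - ncol(d$X)) / 2 else d$n / 2
    expect_equal(fit$loglik, as.numeric(stats::logLik(ref)) +
                   const * log(2 * pi), tolerance = 1e-4)
  }
})

test_that("the log-likelihood trace is non-decreasing", {
  for (m in c("FS", "FFS", "SFS", "FSFS", "CSFS")) {
    for (s in c(101, 103)) {
      inst <- small_instance(s, n = 100)
      fit <- suppressWarnings(lmm_fit(inst$design, method = m))
      expect_gte(min(diff(fit$loglik_trace)), -1e-8)
      expect_length(fit$loglik_trace, fit$n_iter + 1L)
    }
  }
})

test_that("the FFS direction is the FS direction mapped through duplication", {
  inst <- small_instance(105, n = 120)
  pf <- inst$pf
  init <- initial_values(pf)
  params <- lmm_params(init$sigma2, init$D)
  cs <- core_solves(pf, params, init$beta)
  sch <- score(pf, params, init$beta, "half", "ML", cs = cs)
  Fh <- fisher_information(pf, params, "half", cs = cs)
  dirh <- solve(Fh$matrix, sch$vector)
  scf <- score(pf, params, init$beta, "full", "ML", cs = cs)
  Ff <- fisher_information(pf, params, "full", scoring_matrix = TRUE, cs = cs)
  dirf <- solve(Ff$matrix, scf$vector)
  p <- pf$p
  expect_equal(dirf[seq_len(p + 1)], dirh[seq_len(p + 1)], tolerance = 1e-8)
  mapped <- c(dirh[seq_len(p + 1)],
              unlist(lapply(seq_len(pf$fs$r), function(k)
                as.numeric(duplication_matrix(pf$fs$q[k]) %*%
                             dirh[Fh$idx$cov[[k]]]))))
  expect_equal(dirf, mapped, tolerance = 1e-8)
})

test_that("ReML residual variance exceeds ML's on almost every replicate", {
  # downward ML bias: paired one-sided sign test over 100 replicates
  st <- sim_setting("custom", n = 60, q = c(1L), l = c(8L),
                    beta = c(1, 0.5, -0.5), sigma2 = 1,
                    D = list(matrix(0.5, 1, 1)))
  wins <- 0L
  for (i in 1:100) {
    ds <- generate_dataset(st, seed = 200 + i)
    fm <- suppressWarnings(lmm_fit(ds$design, method = "SFS",
                                   criterion = "ML"))
    fr <- suppressWarnings(lmm_fit(ds$design, method = "SFS",
                                   criterion = "ReML"))
    if (fr$sigma2 > fm$sigma2) wins <- wins + 1L
  }
  expect_lt(stats::binom.test(wins, 100, 0.5, "greater")$p.value, 0.01)
})

test_that("CSFS returns PSD covariance blocks without projection", {
  # strongly identified instance: the optimum is interior, so the Cholesky
  # path reaches the same maximum as FS
  st <- sim_setting("custom", n = 600, q = c(2L), l = c(30L),
                    beta = c(0.5, -0.25), sigma2 = 1,
                    D = list(matrix(c(1, 0.3, 0.3, 0.8), 2)))
  ds <- generate_dataset(st, seed = 107)
  fc <- suppressWarnings(lmm_fit(ds$design, method = "CSFS"))
  for (Dk in fc$D)
    expect_gte(min(eigen(Dk, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  ff <- lmm_fit(ds$design, method = "FS")
  expect_equal(fc$loglik, ff$loglik, tolerance = 1e-4)
})

test_that("parameter recovery: replicate means hit truth within 3 MC SEs", {
  st <- sim_setting("setting1")
  n_reps <- 200
  est <- matrix(0, n_reps, length(st$beta) + 3)   # beta + vech(sigma2 D_1)
  for (i in seq_len(n_reps)) {
    ds <- generate_dataset(st, seed = 5000 + i)
    f <- suppressWarnings(lmm_fit(ds$design, method = "FSFS",
                                  criterion = "ML"))
    est[i, ] <- c(f$beta, f$sigma2 * vech(f$D[[1]]))
  }
  truth <- c(st$beta, st$sigma2 * vech(st$D[[1]]))
  mc_se <- apply(est, 2, stats::sd) / sqrt(n_reps)
  expect_true(all(abs(colMeans(est) - truth) <= 3 * mc_se))
})

test_that("hitting max_iter reports non-convergence but returns a result", {
  inst <- small_instance(109, n = 100)
  fit <- suppressWarnings(lmm_fit(inst$design, method = "FS",
                                  control = lmm_control(max_iter = 1L)))
  expect_false(fit$converged)
  expect_true(any(grepl("maximum iterations", fit$warnings)))
  expect_length(fit$beta, 3)
})

test_that("lmm_control validates its arguments", {
  expect_error(lmm_control(tol = 0))
  expect_error(lmm_control(max_iter = 0))
})
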