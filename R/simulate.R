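# Synthetic-data generation for the three standard crossed-factor designs,
# plus the benchmarking harnesses (estimation accuracy / iteration counts /
# degrees-of-freedom truth) and an ACE twin-data generator.

#' Simulation settings for the crossed-factor designs
#'
#' Three preset designs: `setting1` (one factor, `q = 2`, `l = 50`),
#' `setting2` (two factors, `q = (3, 2)`, `l = (100, 50)`) and `setting3`
#' (three factors, `q = (4, 3, 2)`, `l = (100, 50, 10)`), each with
#' `n = 1000` observations and `p = 4` fixed effects by default. True
#' parameter values default to documented stand-ins — `beta` entries in
#' `[-1, 1]` with the last one exactly zero (so a truly-null contrast
#' exists), `sigma2 = 1`, and unit-diagonal `D_k` with off-diagonal values
#' 0.5 / 0.25 / 0 for factors 1 / 2 / 3 (mixed zero and nonzero
#' off-diagonals) — and can be overridden with exact values.
#'
#' @param name Preset name, or `"custom"` with `q` and `l` supplied.
#' @param n Number of observations.
#' @param beta True fixed effects (length sets `p`).
#' @param sigma2 True scalar variance.
#' @param D Optional list of true per-factor covariance blocks (replaces the
#'   stand-ins).
#' @param q,l Per-factor effect and level counts for `name = "custom"`.
#' @return An object of class `sim_setting`.
#' @export
sim_setting <- function(name = c("setting1", "setting2", "setting3", "custom"),
                        n = 1000, beta = c(0.5, -0.25, 0.75, 0), sigma2 = 1,
                        D = NULL, q = NULL, l = NULL) {
  name <- match.arg(name)
  if (name == "custom") {
    if (is.null(q) || is.null(l)) stop("custom settings need q and l",
                                       call. = FALSE)
  } else {
    q <- switch(name, setting1 = 2L, setting2 = c(3L, 2L),
                setting3 = c(4L, 3L, 2L))
    l <- switch(name, setting1 = 50L, setting2 = c(100L, 50L),
                setting3 = c(100L, 50L, 10L))
  }
  q <- as.integer(q); l <- as.integer(l)
  if (is.null(D)) {
    off <- c(0.5, 0.25, 0)
    D <- lapply(seq_along(q), function(k) {
      o <- if (k <= 3) off[k] else 0
      M <- matrix(o, q[k], q[k]); diag(M) <- 1
      M
    })
  }
  if (length(D) != length(q) ||
      any(vapply(D, nrow, 1L) != q))
    stop("D must have one q_k x q_k block per factor", call. = FALSE)
  structure(list(name = name, n = as.integer(n), q = q, l = l,
                 beta = as.numeric(beta), sigma2 = as.numeric(sigma2),
                 D = lapply(D, as.matrix)),
            class = "sim_setting")
}

# uniform level assignment, redrawn until every level is occupied (needed
# for identifiability; at the preset sizes a redraw is rare)
draw_levels <- function(n, lk, max_tries = 1000L) {
  for (t in seq_len(max_tries)) {
    lev <- sample.int(lk, n, replace = TRUE)
    if (all(tabulate(lev, nbins = lk) > 0)) return(lev)
  }
  stop("could not occupy all ", lk, " levels with n = ", n, call. = FALSE)
}

#' Generate a synthetic crossed-factor dataset
#'
#' Draws a dataset from the model `Y = X beta + Z b + e` with
#' `b ~ N(0, sigma2 D)`, `e ~ N(0, sigma2 I)`. The first column of `X` and
#' each factor's first random-effect covariate are intercepts (constant 1);
#' all remaining covariates are i.i.d. standard normal; level assignment is
#' i.i.d. uniform over each factor's levels (redrawn if a level comes up
#' empty). Fully reproducible given `seed`.
#'
#' @param setting A [sim_setting()].
#' @param seed Optional integer seed (`set.seed` is called when supplied).
#' @return A list of class `sim_dataset` with `design` (an [lmm_design()]),
#'   `truth` (`beta`, `sigma2`, `D`) and the `setting`.
#' @export
generate_dataset <- function(setting, seed = NULL) {
  stopifnot(inherits(setting, "sim_setting"))
  if (!is.null(seed)) set.seed(seed)
  n <- setting$n
  p <- length(setting$beta)
  X <- cbind(rep(1, n), matrix(stats::rnorm(n * (p - 1)), n, p - 1))
  factors <- lapply(seq_along(setting$q), function(k) {
    qk <- setting$q[k]
    cm <- cbind(rep(1, n),
                matrix(stats::rnorm(n * (qk - 1)), n, qk - 1))
    list(levels = draw_levels(n, setting$l[k]), covariates = cm,
         l = setting$l[k])
  })
  ds <- list(design = NULL, truth = list(beta = setting$beta,
                                         sigma2 = setting$sigma2,
                                         D = setting$D),
             setting = setting)
  Y <- draw_response(X, factors, setting$beta, setting$sigma2, setting$D)
  ds$design <- lmm_design(Y$Y, X, factors)
  ds$b <- Y$b
  class(ds) <- "sim_dataset"
  ds
}

# draw b and e for fixed covariates/levels and return the response;
# row-wise b_k L' gives per-level effects with covariance sigma2 D_k
draw_response <- function(X, factors, beta, sigma2, D) {
  n <- nrow(X)
  mu <- as.numeric(X %*% beta)
  b <- vector("list", length(factors))
  for (k in seq_along(factors)) {
    f <- factors[[k]]
    qk <- ncol(as.matrix(f$covariates))
    lk <- f[["l"]]
    Lk <- chol_factor(sigma2 * D[[k]])
    bk <- matrix(stats::rnorm(lk * qk), lk, qk) %*% t(Lk)
    b[[k]] <- bk
    lev <- f$levels
    ok <- !is.na(lev)
    contrib <- numeric(n)
    contrib[ok] <- rowSums(as.matrix(f$covariates)[ok, , drop = FALSE] *
                             bk[lev[ok], , drop = FALSE])
    mu <- mu + contrib
  }
  list(Y = mu + stats::rnorm(n, sd = sqrt(sigma2)), b = b)
}

#' Redraw the response of a simulated dataset
#'
#' Keeps the design (`X`, covariates, level assignment) fixed and draws new
#' random effects and noise — the resampling scheme the
#' degrees-of-freedom harness requires.
#'
#' @param dataset A `sim_dataset` from [generate_dataset()].
#' @return The dataset with a new response in `design$Y`.
#' @export
resample_response <- function(dataset) {
  d <- dataset$design
  factors <- lapply(seq_len(d$fs$r), function(k)
    list(levels = d$fs$level_of[[k]], covariates = d$covariates[[k]],
         l = d$fs$l[k]))
  Y <- draw_response(d$X, factors, dataset$truth$beta,
                     dataset$truth$sigma2, dataset$truth$D)
  dataset$design$Y <- Y$Y
  dataset$b <- Y$b
  dataset
}

# MAE and MRD of an estimate vector against a reference vector:
# MAE = mean_i |est_i - ref_i|;
# MRD = MAE / mean_i((|est_i| + |ref_i|)/2)
mae_mrd <- function(est, ref) {
  mae <- mean(abs(est - ref))
  den <- mean((abs(est) + abs(ref)) / 2)
  c(mae = mae, mrd = if (den > 0) mae / den else 0)
}

# unique elements of the scaled covariance sigma2 * D as one vector
cov_elements <- function(sigma2, D) {
  unlist(lapply(D, function(Dk) vech(sigma2 * as.matrix(Dk))),
         use.names = FALSE)
}

#' Benchmark the scoring algorithms on simulated data
#'
#' Runs every requested method on identical data in each replicate
#' (one dataset per replicate, shared across methods) and records iteration
#' counts, convergence, final log-likelihood, and the mean absolute error
#' (MAE) and mean relative difference (MRD) of `beta` and of the elements of
#' `sigma2 D` against the generating truth.
#'
#' Replicate datasets use child seeds expanded deterministically from the
#' parent `seed`, so methods never consume overlapping random streams.
#'
#' @param setting A [sim_setting()].
#' @param methods Character vector of methods for [lmm_fit()].
#' @param criterion `"ML"` or `"ReML"`.
#' @param n_reps Number of replicates.
#' @param seed Parent seed.
#' @param control An [lmm_control()].
#' @return A list of class `benchmark_report` with `replicates` (tibble, one
#'   row per replicate x method) and `summary` (tibble, one row per method
#'   with mean/sd iterations, mean MAE/MRD and the convergence-failure
#'   rate).
#' @export
estimation_benchmark <- function(setting,
                                 methods = c("FS", "FFS", "SFS", "FSFS"),
                                 criterion = c("ML", "ReML"),
                                 n_reps = 50, seed = 1,
                                 control = lmm_control()) {
  criterion <- match.arg(criterion)
  stopifnot(n_reps >= 1)
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, n_reps)
  truth_beta <- setting$beta
  truth_cov <- cov_elements(setting$sigma2, setting$D)

  replicates <- purrr::map_dfr(seq_len(n_reps), function(i) {
    ds <- generate_dataset(setting, seed = child[i])
    pf <- product_forms(ds$design)
    purrr::map_dfr(methods, function(m) {
      fit <- tryCatch(lmm_fit(pf, method = m, criterion = criterion,
                              control = control),
                      error = function(e) NULL)
      if (is.null(fit)) {
        return(tibble::tibble(
          rep = i, method = m, converged = FALSE, n_iter = NA_integer_,
          loglik = NA_real_, mae_beta = NA_real_, mrd_beta = NA_real_,
          mae_cov = NA_real_, mrd_cov = NA_real_))
      }
      mb <- mae_mrd(fit$beta, truth_beta)
      mc <- mae_mrd(cov_elements(fit$sigma2, fit$D), truth_cov)
      tibble::tibble(
        rep = i, method = m, converged = fit$converged,
        n_iter = fit$n_iter, loglik = fit$loglik,
        mae_beta = mb["mae"], mrd_beta = mb["mrd"],
        mae_cov = mc["mae"], mrd_cov = mc["mrd"])
    })
  })

  summary <- replicates |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mean_iter = mean(.data$n_iter, na.rm = TRUE),
      sd_iter = stats::sd(.data$n_iter, na.rm = TRUE),
      mean_mae_beta = mean(.data$mae_beta, na.rm = TRUE),
      mean_mrd_beta = mean(.data$mrd_beta, na.rm = TRUE),
      mean_mae_cov = mean(.data$mae_cov, na.rm = TRUE),
      mean_mrd_cov = mean(.data$mrd_cov, na.rm = TRUE),
      failure_rate = mean(!.data$converged),
      .groups = "drop")

  structure(list(replicates = replicates, summary = summary,
                 setting = setting, criterion = criterion, seed = seed),
            class = "benchmark_report")
}

#' Degrees-of-freedom truth harness
#'
#' Fixes one randomly drawn design (`X`, covariates, level assignment), then
#' repeatedly redraws the random effects and noise, ReML-fits each response
#' (FSFS) and records the Satterthwaite degrees of freedom of a truly-null
#' contrast. The harness truth is the moment-matching value
#' `mean(2 S^4) / Var(S^2)` with `S^2` evaluated at each replicate's
#' estimate: the numerator averaged per replicate and the denominator the
#' empirical variance over the (larger) truth run.
#'
#' @param setting A [sim_setting()] whose `beta` has a zero entry (the
#'   default contrast targets the first one).
#' @param L Optional contrast vector; defaults to the indicator of the first
#'   truly-zero fixed effect.
#' @param n_reps Replicates summarised in `mean_dof` / `sd_dof`.
#' @param n_truth_reps Total replicates feeding the truth estimate
#'   (`>= n_reps`; the first `n_reps` of them are the summary set).
#' @param seed Parent seed.
#' @param control An [lmm_control()].
#' @return A list with `mean_dof`, `sd_dof`, `truth_dof`, `n_dropped`
#'   (non-converged replicates, excluded) and the per-replicate tibble.
#' @export
dof_benchmark <- function(setting, L = NULL, n_reps = 100,
                          n_truth_reps = n_reps, seed = 1,
                          control = lmm_control()) {
  stopifnot(n_truth_reps >= n_reps)
  set.seed(seed)
  if (is.null(L)) {
    z <- which(setting$beta == 0)
    if (!length(z))
      stop("setting has no truly-zero fixed effect; supply L", call. = FALSE)
    L <- as.numeric(seq_along(setting$beta) == z[1])
  }
  base <- generate_dataset(setting)
  d <- base$design
  # n-involving cross-products that do not change across response redraws
  Z <- expand_Z(d)
  P <- crossprod(d$X); R <- crossprod(d$X, Z); U <- crossprod(Z)
  child <- sample.int(.Machine$integer.max - 1L, n_truth_reps)

  replicates <- purrr::map_dfr(seq_len(n_truth_reps), function(i) {
    set.seed(child[i])
    ds <- resample_response(base)
    Y <- ds$design$Y
    pf <- structure(
      list(P = P, Q = crossprod(d$X, Y), R = R, S = sum(Y * Y),
           T = matrix(crossprod(Y, Z), nrow = 1), U = U,
           n = d$n, p = ncol(d$X), fs = d$fs),
      class = "product_forms")
    fit <- tryCatch(lmm_fit(pf, method = "FSFS", criterion = "ReML",
                            control = control),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged)
      return(tibble::tibble(rep = i, converged = FALSE,
                            dof = NA_real_, s2 = NA_real_))
    tt <- approx_t(fit, L)
    tibble::tibble(rep = i, converged = TRUE, dof = tt$df, s2 = tt$se^2)
  })

  ok <- replicates$converged
  head_ok <- replicates[ok & replicates$rep <= n_reps, ]
  s2_all <- replicates$s2[ok]
  truth <- if (sum(ok) > 1 && stats::var(s2_all) > 0)
    mean(2 * s2_all^2) / stats::var(s2_all) else Inf
  list(mean_dof = mean(head_ok$dof), sd_dof = stats::sd(head_ok$dof),
       truth_dof = truth, n_dropped = sum(!ok),
       contrast = L, replicates = replicates)
}

#' Generate synthetic twin data for the ACE model
#'
#' Families of fixed size are split into monozygotic (MZ) and dizygotic (DZ)
#' groups; each group is one random factor whose levels are its families
#' (observations outside the group carry an `NA` level and zero design
#' rows), with within-family position indicators as random-effect
#' covariates. Family effects are drawn from
#' `N(0, sigma_a2 K^a + sigma_c2 K^c)` where `K^a` is all-ones for MZ and
#' `0.5 + 0.5 I` for DZ families, and `K^c` is all-ones for both; residuals
#' are `N(0, sigma_e2)`.
#'
#' @param n_families Total number of families (at least 2 per zygosity).
#' @param family_size Members per family (default twins, 2).
#' @param beta True fixed effects (first column of `X` is an intercept,
#'   remaining covariates standard normal).
#' @param sigma_a2,sigma_c2,sigma_e2 True additive-genetic, common-
#'   environment and residual variances.
#' @param mz_prop Proportion of MZ families.
#' @param seed Optional seed.
#' @return A list with `design`, `Ka_list`, `Kc_list`, `spec` (an ACE
#'   [constraint_spec()]) and `truth` (including `tau_a`, `tau_c`).
#' @export
generate_ace_dataset <- function(n_families, family_size = 2,
                                 beta = c(0.5, -0.25),
                                 sigma_a2 = 0.5, sigma_c2 = 0.3,
                                 sigma_e2 = 1, mz_prop = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_mz <- round(mz_prop * n_families)
  n_dz <- n_families - n_mz
  if (n_mz < 2 || n_dz < 2)
    stop("need at least 2 families of each zygosity", call. = FALSE)
  m <- family_size
  n <- n_families * m
  p <- length(beta)
  X <- cbind(rep(1, n), matrix(stats::rnorm(n * (p - 1)), n, p - 1))

  fam <- rep(seq_len(n_families), each = m)
  pos <- rep(seq_len(m), times = n_families)
  is_mz <- fam <= n_mz

  J <- matrix(1, m, m)
  Ka_mz <- J
  Ka_dz <- 0.5 * J + 0.5 * diag(m)
  Kc <- J

  eff <- numeric(n)
  for (f in seq_len(n_families)) {
    Kf <- sigma_a2 * (if (f <= n_mz) Ka_mz else Ka_dz) + sigma_c2 * Kc
    bf <- as.numeric(chol_factor(Kf) %*% stats::rnorm(m))
    eff[fam == f] <- bf[pos[fam == f]]
  }
  Y <- as.numeric(X %*% beta) + eff + stats::rnorm(n, sd = sqrt(sigma_e2))

  posmat <- matrix(0, n, m)
  posmat[cbind(seq_len(n), pos)] <- 1
  design <- lmm_design(Y, X, list(
    list(levels = ifelse(is_mz, fam, NA_integer_), covariates = posmat,
         l = n_mz),
    list(levels = ifelse(is_mz, NA_integer_, fam - n_mz),
         covariates = posmat, l = n_dz)))

  Ka_list <- list(Ka_mz, Ka_dz)
  Kc_list <- list(Kc, Kc)
  list(design = design, Ka_list = Ka_list, Kc_list = Kc_list,
       spec = ace_constraints(Ka_list, Kc_list),
       truth = list(beta = beta, sigma_a2 = sigma_a2, sigma_c2 = sigma_c2,
                    sigma_e2 = sigma_e2,
                    tau_a = sqrt(sigma_a2 / sigma_e2),
                    tau_c = sqrt(sigma_c2 / sigma_e2)))
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("Estimation benchmark (%s, %s, %d replicates)\n",
              x$setting$name, x$criterion,
              max(x$replicates$rep)))
  print(x$summary)
  invisible(x)
}
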