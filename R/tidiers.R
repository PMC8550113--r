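# broom-style tidiers and a diagnostic plot for lmm_fit objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted crossed-factor LMM
#'
#' Returns one row per parameter: the fixed effects, the scalar variance
#' and the unique elements of each scaled covariance block `sigma2 * D_k`.
#'
#' @param x An `lmm_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `group`, `term`, `estimate`.
#' @export
tidy.lmm_fit <- function(x, ...) {
  fixed <- tibble::tibble(
    group = "fixed", term = paste0("beta", seq_along(x$beta)),
    estimate = x$beta)
  varrow <- tibble::tibble(group = "residual", term = "sigma2",
                           estimate = x$sigma2)
  ran <- purrr::map_dfr(seq_along(x$D), function(k) {
    Dk <- x$sigma2 * x$D[[k]]
    q <- nrow(Dk)
    ij <- which(lower.tri(Dk, diag = TRUE), arr.ind = TRUE)
    tibble::tibble(
      group = paste0("factor", k),
      term = sprintf("sigma2D%d[%d,%d]", k, ij[, 1], ij[, 2]),
      estimate = Dk[ij])
  })
  dplyr::bind_rows(fixed, varrow, ran)
}

#' One-row model summary of a fitted crossed-factor LMM
#'
#' @param x An `lmm_fit` object.
#' @param ... Unused.
#' @return A tibble with the log-likelihood (additive constants dropped),
#'   iteration count, convergence flag, method, criterion and sizes.
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, n_iter = x$n_iter, converged = x$converged,
    method = x$method, criterion = x$criterion,
    nobs = x$pf$n, p = x$pf$p, n_factors = x$pf$fs$r)
}

#' Plot the optimisation trace of a fitted crossed-factor LMM
#'
#' Shows the (restricted) log-likelihood across scoring iterations; with
#' step-halving the accepted trace is non-decreasing.
#'
#' @param object An `lmm_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lmm_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$loglik_trace) - 1L,
                       loglik = object$loglik_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "iteration",
      y = if (object$criterion == "ReML") "restricted log-likelihood"
          else "log-likelihood",
      title = sprintf("%s (%s) optimisation trace", object$method,
                      object$criterion)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
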