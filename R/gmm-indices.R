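#' Information criteria and entropy for a mixture fit
#'
#' AIC \eqn{= -2\ell + 2p}, BIC \eqn{= -2\ell + p \ln n}, sample-size
#' adjusted BIC \eqn{= -2\ell + p \ln((n+2)/24)}, and relative entropy
#' \eqn{E_K = 1 - \sum_i \sum_k (-p_{ik} \ln p_{ik}) / (n \ln K)}. Entropy
#' is 1 when every posterior is crisp (0/1) and 0 when all posteriors are
#' uniform; it is undefined for a 1-class model and reported `NA`.
#'
#' @param fit A `gmm_fit`, or a list with `loglik`, `n_params`,
#'   `posterior`.
#' @param n Sample size (defaults to `fit$n` or the posterior row count).
#' @return Named list: `logLik`, `n_params`, `AIC`, `BIC`, `ssBIC`,
#'   `entropy`.
#' @export
fit_indices <- function(fit, n = NULL) {
  ll <- fit$loglik
  p <- fit$n_params
  post <- fit$posterior
  if (is.null(n)) n <- fit$n %||% nrow(post)
  list(logLik = ll, n_params = p,
       AIC = -2 * ll + 2 * p,
       BIC = -2 * ll + p * log(n),
       ssBIC = -2 * ll + p * log((n + 2) / 24),
       entropy = classification_entropy(post))
}

#' @rdname fit_indices
#' @param posterior Posterior class-probability matrix (rows sum to 1).
#' @export
classification_entropy <- function(posterior) {
  K <- ncol(posterior)
  if (K < 2) return(NA_real_)
  n <- nrow(posterior)
  plogp <- posterior * log(posterior)
  plogp[posterior == 0] <- 0
  1 - sum(-plogp) / (n * log(K))
}

#' Lo-Mendell-Rubin likelihood-ratio test for K vs K-1 classes
#'
#' Approximate likelihood-ratio comparison of nested class solutions. The
#' statistic \eqn{2\Delta\ell} is shrunk by the small-sample factor
#' \eqn{c = 1 + ((p_K - p_{K-1}) \ln n)^{-1}} and referred to a chi-square
#' reference with \eqn{2(p_K - p_{K-1})} degrees of freedom -- the
#' "two-times" rule long used for mixture likelihood-ratio statistics,
#' whose null distribution is heavier than the naive chi-square because
#' the mixing proportion sits on the boundary under the smaller model.
#' The approximation is deliberately conservative-to-nominal under the
#' null; a parametric bootstrap ([bootstrap_lrt()]) is available as a
#' cross-check.
#'
#' A negative log-likelihood difference (larger model fitting worse, a
#' symptom of a local maximum) yields p = 1 with a warning.
#'
#' @param fit_K,fit_Kminus1 `gmm_fit` objects for K and K-1 classes fitted
#'   to the same panel.
#' @param n Sample size (defaults from the fits, which must agree).
#' @return List: `statistic` (2 delta loglik), `adjusted` (LMR-corrected
#'   statistic), `df`, `p_value`.
#' @export
lmr_test <- function(fit_K, fit_Kminus1, n = NULL) {
  if (fit_K$K != fit_Kminus1$K + 1)
    stop("fits must differ by exactly one class", call. = FALSE)
  if (fit_K$n != fit_Kminus1$n)
    stop("fits are not on the same panel (different n)", call. = FALSE)
  if (is.null(n)) n <- fit_K$n
  dp <- fit_K$n_params - fit_Kminus1$n_params
  lr <- 2 * (fit_K$loglik - fit_Kminus1$loglik)
  if (lr < 0) {
    warning("larger model has lower log-likelihood (local maximum?); p = 1")
    return(list(statistic = lr, adjusted = lr, df = 2 * dp, p_value = 1))
  }
  cfac <- 1 + 1 / (dp * log(n))
  adj <- lr / cfac
  df <- 2 * dp
  list(statistic = lr, adjusted = adj, df = df,
       p_value = stats::pchisq(adj, df = df, lower.tail = FALSE))
}

#' Parametric bootstrap likelihood-ratio test for K vs K-1 classes
#'
#' Simulates panels from the fitted (K-1)-class model, preserving each
#' participant's missingness pattern, refits both class counts on each
#' replicate and compares the observed \eqn{2\Delta\ell} with the bootstrap
#' null distribution. Slower but free of the analytic approximation in
#' [lmr_test()].
#'
#' @param panel The observed [visit_panel()].
#' @param spec A [growth_spec()].
#' @param K Larger class count.
#' @param B Bootstrap replicates.
#' @param n_starts Starts per refit (modest by design).
#' @param seed Seed.
#' @return List: `statistic`, `p_value`, `boot_stats`.
#' @export
bootstrap_lrt <- function(panel, spec, K, B = 50, n_starts = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fit0 <- gmm_fit(panel, spec, K - 1, n_starts = n_starts)
  fit1 <- gmm_fit(panel, spec, K, n_starts = n_starts)
  stat <- 2 * (fit1$loglik - fit0$loglik)
  boot <- vapply(seq_len(B), function(b) {
    sim <- simulate_from_fit(fit0, panel)
    b0 <- gmm_fit(sim, spec, K - 1, n_starts = n_starts)
    b1 <- gmm_fit(sim, spec, K, n_starts = n_starts)
    2 * (b1$loglik - b0$loglik)
  }, numeric(1))
  list(statistic = stat,
       p_value = (1 + sum(boot >= stat)) / (B + 1),
       boot_stats = boot)
}

#' Simulate a panel from a fitted growth mixture model
#'
#' Draws classes from the fitted mixing proportions, growth effects from
#' the shared covariance, and residuals from the fitted residual variance;
#' the observed/missing mask of `template` is reapplied so the simulated
#' panel has the same coverage.
#'
#' @param fit A `gmm_fit`.
#' @param template A [visit_panel()] providing the missingness mask
#'   (defaults to a complete panel of `fit$n` rows).
#' @return A [visit_panel()].
#' @export
simulate_from_fit <- function(fit, template = NULL) {
  spec <- fit$spec
  L <- growth_loadings(spec, fit$loadings)
  J <- nrow(L)
  n <- if (is.null(template)) fit$n else nrow(unclass(template))
  cls <- sample.int(fit$K, n, replace = TRUE, prob = fit$pi)
  mu <- t(L %*% fit$alpha[, cls, drop = FALSE])
  Z <- L[, random_columns(spec), drop = FALSE]
  b <- draw_bivariate_effects(n, fit$Psi)
  y <- mu + b %*% t(Z) + matrix(stats::rnorm(n * J, 0, sqrt(fit$sigma2)), n, J)
  if (!is.null(template)) y[is.na(unclass(template))] <- NA
  visit_panel(y, times = spec$times)
}

draw_bivariate_effects <- function(n, Psi) {
  r <- nrow(Psi)
  matrix(stats::rnorm(n * r), n, r) %*% t(chol_psd(Psi))
}
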