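#' Growth model specification
#'
#' Defines the latent growth basis for the mixture engine: the loading
#' matrix \eqn{\Lambda} mapping growth factors to the J visit indicators,
#' the time codes, and which factors carry random effects. For the
#' polynomial bases the columns of \eqn{\Lambda} are \eqn{1, t, t^2, t^3}
#' truncated to the order requested; `latent-basis` frees the interior slope
#' loadings (first fixed 0, last fixed 1) and is supported for single-class
#' fits only.
#'
#' Growth-factor covariance (`Psi`) and the occasion residual variance are
#' constrained equal across classes; by default random effects act on the
#' intercept and linear slope, with the quadratic (and cubic) factor means
#' fixed, a common identification choice for mixture growth models.
#'
#' @param basis One of `"intercept"`, `"linear"`, `"quadratic"`, `"cubic"`,
#'   `"latent-basis"`.
#' @param times Numeric time codes \eqn{t_1..t_J} (default 0..J-1 visit
#'   index, 6-month units).
#' @param n_visits Number of visits (used when `times` not given).
#' @param random Factors with random effects, subset of the basis factors.
#' @return An object of class `growth_spec`.
#' @export
growth_spec <- function(basis = c("quadratic", "linear", "intercept",
                                  "cubic", "latent-basis"),
                        times = NULL, n_visits = 10,
                        random = c("intercept", "slope")) {
  basis <- match.arg(basis)
  if (is.null(times)) times <- seq_len(n_visits) - 1
  factors <- switch(basis,
                    "intercept" = "intercept",
                    "linear" = c("intercept", "slope"),
                    "quadratic" = c("intercept", "slope", "quadratic"),
                    "cubic" = c("intercept", "slope", "quadratic", "cubic"),
                    "latent-basis" = c("intercept", "slope"))
  random <- intersect(random, factors)
  if (length(random) == 0) random <- "intercept"
  structure(list(basis = basis, times = as.numeric(times),
                 factors = factors, random = random),
            class = "growth_spec")
}

#' @export
print.growth_spec <- function(x, ...) {
  cat(sprintf("Growth spec: %s basis, %d visits, random effects on %s\n",
              x$basis, length(x$times), paste(x$random, collapse = " + ")))
  invisible(x)
}

#' Loading matrix for a growth spec
#' @param spec A [growth_spec()].
#' @param loadings Free loadings for the latent-basis slope column.
#' @return J x q matrix with columns named by factor.
#' @export
growth_loadings <- function(spec, loadings = NULL) {
  t <- spec$times
  if (spec$basis == "latent-basis") {
    if (is.null(loadings)) {  # default: linear ramp scaled to [0, 1]
      loadings <- (t - t[1]) / (t[length(t)] - t[1])
    }
    L <- cbind(intercept = rep(1, length(t)), slope = loadings)
    return(L)
  }
  q <- length(spec$factors)
  L <- outer(t, 0:(q - 1), `^`)
  colnames(L) <- spec$factors
  L
}

random_columns <- function(spec) match(spec$random, spec$factors)

# Pre-compute per-missing-pattern quantities for FIML evaluation.
prepare_panel <- function(panel, spec, loadings = NULL) {
  Y <- unclass(panel)
  times <- panel_times(panel) %||% (seq_len(ncol(Y)) - 1)
  if (length(times) != length(spec$times) ||
      any(abs(times - spec$times) > 1e-9))
    stop("panel time codes do not match the growth spec", call. = FALSE)
  L <- growth_loadings(spec, loadings)
  Zc <- random_columns(spec)
  obs <- !is.na(Y)
  key <- apply(obs, 1, function(o) paste(as.integer(o), collapse = ""))
  pats <- lapply(split(seq_len(nrow(Y)), key), function(rows) {
    o <- which(obs[rows[1], ])
    X <- L[o, , drop = FALSE]
    Z <- X[, Zc, drop = FALSE]
    list(rows = rows, o = o, X = X, Z = Z,
         XtX = crossprod(X), ZtZ = crossprod(Z),
         Y = Y[rows, o, drop = FALSE])
  })
  list(Y = Y, n = nrow(Y), J = ncol(Y), q = ncol(L), r = length(Zc),
       L = L, patterns = pats, n_obs = sum(obs))
}

# Per-class log component densities under FIML: each participant contributes
# the marginal normal density of their observed sub-vector.
component_logdens <- function(prep, alpha, Psi, sigma2) {
  K <- ncol(alpha)
  logf <- matrix(NA_real_, prep$n, K)
  for (pat in prep$patterns) {
    S <- pat$Z %*% Psi %*% t(pat$Z) + diag(sigma2, length(pat$o))
    R <- tryCatch(chol(S), error = function(e)
      stop("marginal covariance not positive definite", call. = FALSE))
    logdet <- 2 * sum(log(diag(R)))
    const <- -0.5 * (length(pat$o) * log(2 * pi) + logdet)
    for (k in seq_len(K)) {
      mu <- as.vector(pat$X %*% alpha[, k])
      resid <- sweep(pat$Y, 2, mu)
      U <- backsolve(R, t(resid), transpose = TRUE)
      logf[pat$rows, k] <- const - 0.5 * colSums(U^2)
    }
  }
  logf
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Observed-data log-likelihood of a growth mixture model
#'
#' Full-information maximum likelihood: each participant contributes
#' \eqn{\log \sum_k \pi_k \phi(y_i^{obs}; \Lambda^{obs}\alpha_k,
#' \Sigma^{obs})} with \eqn{\Sigma = \Lambda_r \Psi \Lambda_r' + \sigma^2 I}
#' restricted to the participant's observed visits. Missing-at-random
#' visits are thereby integrated out exactly.
#'
#' @param panel A [visit_panel()].
#' @param fit A `gmm_fit`, or a list with elements `spec`, `pi`, `alpha`
#'   (q x K), `Psi`, `sigma2` (and `loadings` for a latent-basis spec).
#' @return Log-likelihood (scalar).
#' @export
gmm_loglik <- function(panel, fit) {
  prep <- prepare_panel(panel, fit$spec, fit$loadings)
  logf <- component_logdens(prep, fit$alpha, fit$Psi, fit$sigma2)
  sum(logsumexp_rows(sweep(logf, 2, log(fit$pi), `+`)))
}
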