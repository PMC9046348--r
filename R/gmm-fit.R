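#' Fit a growth mixture model by EM
#'
#' Maximum-likelihood estimation of a K-class growth mixture model on a
#' visit panel with missing data. Estimation is EM with full-information
#' maximum likelihood: the E-step computes class posteriors and the
#' conditional moments of the random growth effects from each participant's
#' observed sub-vector; the M-step updates mixing proportions and class
#' growth-factor means in closed form and the shared growth-factor
#' covariance `Psi` and residual variance in closed form from the expected
#' complete-data sufficient statistics. The observed-data log-likelihood is
#' non-decreasing across iterations and is checked.
#'
#' Starting values come from k-means clustering of per-participant
#' least-squares growth coefficients; subsequent starts perturb the class
#' means randomly. All starts are run for `short_iter` iterations and the
#' most promising are run to convergence (absolute log-likelihood change
#' below `tol` or `max_iter` iterations), mirroring the usual two-stage
#' multi-start strategy for mixture likelihoods. Whether the best
#' log-likelihood was replicated by a second start (within 1e-4) is
#' recorded in the convergence record so local-maximum convergence can be
#' flagged.
#'
#' Classes are reported in canonical order of descending intercept mean, so
#' class 1 is always the highest-performing class.
#'
#' @param panel A [visit_panel()].
#' @param spec A [growth_spec()]; `latent-basis` is supported for K = 1
#'   only (fitted by direct quasi-Newton maximization).
#' @param K Number of latent classes (>= 1).
#' @param n_starts Number of random starts (>= 1).
#' @param seed Optional seed for start generation.
#' @param max_iter,tol EM convergence controls.
#' @param short_iter Iterations for the first multi-start stage.
#' @param n_final Number of starts run to full convergence.
#' @param se Compute standard errors for the growth-factor means from the
#'   numerically differentiated observed information (plain ML).
#' @return An object of class `gmm_fit` with elements `K`, `pi`, `alpha`
#'   (factors x classes), `Psi`, `sigma2`, `posterior`, `loglik`,
#'   `n_params`, `n`, `spec`, `convergence`, and optionally `alpha_se`.
#' @export
gmm_fit <- function(panel, spec, K, n_starts = 50, seed = NULL,
                    max_iter = 2000, tol = 1e-6, short_iter = 30,
                    n_final = max(2L, ceiling(n_starts / 10)), se = FALSE) {
  stopifnot(K >= 1, n_starts >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (spec$basis == "latent-basis") {
    if (K > 1)
      stop("latent-basis growth is supported for K = 1 only", call. = FALSE)
    return(fit_latent_basis_k1(panel, spec, se = se))
  }
  prep <- prepare_panel(panel, spec)
  init0 <- initial_values(prep, K)
  n_final <- min(n_final, n_starts)

  stage1 <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    par <- if (s == 1) init0 else perturb_start(init0, prep, K)
    stage1[[s]] <- em_run(prep, par, max_iter = short_iter, tol = tol)
  }
  ll1 <- vapply(stage1, function(r) if (r$degenerate) -Inf else r$loglik,
                numeric(1))
  if (all(!is.finite(ll1)))
    stop("all EM starts degenerated (empty class); ",
         "try fewer classes or more data", call. = FALSE)
  order1 <- order(ll1, decreasing = TRUE)
  finals <- lapply(order1[seq_len(min(n_final, sum(is.finite(ll1))))],
                   function(s) em_run(prep, stage1[[s]]$par,
                                      max_iter = max_iter, tol = tol))
  llf <- vapply(finals, function(r) if (r$degenerate) -Inf else r$loglik,
                numeric(1))
  best <- finals[[which.max(llf)]]
  if (best$degenerate)
    stop("best EM run degenerated (empty class)", call. = FALSE)
  replicated <- sum(abs(llf[is.finite(llf)] - max(llf)) < 1e-4) >= 2

  par <- best$par
  ord <- order(par$alpha[1, ], decreasing = TRUE)   # canonical class order
  par$alpha <- par$alpha[, ord, drop = FALSE]
  par$pi <- par$pi[ord]
  post <- best$posterior[, ord, drop = FALSE]
  dimnames(par$alpha) <- list(spec$factors, paste0("class", seq_len(K)))
  names(par$pi) <- colnames(par$alpha)
  colnames(post) <- colnames(par$alpha)
  rownames(post) <- rownames(prep$Y)

  r <- prep$r
  n_params <- (K - 1) + K * prep$q + r * (r + 1) / 2 + 1
  fit <- structure(list(
    K = K, pi = par$pi, alpha = par$alpha, Psi = par$Psi,
    sigma2 = par$sigma2, posterior = post, loglik = best$loglik,
    n_params = n_params, n = prep$n, J = prep$J, spec = spec,
    loadings = NULL,
    convergence = list(n_starts = n_starts,
                       loglik_by_start = ll1,
                       final_logliks = llf,
                       iterations = best$iterations,
                       converged = best$converged,
                       best_replicated = replicated,
                       loglik_trace = best$loglik_trace,
                       notes = best$notes)),
    class = "gmm_fit")
  if (se) fit$alpha_se <- gmm_alpha_se(panel, fit)
  fit
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("Growth mixture model: K = %d, %s basis, logLik = %.3f\n",
              x$K, x$spec$basis, x$loglik))
  cat("Mixing proportions:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  cat("Growth-factor means:\n")
  print(round(x$alpha, 3))
  cat("Shared Psi (random", paste(x$spec$random, collapse = "+"),
      ") diag:", paste(sprintf("%.3f", diag(x$Psi)), collapse = " "),
      "; residual variance:", sprintf("%.3f", x$sigma2), "\n")
  if (!x$convergence$best_replicated)
    cat("Note: best log-likelihood not replicated across starts\n")
  invisible(x)
}

# ---- EM internals ---------------------------------------------------------

initial_values <- function(prep, K) {
  # per-participant ridge least-squares growth coefficients
  coefs <- matrix(NA_real_, prep$n, prep$q)
  resid_ss <- 0; resid_n <- 0
  for (pat in prep$patterns) {
    B <- t(solve(pat$XtX + diag(0.01, prep$q), t(pat$X) %*% t(pat$Y)))
    coefs[pat$rows, ] <- B
    fitted <- B %*% t(pat$X)
    resid_ss <- resid_ss + sum((pat$Y - fitted)^2)
    resid_n <- resid_n + length(pat$Y)
  }
  km <- tryCatch(stats::kmeans(coefs, centers = K, nstart = 5),
                 error = function(e) NULL)
  if (is.null(km)) {
    qs <- stats::quantile(coefs[, 1], probs = seq(0.1, 0.9, length.out = K))
    alpha <- rbind(qs, matrix(0, prep$q - 1, K))
    pi0 <- rep(1 / K, K)
  } else {
    alpha <- t(km$centers)
    pi0 <- pmax(km$size, 1) / sum(pmax(km$size, 1))
  }
  r <- prep$r
  Psi0 <- diag(pmax(apply(coefs[, seq_len(r), drop = FALSE], 2,
                          stats::var, na.rm = TRUE) / 2, 0.05),
               nrow = r)
  sigma2_0 <- max(resid_ss / max(resid_n, 1), 0.5)
  list(pi = pi0, alpha = alpha, Psi = Psi0, sigma2 = sigma2_0)
}

perturb_start <- function(init, prep, K) {
  scale <- apply(init$alpha, 1, stats::sd)
  fallback <- pmax(abs(init$alpha[, 1]) * 0.1, 0.5)
  bad <- !is.finite(scale) | scale < 1e-6
  scale[bad] <- fallback[bad]
  init$alpha <- init$alpha +
    matrix(stats::rnorm(length(init$alpha), 0, 1), nrow(init$alpha)) * scale
  w <- stats::rexp(K) + 0.25
  init$pi <- w / sum(w)
  init
}

em_run <- function(prep, par, max_iter, tol) {
  K <- length(par$pi)
  ll_old <- -Inf
  notes <- character(0)
  post <- NULL
  converged <- FALSE
  it <- 0
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    step <- tryCatch(em_iteration(prep, par),
                     error = function(e) e)
    if (inherits(step, "error"))
      return(list(par = par, loglik = ll_old, posterior = post,
                  degenerate = TRUE, iterations = it, converged = FALSE,
                  loglik_trace = trace,
                  notes = c(notes, conditionMessage(step))))
    if (step$degenerate)
      return(list(par = par, loglik = step$loglik, posterior = step$posterior,
                  degenerate = TRUE, iterations = it, converged = FALSE,
                  loglik_trace = trace,
                  notes = c(notes, step$notes)))
    par <- step$par
    post <- step$posterior
    trace <- c(trace, step$loglik)
    notes <- unique(c(notes, step$notes))
    if (step$loglik < ll_old - 1e-6)
      notes <- c(notes, sprintf("log-likelihood decreased at iteration %d", it))
    if (is.finite(ll_old) && abs(step$loglik - ll_old) < tol) {
      ll_old <- step$loglik
      converged <- TRUE
      break
    }
    ll_old <- step$loglik
  }
  list(par = par, loglik = ll_old, posterior = post, degenerate = FALSE,
       iterations = it, converged = converged, loglik_trace = trace,
       notes = notes)
}

em_iteration <- function(prep, par) {
  K <- length(par$pi)
  r <- prep$r
  q <- prep$q
  notes <- character(0)

  ## E-step -----------------------------------------------------------------
  logf <- component_logdens(prep, par$alpha, par$Psi, par$sigma2)
  lw <- sweep(logf, 2, log(pmax(par$pi, 1e-300)), `+`)
  lse <- logsumexp_rows(lw)
  loglik <- sum(lse)
  post <- exp(lw - lse)
  wk <- colSums(post)
  if (any(wk < 1e-4))
    return(list(degenerate = TRUE, loglik = loglik, posterior = post,
                notes = "class collapsed to (near) zero weight"))

  ## guard Psi for inversion
  Psi <- par$Psi
  ev <- eigen(Psi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8 * max(ev, 1e-8)) {
    Psi <- Psi + diag(1e-6 * max(diag(Psi), 1e-6), r)
    notes <- c(notes, "near-singular Psi ridged")
  }
  Psi_inv <- solve(Psi)

  ## M-step -----------------------------------------------------------------
  A <- array(0, c(q, q, K)); bvec <- matrix(0, q, K)
  Mstore <- vector("list", length(prep$patterns))
  for (pi_idx in seq_along(prep$patterns)) {
    pat <- prep$patterns[[pi_idx]]
    V <- solve(pat$ZtZ / par$sigma2 + Psi_inv)
    Mk <- vector("list", K)
    for (k in seq_len(K)) {
      mu <- as.vector(pat$X %*% par$alpha[, k])
      resid <- sweep(pat$Y, 2, mu)
      Mk[[k]] <- (resid %*% pat$Z %*% V) / par$sigma2   # rows x r
      pk <- post[pat$rows, k]
      target <- pat$Y - Mk[[k]] %*% t(pat$Z)
      A[, , k] <- A[, , k] + sum(pk) * pat$XtX
      bvec[, k] <- bvec[, k] + t(pat$X) %*% colSums(pk * target)
    }
    Mstore[[pi_idx]] <- list(V = V, Mk = Mk)
  }
  alpha_new <- vapply(seq_len(K),
                      function(k) solve(A[, , k], bvec[, k]), numeric(q))
  alpha_new <- matrix(alpha_new, q, K)

  Psi_acc <- matrix(0, r, r)
  sse <- 0
  for (pi_idx in seq_along(prep$patterns)) {
    pat <- prep$patterns[[pi_idx]]
    st <- Mstore[[pi_idx]]
    npat <- length(pat$rows)
    trZVZ <- sum(pat$Z * (pat$Z %*% st$V))
    Psi_acc <- Psi_acc + npat * st$V
    for (k in seq_len(K)) {
      pk <- post[pat$rows, k]
      mu <- as.vector(pat$X %*% alpha_new[, k])
      e <- sweep(pat$Y, 2, mu) - st$Mk[[k]] %*% t(pat$Z)
      sse <- sse + sum(pk * rowSums(e^2)) + sum(pk) * trZVZ
      Psi_acc <- Psi_acc + crossprod(sqrt(pk) * st$Mk[[k]])
    }
  }
  par_new <- list(pi = wk / prep$n,
                  alpha = alpha_new,
                  Psi = (Psi_acc + t(Psi_acc)) / (2 * prep$n),
                  sigma2 = max(sse / prep$n_obs, 1e-10))
  list(par = par_new, loglik = loglik, posterior = post,
       degenerate = FALSE, notes = notes)
}

# ---- standard errors ------------------------------------------------------

#' Standard errors of growth-factor means and mixing proportions
#'
#' Numerically differentiates the observed-data log-likelihood to obtain
#' the observed information matrix over all free parameters (growth means,
#' log-Cholesky of Psi, log residual SD, multinomial-logit mixing weights)
#' and returns delta-method SEs for the class growth-factor means and the
#' mixing proportions. These are plain ML information-based SEs, not
#' robust (sandwich) SEs.
#'
#' @param panel The fitted panel.
#' @param fit A `gmm_fit`.
#' @return `gmm_param_se`: list with `alpha_se` (matrix shaped like
#'   `fit$alpha`) and `pi_se` (length-K vector). `gmm_alpha_se` returns
#'   just the matrix.
#' @export
gmm_param_se <- function(panel, fit) {
  prep <- prepare_panel(panel, fit$spec, fit$loadings)
  K <- fit$K; q <- prep$q; r <- prep$r
  pack <- function(par) {
    Lc <- chol(par$Psi + diag(1e-12, r))
    th <- c(as.vector(par$alpha),
            log(diag(Lc)), Lc[upper.tri(Lc)],
            0.5 * log(par$sigma2))
    if (K > 1) th <- c(th, log(par$pi[-1] / par$pi[1]))
    th
  }
  unpack <- function(th) {
    i <- 0
    alpha <- matrix(th[seq_len(q * K)], q, K); i <- q * K
    ld <- th[i + seq_len(r)]; i <- i + r
    nut <- r * (r - 1) / 2
    Lc <- diag(exp(ld), r)
    if (nut > 0) { Lc[upper.tri(Lc)] <- th[i + seq_len(nut)]; i <- i + nut }
    sigma2 <- exp(2 * th[i + 1]); i <- i + 1
    pi <- if (K > 1) {
      e <- exp(c(0, th[i + seq_len(K - 1)])); e / sum(e)
    } else 1
    list(alpha = alpha, Psi = crossprod(Lc), sigma2 = sigma2, pi = pi)
  }
  negll <- function(th) {
    par <- unpack(th)
    logf <- component_logdens(prep, par$alpha, par$Psi, par$sigma2)
    -sum(logsumexp_rows(sweep(logf, 2, log(pmax(par$pi, 1e-300)), `+`)))
  }
  th0 <- pack(fit)
  H <- pracma::hessian(negll, th0)
  cov <- tryCatch(solve(H), error = function(e) {
    warning("observed information singular; SEs unavailable")
    matrix(NA_real_, length(th0), length(th0))
  })
  alpha_se <- matrix(sqrt(pmax(diag(cov)[seq_len(q * K)], 0)), q, K,
                     dimnames = dimnames(fit$alpha))
  pi_se <- rep(NA_real_, K)
  if (K > 1) {
    tix <- length(th0) - (K - 1) + seq_len(K - 1)
    cov_t <- cov[tix, tix, drop = FALSE]
    Jac <- matrix(0, K, K - 1)   # d pi_k / d logit_j (logits for classes 2..K)
    for (k in seq_len(K)) for (j in seq_len(K - 1))
      Jac[k, j] <- fit$pi[k] * ((k == j + 1) - fit$pi[j + 1])
    pi_se <- sqrt(pmax(diag(Jac %*% cov_t %*% t(Jac)), 0))
  }
  list(alpha_se = alpha_se, pi_se = pi_se)
}

#' @rdname gmm_param_se
#' @export
gmm_alpha_se <- function(panel, fit) gmm_param_se(panel, fit)$alpha_se

# ---- latent basis (K = 1) -------------------------------------------------

fit_latent_basis_k1 <- function(panel, spec, se = FALSE) {
  prep0 <- prepare_panel(panel, growth_spec("linear", times = spec$times,
                                            random = spec$random))
  J <- length(spec$times)
  nfree <- J - 2
  r <- 2
  pack_len <- 2 + nfree + 3 + 1
  obj <- function(th) {
    if (any(!is.finite(th))) return(1e10)
    alpha <- matrix(th[1:2], 2, 1)
    lam <- c(0, th[2 + seq_len(nfree)], 1)
    ld <- pmin(th[2 + nfree + 1:2], 20)
    off <- th[2 + nfree + 3]
    Lc <- diag(exp(ld)); Lc[1, 2] <- off
    Psi <- crossprod(Lc)
    sigma2 <- exp(2 * pmin(th[pack_len], 20))
    tryCatch({
      prep <- prepare_panel(panel, spec, loadings = lam)
      logf <- component_logdens(prep, alpha, Psi, sigma2)
      -sum(logf)
    }, error = function(e) 1e10)
  }
  # initialize from the linear model
  lin <- gmm_fit(panel, growth_spec("linear", times = spec$times,
                                    random = spec$random),
                 K = 1, n_starts = 1)
  lam0 <- (spec$times - spec$times[1]) / diff(range(spec$times))
  slope_scale <- lin$alpha[2, 1] * diff(range(spec$times))
  th0 <- c(lin$alpha[1, 1], slope_scale, lam0[-c(1, J)],
           0.5 * log(pmax(diag(lin$Psi), 0.1)) *
             c(1, 1) + c(0, log(max(abs(diff(range(spec$times))), 1))),
           0, 0.5 * log(lin$sigma2))
  opt <- stats::optim(th0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  th <- opt$par
  alpha <- matrix(th[1:2], 2, 1,
                  dimnames = list(c("intercept", "slope"), "class1"))
  lam <- unname(c(0, th[2 + seq_len(nfree)], 1))
  Lc <- diag(exp(th[2 + nfree + 1:2])); Lc[1, 2] <- th[2 + nfree + 3]
  Psi <- crossprod(Lc)
  sigma2 <- exp(2 * th[pack_len])
  n <- nrow(unclass(panel))
  structure(list(
    K = 1L, pi = c(class1 = 1), alpha = alpha, Psi = Psi, sigma2 = sigma2,
    posterior = matrix(1, n, 1, dimnames = list(rownames(panel), "class1")),
    loglik = -opt$value,
    n_params = 2 + nfree + 3 + 1, n = n, J = J, spec = spec,
    loadings = lam,
    convergence = list(n_starts = 1, iterations = opt$counts[1],
                       converged = opt$convergence == 0,
                       best_replicated = TRUE, notes = character(0))),
    class = "gmm_fit")
}
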