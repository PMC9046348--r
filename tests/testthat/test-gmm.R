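# Independent multivariate-normal log-density used as oracle throughout.
oracle_dmvnorm_log <- function(y, mu, S) {
  d <- length(y)
  -0.5 * (d * log(2 * pi) + determinant(S)$modulus[1] +
            t(y - mu) %*% solve(S) %*% (y - mu))[1]
}

test_that("single-class complete-data likelihood equals the closed form", {
  set.seed(10)
  tt <- 0:4
  spec <- growth_spec("quadratic", times = tt)
  alpha <- matrix(c(45, -0.5, 0.05), 3)
  Psi <- matrix(c(9, 0.5, 0.5, 0.25), 2)
  s2 <- 4
  L <- cbind(1, tt, tt^2)
  S <- L[, 1:2] %*% Psi %*% t(L[, 1:2]) + diag(s2, 5)
  mu <- as.vector(L %*% alpha)
  Y <- matrix(rnorm(30, 45, 6), 6, 5)
  p <- visit_panel(Y, times = tt)
  ll <- gmm_loglik(p, list(spec = spec, pi = 1, alpha = alpha,
                           Psi = Psi, sigma2 = s2))
  ll_oracle <- sum(apply(Y, 1, oracle_dmvnorm_log, mu = mu, S = S))
  expect_equal(ll, ll_oracle, tolerance = 1e-10)
})

test_that("FIML equals explicit marginalization over missing coordinates", {
  spec <- growth_spec("linear", times = 0:2)
  alpha <- cbind(c(45, -1), c(35, 0.5))
  Psi <- matrix(c(9, 1, 1, 0.25), 2)
  s2 <- 4
  pi_k <- c(0.6, 0.4)
  Y <- rbind(c(44, 42, NA), c(36, NA, 38), c(50, 48, 47))
  p <- visit_panel(Y, times = 0:2)
  ll <- gmm_loglik(p, list(spec = spec, pi = pi_k, alpha = alpha,
                           Psi = Psi, sigma2 = s2))
  # oracle: numerically integrate the full trivariate density over the
  # missing coordinate
  L <- cbind(1, 0:2)
  S <- L %*% Psi %*% t(L) + diag(s2, 3)
  lik_row <- function(y) {
    miss <- which(is.na(y))
    f <- 0
    for (k in 1:2) {
      mu <- as.vector(L %*% alpha[, k])
      fk <- if (length(miss) == 0) exp(oracle_dmvnorm_log(y, mu, S))
      else stats::integrate(Vectorize(function(z) {
        yy <- y; yy[miss] <- z
        exp(oracle_dmvnorm_log(yy, mu, S))
      }), -Inf, Inf, rel.tol = 1e-12)$value
      f <- f + pi_k[k] * fk
    }
    log(f)
  }
  ll_oracle <- sum(apply(Y, 1, lik_row))
  expect_equal(ll, ll_oracle, tolerance = 1e-10)
})

test_that("duplicating every participant doubles the log-likelihood", {
  set.seed(11)
  Y <- matrix(rnorm(40, 42, 5), 8, 5)
  Y[2, 4] <- NA; Y[5, 1:2] <- NA
  spec <- growth_spec("quadratic", times = 0:4)
  fitpar <- list(spec = spec, pi = c(0.5, 0.5),
                 alpha = cbind(c(45, 0, 0), c(38, -0.5, 0.05)),
                 Psi = diag(c(4, 0.1)), sigma2 = 9)
  ll1 <- gmm_loglik(visit_panel(Y, times = 0:4), fitpar)
  ll2 <- gmm_loglik(visit_panel(rbind(Y, Y), times = 0:4), fitpar)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-12)
})

test_that("K = 1 EM agrees with a direct numerical maximizer", {
  cfg <- generator_config(n_participants = 150, class_proportions = 1,
                          seed = 5,
                          class_growth_means = matrix(c(42, -0.5, 0.06), 1))
  co <- generate_cohort(cfg)
  p <- build_panel(co)
  sp <- growth_spec("quadratic", times = 0:9)
  f1 <- gmm_fit(p, sp, K = 1, n_starts = 1)
  negll <- function(th) {
    a <- matrix(th[1:3], 3)
    Lc <- diag(exp(pmin(th[4:5], 20))); Lc[1, 2] <- th[6]
    tryCatch(-gmm_loglik(p, list(spec = sp, pi = 1, alpha = a,
                                 Psi = crossprod(Lc),
                                 sigma2 = exp(2 * pmin(th[7], 20)))),
             error = function(e) 1e10)
  }
  o <- optim(c(40, 0, 0, log(3), log(0.3), 0, log(3)), negll,
             method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(f1$loglik, -o$value, tolerance = 1e-4)
  expect_equal(unname(f1$alpha[, 1]), o$par[1:3], tolerance = 1e-3)
})

test_that("well-separated classes give crisp posteriors and exact means", {
  alpha <- cbind(c(80, 0, 0), c(20, 0, 0))
  sim <- simulate_quadratic_panel(120, alpha, c(0.5, 0.5), int_sd = 0.01,
                                  slope_sd = 0.001, resid_sd = 0.05,
                                  J = 6, seed = 17)
  fit <- gmm_fit(sim$panel, growth_spec("quadratic", times = 0:5), K = 2,
                 n_starts = 4, seed = 1)
  expect_true(all(pmax(fit$posterior[, 1], fit$posterior[, 2]) > 1 - 1e-8))
  expect_equal(unname(fit$alpha[1, ]), c(80, 20), tolerance = 0.05)
  expect_equal(classification_entropy(fit$posterior), 1, tolerance = 1e-6)
  # modal assignment recovers the simulated classes (canonical order:
  # class 1 has the higher intercept)
  expect_equal(modal_assign(fit$posterior), sim$class)
})

test_that("the EM log-likelihood trace is monotone non-decreasing", {
  sim <- simulate_quadratic_panel(
    200, cbind(c(49.6, 0, 0.04), c(41.9, -0.45, 0.07), c(34.2, -1, 0.12)),
    c(31, 100, 53) / 184, seed = 23)
  Y <- unclass(sim$panel)
  Y[sample(length(Y), 300)] <- NA   # sprinkle missingness
  p <- suppressWarnings(visit_panel(Y, times = 0:9))
  fit <- gmm_fit(p, growth_spec("quadratic", times = 0:9), K = 3,
                 n_starts = 6, seed = 2)
  tr <- fit$convergence$loglik_trace
  expect_gt(length(tr), 3)
  expect_true(all(diff(tr) > -1e-6))
})

test_that("classes report in canonical descending-intercept order and the
           likelihood is label-permutation invariant", {
  sim <- simulate_quadratic_panel(
    250, cbind(c(50, 0, 0), c(35, -0.5, 0.05)), c(0.4, 0.6),
    int_sd = 2, resid_sd = 3, J = 8, seed = 31)
  p <- sim$panel
  spec <- growth_spec("quadratic", times = 0:7)
  fit <- gmm_fit(p, spec, K = 2, n_starts = 4, seed = 3)
  expect_true(all(diff(fit$alpha[1, ]) < 0))
  perm <- list(spec = spec, pi = rev(fit$pi),
               alpha = fit$alpha[, 2:1], Psi = fit$Psi,
               sigma2 = fit$sigma2)
  expect_equal(gmm_loglik(p, perm), fit$loglik, tolerance = 1e-9)
})

test_that("information criteria and entropy match their closed forms", {
  post <- diag(3)[c(1, 2, 3, 1), ]
  fake <- list(loglik = -100, n_params = 10, posterior = post, n = 184)
  idx <- fit_indices(fake)
  expect_equal(idx$AIC, 220)
  expect_equal(idx$BIC, 200 + 10 * log(184))
  expect_equal(idx$ssBIC, 200 + 10 * log(186 / 24))
  expect_equal(idx$entropy, 1)
  unif <- matrix(1 / 3, 5, 3)
  expect_equal(classification_entropy(unif), 0)
  expect_true(is.na(classification_entropy(matrix(1, 4, 1))))
  # ssBIC penalty is below the BIC penalty whenever n > 22
  for (n in c(23, 50, 184, 1000))
    expect_lt(log((n + 2) / 24), log(n))
})

test_that("the LMR test degrades gracefully on trivial comparisons", {
  f2 <- list(K = 2, n = 184, loglik = -1000, n_params = 11)
  f1 <- list(K = 1, n = 184, loglik = -1000, n_params = 7)
  res <- lmr_test(f2, f1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  f2b <- list(K = 2, n = 184, loglik = -1001, n_params = 11)
  expect_warning(res2 <- lmr_test(f2b, f1), "local maximum")
  expect_equal(res2$p_value, 1)
  expect_error(lmr_test(f2, list(K = 3, n = 184, loglik = 0, n_params = 2)),
               "exactly one class")
})

test_that("the LMR test detects well-separated extra classes", {
  sim <- simulate_quadratic_panel(
    300, cbind(c(60, 0, 0), c(30, 0, 0)), c(0.5, 0.5),
    int_sd = 2, resid_sd = 3, J = 6, seed = 41)
  spec <- growth_spec("quadratic", times = 0:5)
  f1 <- gmm_fit(sim$panel, spec, 1, n_starts = 1)
  f2 <- gmm_fit(sim$panel, spec, 2, n_starts = 4, seed = 4)
  expect_lt(lmr_test(f2, f1)$p_value, 1e-6)
})

test_that("covariance coverage counts pairwise observation exactly", {
  Y <- rbind(c(1, 2, 3), c(1, NA, 3), c(NA, NA, 3), c(1, 2, NA))
  p <- visit_panel(Y, times = 0:2)
  cc <- covariance_coverage(p)
  hand <- rbind(c(3, 2, 2), c(2, 2, 1), c(2, 1, 3)) / 4
  expect_equal(unname(cc$matrix), hand)
  expect_equal(cc$minimum, 0.25)
  full <- visit_panel(matrix(1, 5, 3), times = 0:2)
  expect_equal(unname(covariance_coverage(full)$matrix),
               matrix(1, 3, 3))
  sparse <- visit_panel(rbind(c(1, NA), c(1, NA), c(1, NA), c(1, NA),
                              c(1, NA), c(1, NA), c(1, NA), c(1, NA),
                              c(1, NA), c(1, NA), c(1, NA), c(NA, 1)),
                        times = 0:1)
  expect_warning(covariance_coverage(sparse), "below")
})

test_that("simulated fits are reproducible and respect the template mask", {
  sim <- simulate_quadratic_panel(
    60, cbind(c(50, 0, 0), c(35, 0, 0)), c(0.5, 0.5), J = 5, seed = 3)
  fit <- gmm_fit(sim$panel, growth_spec("quadratic", times = 0:4), K = 2,
                 n_starts = 2, seed = 5)
  Y <- unclass(sim$panel); Y[1, 3] <- NA; Y[10, 4:5] <- NA
  tmpl <- visit_panel(Y, times = 0:4)
  set.seed(7)
  s1 <- simulate_from_fit(fit, tmpl)
  set.seed(7)
  s2 <- simulate_from_fit(fit, tmpl)
  expect_identical(unclass(s1), unclass(s2))
  expect_true(all(is.na(unclass(s1)[is.na(Y)])))
})
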