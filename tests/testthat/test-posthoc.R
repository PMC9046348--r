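test_that("modal assignment takes the posterior argmax with logged ties", {
  expect_equal(modal_assign(matrix(c(0.9, 0.05, 0.05), 1)), 1)
  expect_message(lab <- modal_assign(matrix(c(0.5, 0.5, 0), 1)), "tie")
  expect_equal(lab, 1)
  expect_error(modal_assign(matrix(c(0.6, 0.3), 1)), "sum to 1")
  # brute-force argmax oracle on random posteriors
  set.seed(131)
  P <- matrix(rexp(3000), 1000, 3)
  P <- P / rowSums(P)
  oracle <- apply(P, 1, which.max)
  expect_equal(modal_assign(P), oracle)
})

test_that("univariable screening dispatches tests and applies the 0.10 rule", {
  set.seed(141)
  n <- 300
  cls <- sample(1:3, n, replace = TRUE)
  cov <- data.frame(
    shifted = rnorm(n) + (cls == 3),          # 1 SD shift: should select
    noise = rnorm(n),
    constant = 5,
    count = rnbinom(n, size = 1, mu = 2 + 2 * (cls == 3)),
    cat_sparse = factor(ifelse(runif(n) < 0.02, "rare", "common")),
    cat_bal = factor(sample(c("a", "b"), n, replace = TRUE)))
  sc <- univariable_screen(cov, cls, skewed = "count")
  expect_true(sc$selected[sc$variable == "shifted"])
  expect_identical(sc$test[sc$variable == "shifted"], "ANOVA F")
  expect_identical(sc$test[sc$variable == "count"], "Kruskal-Wallis")
  expect_true(sc$selected[sc$variable == "count"])
  expect_match(sc$note[sc$variable == "constant"], "constant")
  expect_false(sc$selected[sc$variable == "constant"])
  expect_identical(sc$test[sc$variable == "cat_sparse"], "Fisher exact")
  expect_identical(sc$test[sc$variable == "cat_bal"], "chi-square")
  expect_error(univariable_screen(cov, rep(1, n)), "two classes")
})

test_that("a covariate identical across classes is effectively never selected", {
  set.seed(151)
  hits <- replicate(40, {
    cls <- sample(1:3, 200, replace = TRUE)
    sc <- univariable_screen(data.frame(x = rnorm(200)), cls)
    sc$selected[1]
  })
  expect_lt(mean(hits), 0.25)   # nominal 10% plus binomial noise
})

test_that("two-class multinomial agrees with binary logistic regression", {
  set.seed(161)
  n <- 600
  x1 <- rnorm(n); x2 <- rnorm(n)
  eta <- -0.3 + 0.8 * x1 - 0.5 * x2
  y <- rbinom(n, 1, plogis(eta)) + 1
  mf <- multinomial_fit(data.frame(x1 = x1, x2 = x2), y, reference = 1,
                        prune = FALSE)
  glm_fit <- glm(I(y == 2) ~ x1 + x2, family = binomial)
  est <- mf$table$estimate[match(c("x1", "x2"), mf$table$term)]
  expect_equal(est, unname(coef(glm_fit)[c("x1", "x2")]), tolerance = 1e-6)
})

test_that("per-SD odds ratios are invariant to covariate rescaling", {
  set.seed(171)
  n <- 800
  x <- rnorm(n, 0, 2)
  z <- rnorm(n)
  cls <- 1 + rbinom(n, 2, plogis(0.4 * x) / 2)
  d1 <- data.frame(x = x, z = z)
  d2 <- data.frame(x = 10 * x, z = z)
  m1 <- multinomial_fit(d1, cls, reference = 1, scale_per_sd = "x",
                        prune = FALSE)
  m2 <- multinomial_fit(d2, cls, reference = 1, scale_per_sd = "x",
                        prune = FALSE)
  expect_equal(m1$table$OR[m1$table$term == "x"],
               m2$table$OR[m2$table$term == "x"], tolerance = 1e-6)
})

test_that("null covariates yield CIs covering 1; backward pruning drops them", {
  set.seed(181)
  n <- 4000
  cls <- sample(1:3, n, replace = TRUE, prob = c(0.2, 0.5, 0.3))
  cov <- data.frame(active = rnorm(n) - 0.6 * (cls == 3),
                    idle = rnorm(n))
  m <- multinomial_fit(cov, cls, reference = 1, prune = FALSE)
  idle_rows <- m$table[m$table$term == "idle", ]
  expect_true(all(idle_rows$ci_lo < 1 & idle_rows$ci_hi > 1))
  mp <- multinomial_fit(cov, cls, reference = 1, prune = TRUE)
  expect_true("idle" %in% mp$dropped)
  expect_false("active" %in% mp$dropped)
})

test_that("known multinomial-logit coefficients are recovered", {
  set.seed(191)
  n <- 8000
  x <- rnorm(n)          # per-SD covariate (unit SD)
  w <- rnorm(n)
  b2 <- log(0.33); b3 <- log(0.12)
  e2 <- exp(0.8 + b2 * x + 0.2 * w)
  e3 <- exp(0.5 + b3 * x - 0.1 * w)
  pr <- cbind(1, e2, e3) / (1 + e2 + e3)
  cls <- apply(pr, 1, function(p) sample.int(3, 1, prob = p))
  m <- multinomial_fit(data.frame(x = x, w = w), cls, reference = 1,
                       scale_per_sd = "x", prune = FALSE)
  r3 <- m$table[m$table$term == "x" & m$table$class == "3", ]
  expect_lt(abs(r3$estimate - b3), 3 * r3$se)
  r2 <- m$table[m$table$term == "x" & m$table$class == "2", ]
  expect_lt(abs(r2$estimate - b2), 3 * r2$se)
})

test_that("separation triggers a warning, singular designs an error", {
  set.seed(201)
  n <- 80
  x <- c(rnorm(n / 2, -8), rnorm(n / 2, 8))
  cls <- rep(1:2, each = n / 2)
  expect_warning(multinomial_fit(data.frame(x = x), cls, reference = 1,
                                 prune = FALSE), "separation")
})

test_that("missingness correlates match hand-computed Spearman rho", {
  Y <- rbind(c(1, 1, NA, NA), c(1, NA, NA, NA), c(1, 1, 1, NA),
             c(1, 1, 1, 1), c(1, 1, 1, 1))
  p <- visit_panel(Y, times = 0:3)
  miss <- c(2, 3, 1, 0, 0)
  x <- c(10, 8, 13, 14, 12)
  # hand computation on ranks
  rho_hand <- cor(rank(miss), rank(x)) # small-sample definition w/ ties
  mc <- missingness_correlates(p, data.frame(edu = x))
  expect_equal(mc$rho, rho_hand, tolerance = 1e-10)

  # education-driven dropout is detected with the right sign
  cfg <- generator_config(n_participants = 3000, seed = 211,
    missingness_model = list(intercept = -1.2, education = -0.8,
                             enroll_date = 0, monotone = TRUE,
                             first_hazard_visit = 1L))
  co <- generate_cohort(cfg)
  pp <- build_panel(co)
  mc2 <- missingness_correlates(pp, data.frame(
    education = co$baseline_table$education,
    wrat4 = co$baseline_table$wrat4))
  edu <- mc2[mc2$variable == "education", ]
  expect_lt(edu$rho, -0.1)
  expect_true(edu$flagged)

  # MCAR: correlations are null to sampling error
  cfg0 <- generator_config(n_participants = 2000, seed = 221,
    missingness_model = list(intercept = -1.5, education = 0,
                             enroll_date = 0, monotone = TRUE,
                             first_hazard_visit = 1L))
  co0 <- generate_cohort(cfg0)
  mc0 <- missingness_correlates(build_panel(co0), data.frame(
    education = co0$baseline_table$education,
    enroll_date = co0$baseline_table$enroll_date))
  expect_lt(max(abs(mc0$rho)), 0.08)

  # degenerate: no missingness at all
  full <- visit_panel(matrix(1:20, 5, 4), times = 0:3)
  mc3 <- missingness_correlates(full, data.frame(x = rnorm(5)))
  expect_true(all(is.na(mc3$rho)))
})

test_that("three-step separation: covariates never touch the posterior", {
  sim <- simulate_quadratic_panel(150, cbind(c(50, 0, 0), c(30, 0, 0)),
                                  c(0.5, 0.5), J = 5, seed = 231)
  fit <- gmm_fit(sim$panel, growth_spec("quadratic", times = 0:4), 2,
                 n_starts = 2, seed = 10)
  post_before <- fit$posterior
  cls <- modal_assign(fit$posterior)
  cov <- data.frame(x = rnorm(150) + cls)
  invisible(multinomial_fit(cov, cls, reference = 1, prune = FALSE))
  expect_identical(fit$posterior, post_before)
})
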