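test_that("noiseless norm samples are recovered exactly", {
  cfg <- generator_config(seed = 2)
  set.seed(2)
  ns <- generate_norm_sample(cfg, n = 2000, noise_sd = 0)
  nm <- fit_norms(ns)
  gen <- cfg$norm_model$coef
  expect_equal(unname(nm$coefficients["age"]), unname(gen["age"]),
               tolerance = 1e-8)
  expect_equal(unname(nm$coefficients["education"]),
               unname(gen["education"]), tolerance = 1e-8)
  expect_equal(unname(nm$coefficients["sexM"]), unname(gen["sexM"]),
               tolerance = 1e-8)
  # race offsets relative to the reference level (black, coded 0)
  expect_equal(unname(nm$coefficients["racewhite"]),
               unname(gen["racewhite"]), tolerance = 1e-8)
  expect_equal(unname(nm$coefficients["(Intercept)"]),
               unname(gen["intercept"]), tolerance = 1e-8)
  expect_lt(nm$residual_sd, 1e-8)
})

test_that("noisy norm fits recover coefficients and residual SD within 3 SE", {
  cfg <- generator_config(seed = 3)
  set.seed(3)
  n <- 10000
  ns <- generate_norm_sample(cfg, n = n, noise_sd = 5)
  nm <- fit_norms(ns)
  lmfit <- lm(raw ~ age + education + sex + race, data = ns)
  ses <- sqrt(diag(vcov(lmfit)))
  gen <- cfg$norm_model$coef
  expect_lt(abs(nm$coefficients["age"] - gen["age"]), 3 * ses["age"])
  expect_lt(abs(nm$coefficients["education"] - gen["education"]),
            3 * ses["education"])
  # residual SD: sampling SE approx sd / sqrt(2n) by the chi-square law
  expect_lt(abs(nm$residual_sd - 5), 3 * 5 / sqrt(2 * n))
})

test_that("missing strata and degenerate designs raise errors", {
  cfg <- generator_config(seed = 4)
  set.seed(4)
  ns <- generate_norm_sample(cfg, n = 1000)
  sub <- ns[ns$race != "other", ]
  expect_error(fit_norms(sub, required_races = c("black", "white",
                                                 "hispanic", "other")),
               "other")
  ns2 <- ns
  ns2$education <- 12          # constant column -> rank-deficient
  expect_error(fit_norms(ns2), "collinear|rank")
  expect_error(generate_norm_sample(cfg, n = 100), ">= 200")
  expect_error(generate_norm_sample(cfg, n = 500, age_range = c(60, 50)),
               "age_range")
})

test_that("practice correction is additive, anchored at visit 0, and capped", {
  pm <- practice_model(c(0, 2, 2, 2.5))
  expect_equal(correct_practice(50, 0, pm), 50)
  expect_equal(correct_practice(50, 1, pm), 48)
  expect_equal(correct_practice(50, 9, pm), 47.5)  # beyond range: last gain
  expect_error(correct_practice(50, -1, pm), ">= 0")
  expect_error(practice_model(c(1, 2)), "visit 0")

  cfg <- generator_config(seed = 5)
  set.seed(5)
  retest <- generate_retest_sample(cfg, n = 400, noise_sd = 0)
  est <- estimate_practice(retest)
  expect_equal(est$expected_gain_by_visit, cfg$practice_gains,
               tolerance = 1e-10)
})

test_that("injected practice gains are removed exactly by paired correction", {
  # same seed with and without a +2 gain bump: the corrected panels must
  # coincide because gains enter raw scores deterministically
  gains <- c(0, 2, rep(2, 8))
  cfg_bump <- generator_config(n_participants = 80, seed = 11,
                               practice_gains = gains)
  cfg_flat <- generator_config(n_participants = 80, seed = 11,
                               practice_gains = rep(0, 10))
  co_bump <- generate_cohort(cfg_bump)
  co_flat <- generate_cohort(cfg_flat)
  pm <- practice_model(gains)
  raw_b <- correct_practice(co_bump$visit_table$raw_motor,
                            co_bump$visit_table$visit, pm)
  expect_equal(raw_b, co_flat$visit_table$raw_motor, tolerance = 1e-9)
})

test_that("peak-age T-scores implement the age-25 substitution transform", {
  nm <- toy_norm_model(intercept = 30, age = 0, education = 0.5,
                       residual_sd = 8)
  demog <- list(age = 55, education = 12, sex = "F", race = "black")
  # prediction is 30 + 0.5 * 12 = 36; raw 44 is one residual SD above
  expect_equal(peak_age_tscore(44, demog, nm), 60)
  expect_equal(peak_age_tscore(36, demog, nm), 50)   # at prediction
  expect_equal(peak_age_tscore(28, demog, nm), 40)   # 1 SD below
  expect_error(peak_age_tscore(44, list(age = 55, education = 12,
                                        sex = "F"), nm), "race")
})

test_that("chronological and peak-age scores relate through the age effect", {
  nm <- toy_norm_model(intercept = 50, age = -0.3, education = 0.4,
                       residual_sd = 6)
  demog25 <- list(age = 25, education = 14, sex = "M", race = "black")
  expect_equal(chronological_tscore(48, demog25, nm),
               peak_age_tscore(48, demog25, nm))
  demog60 <- list(age = 60, education = 14, sex = "M", race = "black")
  # negative age slope and age > 25: chronological norms are easier
  expect_gte(chronological_tscore(48, demog60, nm),
             peak_age_tscore(48, demog60, nm))
  pred60 <- predict_norm(nm, demog60)
  expect_equal(chronological_tscore(pred60, demog60, nm), 50)
})

test_that("T-scores shift by 10 per residual SD of raw score", {
  nm <- toy_norm_model(residual_sd = 7)
  demog <- list(age = 40, education = 12, sex = "M", race = "black")
  base <- peak_age_tscore(42, demog, nm)
  expect_equal(peak_age_tscore(42 + 7, demog, nm), base + 10)
  expect_equal(chronological_tscore(42 - 2 * 7, demog, nm),
               chronological_tscore(42, demog, nm) - 20)
})

test_that("global score averages available domains", {
  expect_equal(global_tscore(c(40, 50, 60)), 50)
  expect_equal(global_tscore(47), 47)
  v <- c(41.2, 55.3, 39.9, 48, 52.5, 44.4, 61)
  expect_equal(global_tscore(v), sum(v) / 7)
  expect_equal(global_tscore(c(45, NA, 55)), 50)
  expect_warning(res <- global_tscore(c(NA_real_, NA_real_)), "missing")
  expect_true(is.na(res))
  m <- rbind(c(40, 50), c(NA, 44), c(NA, NA))
  expect_warning(g <- global_tscore(m), "no domain scores")
  expect_equal(g[1:2], c(45, 44))
  expect_true(is.na(g[3]))
})

test_that("scores generated at T = 50 for 25-year-olds renorm to mean 50", {
  cfg <- generator_config(seed = 8)
  set.seed(8)
  ns <- generate_norm_sample(cfg, n = 8000)
  nm <- fit_norms(ns)
  # young adults whose raw scores sit exactly at their age-25 expectation
  set.seed(9)
  probe <- generate_norm_sample(cfg, n = 2000, age_range = c(25, 25),
                                noise_sd = 0)
  ts <- peak_age_tscore(probe$raw, probe[c("age", "education", "sex", "race")],
                        nm)
  expect_lt(abs(mean(ts) - 50), 3 * 10 / sqrt(2000) + 0.2)
})

test_that("norm and practice models survive a JSON round trip", {
  nm <- toy_norm_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_norm_model(nm, path)
  nm2 <- read_norm_model(path)
  expect_equal(nm2$coefficients, as.list(nm$coefficients) |> unlist())
  expect_equal(nm2$residual_sd, nm$residual_sd)
  pm <- practice_model(c(0, 1.5, 2))
  write_norm_model(pm, path)
  expect_equal(read_norm_model(path)$expected_gain_by_visit, c(0, 1.5, 2))
})
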