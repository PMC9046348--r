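#' Generate a synthetic longitudinal cohort
#'
#' Draws a full synthetic cohort under the trajectory model described in
#' [generator_config()]: baseline covariates, latent class membership from a
#' covariate-driven multinomial logit (intercepts calibrated so marginal
#' class shares equal the configured proportions), quadratic growth
#' trajectories of global peak-age T-scores with shared random effects,
#' per-domain raw test scores consistent with the generating normative
#' regression and practice-gain schedule, physiologic-reserve item
#' measurements, and missing-at-random dropout driven by education and
#' enrollment date (visit 0 always observed; dropout monotone by default).
#'
#' Covariates are simulated independently of the trajectory residuals given
#' class, so the three-step covariate analysis has a known truth.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed; defaults to `cfg$seed`. The same config and
#'   seed reproduce the cohort exactly.
#' @return An object of class `synthetic_cohort`: a list with `visit_table`
#'   (long format: id, visit, true_class, observed, age_at_visit, global_T,
#'   one `raw_<domain>` column per domain), `baseline_table` (demographics,
#'   clinical covariates and the 39 physiologic-reserve item measurements),
#'   `truth` (latent class, growth-factor realizations, latent reserve,
#'   dropout visit) and the `config`.
#' @export
generate_cohort <- function(cfg, seed = cfg$seed) {
  validate_generator_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_participants
  J <- cfg$n_visits
  K <- length(cfg$class_proportions)
  cm <- cfg$covariate_model

  ## ---- baseline covariates -------------------------------------------
  age <- stats::rnorm(n, cm$age["mean"], cm$age["sd"])
  education <- pmin(20, pmax(6, round(stats::rnorm(n, cm$education["mean"],
                                                   cm$education["sd"]))))
  wrat4 <- stats::rnorm(n, cm$wrat4["mean"], cm$wrat4["sd"])
  paofi <- stats::rnbinom(n, size = cm$paofi["size"], mu = cm$paofi["mu"])
  bdi <- stats::rnbinom(n, size = cm$bdi["size"], mu = cm$bdi["mu"])
  reserve_latent <- pmin(0.98, pmax(0.02,
    stats::rnorm(n, cm$reserve["mean"], cm$reserve["sd"])))
  sex <- ifelse(stats::runif(n) < cm$p_male, "M", "F")
  race <- sample(names(cm$race_probs), n, replace = TRUE, prob = cm$race_probs)
  lifetime_mdd <- stats::rbinom(n, 1, cm$p_lifetime_mdd)
  current_mdd <- ifelse(lifetime_mdd == 1,
                        stats::rbinom(n, 1, cm$p_current_mdd / cm$p_lifetime_mdd),
                        0L)
  substance_use <- stats::rbinom(n, 1, cm$p_substance)
  aids <- stats::rbinom(n, 1, cm$p_aids)
  disease_duration <- pmax(0.5, stats::rnorm(n, cm$disease_duration["mean"],
                                             cm$disease_duration["sd"]))
  nadir_cd4 <- round(stats::rlnorm(n, cm$nadir_cd4["meanlog"],
                                   cm$nadir_cd4["sdlog"]))
  current_cd4 <- round(stats::rlnorm(n, cm$current_cd4["meanlog"],
                                     cm$current_cd4["sdlog"]))
  art_status <- sample(names(cm$art_probs), n, replace = TRUE,
                       prob = cm$art_probs)
  suppressed <- stats::rbinom(n, 1, cm$p_suppressed)
  hiv_rna <- ifelse(suppressed == 1, stats::runif(n, 0, 40),
                    stats::rlnorm(n, log(5000), 1.5) + 40)
  enroll_date <- stats::runif(n, cm$enroll_years[1], cm$enroll_years[2])

  ## ---- latent class via calibrated multinomial logit -----------------
  X <- cbind(age = age - cm$age["mean"],
             paofi = paofi,
             reserve_z = (reserve_latent - cm$reserve["mean"]) / cm$reserve["sd"],
             wrat4_z = (wrat4 - cm$wrat4["mean"]) / cm$wrat4["sd"])
  if (K > 1) {
    eta <- X %*% cm$class_logit[, seq_len(K - 1), drop = FALSE]  # n x (K-1)
    alpha <- calibrate_logit_intercepts(eta, cfg$class_proportions)
    pr <- class_probabilities(eta, alpha)
    true_class <- apply(pr, 1, function(p) sample.int(K, 1L, prob = p))
  } else {
    alpha <- numeric(0)
    true_class <- rep(1L, n)
  }

  ## ---- growth trajectories -------------------------------------------
  tt <- seq_len(J) - 1
  Psi <- random_effect_cov(cfg)
  b <- draw_bivariate_normal(n, Psi)              # n x 2 (intercept, slope)
  am <- cfg$class_growth_means[true_class, , drop = FALSE]
  mu <- (am[, 1] + b[, 1]) %o% rep(1, J) +
        (am[, 2] + b[, 2]) %o% tt +
        am[, 3] %o% tt^2
  eps <- matrix(stats::rnorm(n * J, 0, cfg$residual_sd), n, J)
  global_T <- mu + eps                            # n x J

  ## ---- per-domain raw scores ----------------------------------------
  nd <- length(cfg$domains)
  nm <- cfg$norm_model
  pred25 <- norm_prediction(nm$coef, age = rep(25, n), education = education,
                            sex = sex, race = race)
  raw <- array(NA_real_, c(n, J, nd))
  for (j in seq_len(J)) {
    delta <- matrix(stats::rnorm(n * nd, 0, cfg$domain_scatter_sd), n, nd)
    delta <- delta - rowMeans(delta)  # centre so domain mean == global score
    Tdom <- global_T[, j] + delta
    raw[, j, ] <- pred25 + (Tdom - 50) / 10 * nm$residual_sd +
      cfg$practice_gains[j]
  }

  ## ---- missingness ----------------------------------------------------
  mm <- cfg$missingness_model
  educ_z <- (education - cm$education["mean"]) / cm$education["sd"]
  date_z <- (enroll_date - mean(cm$enroll_years)) /
    (diff(cm$enroll_years) / 4)
  hazard <- stats::plogis(mm$intercept + mm$education * educ_z +
                            mm$enroll_date * date_z)
  observed <- matrix(TRUE, n, J)
  first <- if (is.null(mm$first_hazard_visit)) 1L else mm$first_hazard_visit
  dropout_visit <- rep(NA_integer_, n)
  for (j in seq(first + 1L, J)) {                 # visit index j-1 >= first
    miss <- stats::runif(n) < hazard
    if (isTRUE(mm$monotone)) {
      newdrop <- miss & observed[, j]
      observed[newdrop, j:J] <- FALSE
      dropout_visit[newdrop & is.na(dropout_visit)] <- j - 1L
    } else {
      observed[miss, j] <- FALSE
    }
  }
  observed[, 1] <- TRUE                           # visit 0 always observed

  ## ---- physiologic reserve item measurements -------------------------
  items_df <- draw_reserve_items(n, reserve_latent, sex, cfg$deficit_probs,
                                 current_cd4, nadir_cd4, hiv_rna,
                                 disease_duration)

  ## ---- assemble -------------------------------------------------------
  id <- sprintf("P%04d", seq_len(n))
  visit_table <- data.frame(
    id = rep(id, each = J),
    visit = rep(tt, times = n),
    true_class = rep(true_class, each = J),
    observed = as.vector(t(observed)),
    age_at_visit = rep(age, each = J) + rep(tt, times = n) / 2,
    global_T = as.vector(t(global_T)),
    stringsAsFactors = FALSE)
  for (d in seq_len(nd))
    visit_table[[paste0("raw_", cfg$domains[d])]] <- as.vector(t(raw[, , d]))

  baseline_table <- data.frame(
    id = id, age = age, sex = sex, race = race, education = education,
    wrat4 = wrat4, paofi = paofi, bdi = bdi,
    lifetime_mdd = lifetime_mdd, current_mdd = current_mdd,
    substance_use = substance_use, aids = aids,
    art_status = art_status, enroll_date = enroll_date,
    true_class = true_class, stringsAsFactors = FALSE)
  baseline_table <- cbind(baseline_table, items_df)

  structure(list(visit_table = visit_table,
                 baseline_table = baseline_table,
                 truth = list(class = true_class, growth_effects = b,
                              reserve = reserve_latent,
                              dropout_visit = dropout_visit,
                              logit_intercepts = alpha),
                 config = cfg, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  K <- length(x$config$class_proportions)
  cat(sprintf("Synthetic cohort: %d participants, %d visits, %d classes\n",
              x$config$n_participants, x$config$n_visits, K))
  cat("Realized class counts:",
      paste(tabulate(x$truth$class, K), collapse = " / "), "\n")
  cat(sprintf("Observed visits: %d of %d\n", sum(x$visit_table$observed),
              nrow(x$visit_table)))
  invisible(x)
}

random_effect_cov <- function(cfg) {
  si <- cfg$random_intercept_sd
  ss <- cfg$random_slope_sd
  r <- cfg$random_effect_corr
  matrix(c(si^2, r * si * ss, r * si * ss, ss^2), 2, 2)
}

draw_bivariate_normal <- function(n, Sigma) {
  L <- chol_psd(Sigma)
  matrix(stats::rnorm(2 * n), n, 2) %*% t(L)
}

# lower-triangular factor tolerant of zero-variance components
chol_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(v), nrow = length(v)) %*% t(e$vectors)
}

norm_prediction <- function(coef, age, education, sex, race) {
  coef["intercept"] + coef["age"] * age + coef["education"] * education +
    coef["sexM"] * (sex == "M") +
    unname(coef[paste0("race", race)])
}

class_probabilities <- function(eta, alpha) {
  full <- cbind(0, sweep(eta, 2, alpha, "+"))
  full <- full - apply(full, 1, max)
  w <- exp(full)
  w / rowSums(w)
}

# Fixed-point calibration: shift logit intercepts until the average class
# probabilities hit the target proportions.
calibrate_logit_intercepts <- function(eta, target, max_iter = 200,
                                       tol = 1e-10) {
  K <- length(target)
  alpha <- log(target[-1] / target[1])
  for (it in seq_len(max_iter)) {
    pbar <- colMeans(class_probabilities(eta, alpha))
    if (max(abs(pbar - target)) < tol) break
    alpha <- alpha + (log(target[-1] / target[1]) - log(pbar[-1] / pbar[1]))
  }
  alpha
}

draw_reserve_items <- function(n, reserve_latent, sex, deficit_probs,
                               current_cd4, nadir_cd4, hiv_rna,
                               disease_duration) {
  crit <- reserve_criteria()
  items <- names(deficit_probs)
  out <- data.frame(row.names = seq_len(n))
  shift <- (1 - reserve_latent) - mean(deficit_probs)
  for (it in items) {
    p <- pmin(0.98, pmax(0.02, deficit_probs[[it]] + shift))
    deficit <- stats::rbinom(n, 1, p) == 1
    if (it == "hypertension") {
      flag <- deficit & stats::runif(n) < 0.7
      bp_def <- deficit & !flag
      out$hypertension <- as.integer(flag)
      out$systolic <- ifelse(bp_def & stats::runif(n) < 0.5,
                             stats::runif(n, 131, 180),
                             stats::runif(n, 100, 130))
      out$diastolic <- ifelse(bp_def & out$systolic <= 130,
                              stats::runif(n, 86, 110),
                              stats::runif(n, 60, 85))
      next
    }
    rules <- crit[crit$item == it, , drop = FALSE]
    if (isTRUE(rules$is_flag[1])) {
      out[[it]] <- as.integer(deficit)
      next
    }
    val <- numeric(n)
    for (s in unique(ifelse(is.na(rules$sex), "", rules$sex))) {
      rule <- if (s == "") rules[1, ] else rules[rules$sex == s, ]
      idx <- if (s == "") seq_len(n) else which(sex == s)
      if (length(idx) == 0) next
      val[idx] <- sample_measurement(rule, deficit[idx])
    }
    out[[it]] <- val
  }
  out$current_cd4 <- current_cd4
  out$nadir_cd4 <- nadir_cd4
  out$hiv_rna <- hiv_rna
  out$disease_duration <- disease_duration
  out
}

# Draw a measurement uniformly inside the normal band or the deficit region
# implied by one criteria-table rule.
sample_measurement <- function(rule, deficit) {
  m <- length(deficit)
  lo <- rule$low; hi <- rule$high
  smin <- rule$sample_min; smax <- rule$sample_max
  norm_lo <- if (is.na(lo)) smin else lo
  norm_hi <- if (is.na(hi)) smax else hi
  val <- stats::runif(m, norm_lo, norm_hi)
  idx <- which(deficit)
  if (length(idx) > 0) {
    below_ok <- !is.na(lo) && lo > smin
    above_ok <- !is.na(hi) && hi < smax
    side_below <- if (below_ok && above_ok) stats::runif(length(idx)) < 0.5
                  else rep(below_ok, length(idx))
    val[idx] <- ifelse(side_below,
                       stats::runif(length(idx), smin, lo - 1e-9),
                       stats::runif(length(idx), hi + 1e-9, smax))
    if (isTRUE(rule$high_inclusive) && above_ok)
      val[idx][!side_below] <- stats::runif(sum(!side_below), hi, smax)
  }
  val
}

#' Generate a synthetic normative sample
#'
#' Draws demographics (age uniform over `age_range`, education, sex,
#' race/ethnicity from the configured covariate model) and raw scores from
#' the generator's normative regression with residual noise `noise_sd`,
#' enabling exact- and noisy-recovery tests of [fit_norms()].
#'
#' @param cfg A [generator_config()].
#' @param n Sample size (>= 200).
#' @param age_range Length-2 numeric range of ages.
#' @param noise_sd Residual SD; defaults to the config's normative SD.
#' @return Data frame with `age`, `education`, `sex`, `race`, `raw`.
#' @export
generate_norm_sample <- function(cfg, n, age_range = c(20, 70),
                                 noise_sd = cfg$norm_model$residual_sd) {
  validate_generator_config(cfg)
  if (n < 200) stop("normative sample size must be >= 200", call. = FALSE)
  if (length(age_range) != 2 || age_range[2] < age_range[1])
    stop("age_range must be a non-empty increasing interval", call. = FALSE)
  cm <- cfg$covariate_model
  age <- stats::runif(n, age_range[1], age_range[2])
  education <- pmin(20, pmax(6, round(stats::rnorm(n, cm$education["mean"],
                                                   cm$education["sd"]))))
  sex <- ifelse(stats::runif(n) < cm$p_male, "M", "F")
  race <- sample(names(cm$race_probs), n, replace = TRUE, prob = cm$race_probs)
  raw <- norm_prediction(cfg$norm_model$coef, age, education, sex, race) +
    stats::rnorm(n, 0, noise_sd)
  data.frame(age = age, education = education, sex = sex, race = race,
             raw = raw, stringsAsFactors = FALSE)
}

#' Generate a synthetic retest sample
#'
#' Repeated administrations of a test to a demographically stable sample, so
#' practice gains can be estimated for [practice_model()]. Each subject's
#' expected score is their baseline expectation plus the configured practice
#' gain at each visit.
#'
#' @param cfg A [generator_config()].
#' @param n Number of retest subjects.
#' @param noise_sd Occasion noise SD.
#' @return Long data frame with `id`, `visit`, `raw`.
#' @export
generate_retest_sample <- function(cfg, n = 500, noise_sd = 2) {
  validate_generator_config(cfg)
  J <- cfg$n_visits
  base <- stats::rnorm(n, 50, 8)
  data.frame(
    id = rep(seq_len(n), each = J),
    visit = rep(seq_len(J) - 1, times = n),
    raw = rep(base, each = J) + rep(cfg$practice_gains, times = n) +
      stats::rnorm(n * J, 0, noise_sd))
}

#' Write a synthetic cohort to disk
#'
#' Writes `visit_table.csv`, `baseline_table.csv`, `truth.json` and
#' `config.yaml` under `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$visit_table, file.path(dir, "visit_table.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$baseline_table, file.path(dir, "baseline_table.csv"),
                   row.names = FALSE)
  truth <- cohort$truth
  truth$growth_effects <- apply(truth$growth_effects, 1, as.numeric,
                                simplify = FALSE)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  write_generator_config(cohort$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
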