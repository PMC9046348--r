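#' Synthetic cohort generator configuration
#'
#' Builds the configuration object consumed by [generate_cohort()]. Defaults
#' describe a cohort of 184 older adults ageing with HIV observed at up to
#' ten 6-month visits, with three latent trajectory classes of global
#' peak-age T-scores following quadratic mean growth
#' \eqn{y_{it} = (\alpha_{0k} + b_{0i}) + (\alpha_{1k} + b_{1i}) t +
#' \alpha_{2k} t^2 + \epsilon_{it}} on the visit-index time scale
#' \eqn{t = 0, \ldots, 9}. Random effects act on the intercept and linear
#' slope only and are shared across classes, as is the residual variance.
#'
#' Default class proportions are 31/184, 100/184 and 53/184 and the default
#' class growth means are (49.62, 0.04, 0.04), (41.91, -0.45, 0.07) and
#' (34.22, -1.04, 0.12) for the high, intermediate and low classes. The
#' within-class variance components are not identified by those published
#' summaries; the defaults (random intercept SD 4, random slope SD 0.3,
#' residual SD 4) were chosen once to give a realistic visual spread of
#' individual trajectories and are stated as package defaults.
#'
#' Class membership is assigned from a multinomial logit on baseline
#' covariates (age per year, PAOFI symptom count, physiologic reserve per
#' SD, WRAT4 cognitive reserve per SD) whose slopes default to the log odds
#' ratios 1.06/1.07/0.83/0.33 (intermediate class) and 1.20/1.14/0.48/0.12
#' (low class) against the high class; intercepts are calibrated at
#' generation time so marginal class shares match `class_proportions`.
#' Dropout is missing-at-random: a per-visit hazard on the logit scale
#' driven by education (negative) and enrollment date (positive), monotone
#' by default.
#'
#' @param n_participants Number of participants.
#' @param n_visits Number of visits (>= 3), 6-month spacing, coded 0..J-1.
#' @param class_proportions Mixing proportions, summing to 1.
#' @param class_growth_means K x 3 matrix of (intercept, linear, quadratic)
#'   mean growth factors in T-score units per visit unit.
#' @param random_intercept_sd,random_slope_sd,residual_sd Standard
#'   deviations of the shared random intercept, random linear slope and
#'   occasion residual (T-score units).
#' @param random_effect_corr Correlation between random intercept and slope.
#' @param covariate_model List of covariate distributions and the per-class
#'   multinomial-logit coefficient matrix `class_logit` (rows: age, paofi,
#'   reserve_z, wrat4_z; columns: classes 2..K).
#' @param missingness_model List with logit `intercept` and coefficients
#'   `education`, `enroll_date` (applied to z-scored covariates) for the
#'   per-visit dropout hazard, and `monotone` flag.
#' @param deficit_probs Baseline deficit probabilities for the 35 non-HIV
#'   physiologic reserve items (the four HIV items are generated from their
#'   own clinical distributions).
#' @param norm_model Generating normative regression for raw domain scores:
#'   coefficient vector (`intercept`, `age`, `education`, `sexM`, race
#'   offsets) and `residual_sd` in raw-score units.
#' @param practice_gains Additive raw-score practice gains by visit
#'   (first element must be 0).
#' @param domain_scatter_sd SD of between-domain scatter around the global
#'   trajectory (T-score units); scatter is centred within each visit so the
#'   across-domain mean reproduces the global score exactly.
#' @param domains Names of the neuropsychological domains.
#' @param seed Default seed used by [generate_cohort()] when none is given.
#' @return A validated object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 184,
                             n_visits = 10,
                             class_proportions = c(31, 100, 53) / 184,
                             class_growth_means = rbind(
                               c(49.62,  0.04, 0.04),
                               c(41.91, -0.45, 0.07),
                               c(34.22, -1.04, 0.12)),
                             random_intercept_sd = 4,
                             random_slope_sd = 0.3,
                             residual_sd = 4,
                             random_effect_corr = 0,
                             covariate_model = default_covariate_model(),
                             missingness_model = default_missingness_model(),
                             deficit_probs = default_deficit_probs(),
                             norm_model = default_norm_model(),
                             practice_gains = c(0, 1.5, rep(2, max(0, n_visits - 2))),
                             domain_scatter_sd = 9,
                             domains = c("verbal_fluency", "executive",
                                         "speed", "learning", "recall",
                                         "working_memory", "motor"),
                             seed = NULL) {
  cfg <- structure(as.list(environment()), class = "generator_config")
  validate_generator_config(cfg)
}

#' @rdname generator_config
#' @export
default_covariate_model <- function() {
  list(
    age = c(mean = 52.9, sd = 3.9),
    education = c(mean = 13.1, sd = 2.6),
    wrat4 = c(mean = 93.5, sd = 15.4),
    paofi = c(size = 0.8, mu = 4),
    bdi = c(size = 1.2, mu = 11),
    reserve = c(mean = 0.70, sd = 0.10),
    p_male = 0.82,
    race_probs = c(black = 0.46, white = 0.43, hispanic = 0.09, other = 0.02),
    p_lifetime_mdd = 0.49, p_current_mdd = 0.12, p_substance = 0.73,
    p_aids = 0.72,
    disease_duration = c(mean = 13.3, sd = 6.2),
    nadir_cd4 = c(meanlog = log(108.5), sdlog = 1.3),
    current_cd4 = c(meanlog = log(475), sdlog = 0.5),
    art_probs = c(current = 0.82, past = 0.11, naive = 0.07),
    p_suppressed = 0.57,
    enroll_years = c(2003, 2017),
    # log odds ratios vs the highest (reference) class, columns = classes 2..K
    class_logit = cbind(class2 = log(c(age = 1.06, paofi = 1.07,
                                       reserve_z = 0.83, wrat4_z = 0.33)),
                        class3 = log(c(age = 1.20, paofi = 1.14,
                                       reserve_z = 0.48, wrat4_z = 0.12)))
  )
}

#' @rdname generator_config
#' @export
default_missingness_model <- function() {
  list(intercept = -2.25, education = -0.25, enroll_date = 0.45,
       monotone = TRUE, first_hazard_visit = 1L)
}

#' @rdname generator_config
#' @export
default_deficit_probs <- function() {
  items <- setdiff(reserve_items(),
                   c("current_cd4", "nadir_cd4", "hiv_rna", "disease_duration"))
  stats::setNames(seq(0.08, 0.46, length.out = length(items)), items)
}

#' @rdname generator_config
#' @export
default_norm_model <- function() {
  list(coef = c(intercept = 38, age = -0.125, education = 0.9, sexM = 0.5,
                raceblack = 0, racewhite = 1.2, racehispanic = 0.6,
                raceother = 0.3),
       residual_sd = 7)
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  err <- function(...) stop("generator configuration error: ", ...,
                            call. = FALSE)
  if (cfg$n_visits < 3) err("n_visits must be >= 3")
  if (cfg$n_participants < 1) err("n_participants must be positive")
  if (abs(sum(cfg$class_proportions) - 1) > 1e-12)
    err("class_proportions must sum to 1 (within 1e-12)")
  if (any(cfg$class_proportions < 0)) err("class_proportions must be >= 0")
  K <- length(cfg$class_proportions)
  if (!is.matrix(cfg$class_growth_means) ||
      nrow(cfg$class_growth_means) != K || ncol(cfg$class_growth_means) != 3)
    err("class_growth_means must be a ", K, " x 3 matrix ",
        "(intercept, linear, quadratic per class)")
  sds <- c(cfg$random_intercept_sd, cfg$random_slope_sd, cfg$residual_sd,
           cfg$domain_scatter_sd)
  if (any(sds < 0)) err("standard deviations must be >= 0")
  if (abs(cfg$random_effect_corr) > 1) err("random_effect_corr must be in [-1, 1]")
  if (length(cfg$practice_gains) != cfg$n_visits)
    err("practice_gains must have length n_visits")
  if (cfg$practice_gains[1] != 0) err("practice gain at visit 0 must be 0")
  if (K > 1) {
    cl <- cfg$covariate_model$class_logit
    if (!is.matrix(cl) || ncol(cl) != K - 1 || nrow(cl) != 4)
      err("covariate_model$class_logit must be a 4 x (K-1) matrix")
  }
  cfg
}

#' Write a generator configuration to YAML
#' @param cfg A `generator_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(cfg, path) {
  lst <- unclass(cfg)
  lst$class_growth_means <- apply(cfg$class_growth_means, 1, as.numeric,
                                  simplify = FALSE)
  lst$covariate_model$class_logit <-
    apply(cfg$covariate_model$class_logit, 2, as.numeric, simplify = FALSE)
  yaml::write_yaml(lst, path)
  invisible(path)
}
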