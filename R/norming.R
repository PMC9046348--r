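#' Fit a demographic normative regression
#'
#' Least-squares regression of raw test score on age, education, sex and
#' race/ethnicity in a normative sample. The fitted model maps demographics
#' to an expected raw score and stores the residual SD; both are the basis
#' of the T-score transform (mean 50, SD 10). The functional form is a
#' linear main-effects regression.
#'
#' @param norm_sample Data frame with columns `age`, `education`, `sex`,
#'   `race`, `raw`.
#' @param required_races Race/ethnicity levels that must be present; by
#'   default all levels found in the sample are used, but passing the
#'   cohort's levels guards against silent extrapolation to strata the
#'   norms never saw.
#' @return An object of class `norm_model`: `coefficients`, `residual_sd`,
#'   `levels`, `fitted_on`.
#' @export
fit_norms <- function(norm_sample, required_races = NULL) {
  needed <- c("age", "education", "sex", "raw", "race")
  missing_cols <- setdiff(needed, names(norm_sample))
  if (length(missing_cols) > 0)
    stop("normative sample lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!is.null(required_races)) {
    absent <- setdiff(required_races, unique(norm_sample$race))
    if (length(absent) > 0)
      stop("normative sample has no observations for race/ethnicity level(s): ",
           paste(absent, collapse = ", "),
           "; refusing to extrapolate", call. = FALSE)
  }
  norm_sample$sex <- factor(norm_sample$sex)
  norm_sample$race <- factor(norm_sample$race)
  fit <- stats::lm(raw ~ age + education + sex + race, data = norm_sample)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient normative design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res_sd <- sqrt(sum(stats::residuals(fit)^2) / stats::df.residual(fit))
  structure(list(coefficients = stats::coef(fit),
                 residual_sd = res_sd,
                 sex_levels = levels(norm_sample$sex),
                 race_levels = levels(norm_sample$race),
                 fitted_on = sprintf("normative sample of n = %d",
                                     nrow(norm_sample))),
            class = "norm_model")
}

#' @export
print.norm_model <- function(x, ...) {
  cat("Normative regression (", x$fitted_on, ")\n", sep = "")
  print(round(x$coefficients, 4))
  cat(sprintf("Residual SD: %.4f\n", x$residual_sd))
  invisible(x)
}

#' Predict the expected raw score for given demographics
#'
#' @param nm A [fit_norms()] model.
#' @param demographics Data frame (or named list) with `age`, `education`,
#'   `sex`, `race`.
#' @param age_override Optional age substituted for the recorded
#'   chronological age (e.g. 25 for peak-age norming).
#' @return Numeric vector of expected raw scores.
#' @export
predict_norm <- function(nm, demographics, age_override = NULL) {
  d <- as.data.frame(demographics, stringsAsFactors = FALSE)
  for (f in c("age", "education", "sex", "race"))
    if (is.null(d[[f]]) || anyNA(d[[f]]))
      stop("missing demographic field: '", f, "'", call. = FALSE)
  if (!is.null(age_override)) d$age <- age_override
  bad_race <- setdiff(unique(as.character(d$race)), nm$race_levels)
  if (length(bad_race) > 0)
    stop("race/ethnicity level(s) unseen by the norms: ",
         paste(bad_race, collapse = ", "), call. = FALSE)
  cf <- nm$coefficients
  pred <- cf["(Intercept)"] + cf["age"] * d$age + cf["education"] * d$education
  for (lv in nm$sex_levels[-1])
    pred <- pred + ifelse(d$sex == lv, cf[paste0("sex", lv)], 0)
  for (lv in nm$race_levels[-1])
    pred <- pred + ifelse(d$race == lv, cf[paste0("race", lv)], 0)
  unname(pred)
}

#' Practice-effect model
#'
#' Additive expected raw-score gains from repeat test exposure, indexed by
#' visit. The gain at visit 0 (first exposure) is zero by definition.
#'
#' @param expected_gain_by_visit Numeric vector of gains, first element 0.
#' @return An object of class `practice_model`.
#' @export
practice_model <- function(expected_gain_by_visit) {
  g <- as.numeric(expected_gain_by_visit)
  if (length(g) < 1 || g[1] != 0)
    stop("practice gain at visit 0 must be 0", call. = FALSE)
  structure(list(expected_gain_by_visit = g), class = "practice_model")
}

#' Estimate practice gains from a retest sample
#'
#' Mean within-subject raw-score change from the first exposure at each
#' repeat visit, in a sample assumed cognitively stable over the retest
#' window (so any systematic gain is attributable to practice).
#'
#' @param retest Long data frame with `id`, `visit`, `raw`.
#' @return A [practice_model()].
#' @export
estimate_practice <- function(retest) {
  stopifnot(all(c("id", "visit", "raw") %in% names(retest)))
  base <- retest[retest$visit == 0, c("id", "raw")]
  names(base)[2] <- "raw0"
  m <- merge(retest, base, by = "id")
  gain <- tapply(m$raw - m$raw0, m$visit, mean)
  gain <- gain[order(as.numeric(names(gain)))]
  gain[1] <- 0
  practice_model(unname(gain))
}

#' Correct a raw score for practice effects
#'
#' Subtracts the expected gain from repeat exposure at the given visit. A
#' visit index beyond the model's range reuses the last gain (practice
#' effects are assumed to have saturated).
#'
#' @param raw Raw score(s).
#' @param visit_index Visit index (0-based); 0 = first exposure, unchanged.
#' @param pm A [practice_model()].
#' @return Corrected raw score(s).
#' @export
correct_practice <- function(raw, visit_index, pm) {
  stopifnot(inherits(pm, "practice_model"))
  if (any(visit_index < 0)) stop("visit_index must be >= 0", call. = FALSE)
  g <- pm$expected_gain_by_visit
  idx <- pmin(visit_index + 1L, length(g))
  raw - g[idx]
}

#' Peak-age T-score
#'
#' Demographically adjusted T-score in which age 25 -- when most fluid
#' neurocognitive capacities peak -- is substituted for chronological age in
#' the normative regression, so performance is benchmarked against
#' 25-year-olds of the same education, sex and race/ethnicity:
#' \eqn{T = 50 + 10 (raw - \hat y_{25}) / \hat\sigma}. A peak-age T of 40 is
#' one SD below the mean of matched 25-year-olds.
#'
#' @param raw Raw score(s), already practice-corrected.
#' @param demographics Data frame/list with `age`, `education`, `sex`, `race`.
#' @param nm A [fit_norms()] model.
#' @return Numeric T-score(s).
#' @export
peak_age_tscore <- function(raw, demographics, nm) {
  pred <- predict_norm(nm, demographics, age_override = 25)
  50 + 10 * (raw - pred) / nm$residual_sd
}

#' Chronological-age T-score
#'
#' The traditional demographically adjusted T-score using the recorded
#' chronological age in the normative regression.
#'
#' @inheritParams peak_age_tscore
#' @return Numeric T-score(s).
#' @export
chronological_tscore <- function(raw, demographics, nm) {
  pred <- predict_norm(nm, demographics)
  50 + 10 * (raw - pred) / nm$residual_sd
}

#' Global T-score across a test battery
#'
#' Arithmetic mean of the available per-domain T-scores. With every domain
#' missing the result is `NA` with a warning.
#'
#' @param domain_ts Numeric vector (one participant) or matrix
#'   (participants x domains) of domain T-scores.
#' @return Mean T-score(s).
#' @export
global_tscore <- function(domain_ts) {
  if (is.matrix(domain_ts) || is.data.frame(domain_ts)) {
    m <- as.matrix(domain_ts)
    out <- rowMeans(m, na.rm = TRUE)
    allmiss <- rowSums(!is.na(m)) == 0
    if (any(allmiss)) {
      warning(sum(allmiss), " participant(s) with no domain scores; NA returned")
      out[allmiss] <- NA_real_
    }
    return(out)
  }
  if (all(is.na(domain_ts))) {
    warning("all domain scores missing; NA returned")
    return(NA_real_)
  }
  mean(domain_ts, na.rm = TRUE)
}

#' Serialize / restore norm and practice models
#'
#' @param x A `norm_model` or `practice_model`.
#' @param path JSON file path.
#' @return For writers, `path`; for readers, the restored object.
#' @export
write_norm_model <- function(x, path) {
  lst <- unclass(x)
  if (!is.null(lst$coefficients))
    lst$coefficients <- as.list(lst$coefficients)  # keep names in JSON
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_norm_model
#' @export
read_norm_model <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(lst$expected_gain_by_visit))
    return(practice_model(lst$expected_gain_by_visit))
  lst$coefficients <- unlist(lst$coefficients)
  structure(lst, class = "norm_model")
}
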