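# Shared fixtures and independent oracles for the test suite.

# Hand-coded dichotomization oracle: one explicit if/else per health
# criterion, written directly from the printed criteria table and kept
# independent of the package's CSV-driven dispatch.
oracle_dichotomize <- function(item, value, sex = NULL) {
  deficit <- switch(item,
    bmi = value > 25 || value < 18,
    wbc = value < 4000,
    mchc = if (sex == "M") value < 27.8 || value > 33.8
           else value < 26.9 || value > 33.3,
    bun = value < 8 || value > 23,
    creatinine = value < 0.6 || value > 1.2,
    calcium = value < 9.2 || value > 10.8,
    chloride = value < 96 || value > 106,
    total_protein = value < 6 || value > 7.8,
    albumin = value < 3.5,
    fibrinogen = value > 3.25,
    egfr = value < 60,
    hemoglobin = if (sex == "M") value < 12 else value < 10,
    ast = value > 31,
    alt = value > 31,
    alp = value < 38 || value > 126,
    potassium = value < 3.5 || value > 5.3,
    bilirubin = value > 1.1,
    triglycerides = value >= 150,
    cholesterol = value > 200,
    hdl = if (sex == "M") value < 40 else value < 50,
    glucose = value > 200,
    weight_loss = value > 0,
    platelets = value < 150,
    hcv = ,
    diabetes = ,
    copd = ,
    malignancy = ,
    myocardial_infarction = ,
    renal_disease = ,
    hyperlipidemia = ,
    cerebrovascular_accident = ,
    sensory_neuropathy = ,
    neuropathic_pain = ,
    smoking = value > 0,
    hypertension = {
      v <- as.list(value)
      isTRUE(v$flag > 0) ||
        (!is.null(v$systolic) && v$systolic > 130) ||
        (!is.null(v$diastolic) && v$diastolic > 85)
    },
    current_cd4 = value < 500,
    nadir_cd4 = value < 200,
    hiv_rna = value > 40,
    disease_duration = value > 10,
    stop("oracle: unknown item ", item))
  if (deficit) "deficit" else "normal"
}

# A complete profile satisfying every normal condition.
profile_all_normal <- function() {
  list(bmi = 22, wbc = 6000, mchc = 30, bun = 15, creatinine = 0.9,
       calcium = 9.8, chloride = 100, total_protein = 7, albumin = 4.2,
       fibrinogen = 2.5, egfr = 90, hemoglobin = 14, ast = 25, alt = 22,
       alp = 80, potassium = 4.2, bilirubin = 0.7, triglycerides = 120,
       cholesterol = 170, hdl = 55, glucose = 90, weight_loss = 0,
       platelets = 250, hcv = 0, diabetes = 0, copd = 0, malignancy = 0,
       myocardial_infarction = 0, renal_disease = 0,
       hypertension = list(flag = 0, systolic = 118, diastolic = 72),
       hyperlipidemia = 0, cerebrovascular_accident = 0,
       sensory_neuropathy = 0, neuropathic_pain = 0, smoking = 0,
       current_cd4 = 600, nadir_cd4 = 300, hiv_rna = 20,
       disease_duration = 5)
}

# A complete profile failing every criterion (male cutoffs).
profile_all_deficit <- function() {
  list(bmi = 30, wbc = 3000, mchc = 35, bun = 30, creatinine = 1.8,
       calcium = 8.5, chloride = 110, total_protein = 5.5, albumin = 3.0,
       fibrinogen = 4.0, egfr = 45, hemoglobin = 10, ast = 50, alt = 60,
       alp = 150, potassium = 5.8, bilirubin = 1.5, triglycerides = 200,
       cholesterol = 250, hdl = 30, glucose = 260, weight_loss = 1,
       platelets = 100, hcv = 1, diabetes = 1, copd = 1, malignancy = 1,
       myocardial_infarction = 1, renal_disease = 1,
       hypertension = list(flag = 1, systolic = 150, diastolic = 95),
       hyperlipidemia = 1, cerebrovascular_accident = 1,
       sensory_neuropathy = 1, neuropathic_pain = 1, smoking = 1,
       current_cd4 = 300, nadir_cd4 = 100, hiv_rna = 10000,
       disease_duration = 20)
}

# Generator config with all trajectory noise silenced.
noiseless_config <- function(n = 40, K = 3, seed = 1) {
  generator_config(n_participants = n, seed = seed,
                   random_intercept_sd = 0, random_slope_sd = 0,
                   residual_sd = 0, domain_scatter_sd = 0,
                   practice_gains = rep(0, 10))
}

# Config with missingness switched off (hazard ~ 0).
no_missing_model <- function() {
  list(intercept = -30, education = 0, enroll_date = 0,
       monotone = TRUE, first_hazard_visit = 1L)
}

# Small synthetic norm model with hand-set coefficients, bypassing lm().
toy_norm_model <- function(intercept = 30, age = 0, education = 0.5,
                           residual_sd = 8) {
  structure(list(
    coefficients = c("(Intercept)" = intercept, age = age,
                     education = education, sexM = 0),
    residual_sd = residual_sd,
    sex_levels = c("F", "M"), race_levels = "black",
    fitted_on = "hand-set"), class = "norm_model")
}

# Complete-data panel from an explicit K-class quadratic mixture.
simulate_quadratic_panel <- function(n, alpha, pi_k, int_sd = 3,
                                     slope_sd = 0.3, resid_sd = 4,
                                     J = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- 0:(J - 1)
  K <- length(pi_k)
  cls <- sample.int(K, n, replace = TRUE, prob = pi_k)
  mu <- t(cbind(1, tt, tt^2) %*% alpha[, cls])
  y <- mu + rnorm(n, 0, int_sd) + outer(rnorm(n, 0, slope_sd), tt) +
    matrix(rnorm(n * J, 0, resid_sd), n, J)
  list(panel = visit_panel(y, times = tt), class = cls)
}
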