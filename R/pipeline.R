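#' Pipeline run configuration
#'
#' Bundles every stage option of the end-to-end analysis:
#' generate -> norm -> classify -> reserve -> growth mixture enumeration ->
#' three-step covariate analysis.
#'
#' @param seed Master seed; recorded in the output manifest and used for
#'   every stochastic stage.
#' @param generator A [generator_config()].
#' @param base_model Growth basis for the mixture (`"quadratic"` default)
#'   or `"auto"` to select by single-class information criteria.
#' @param Kmax Largest class count to enumerate.
#' @param n_starts Random starts per mixture fit.
#' @param n_norm Synthetic normative sample size.
#' @param n_retest Synthetic retest sample size for practice estimation.
#' @param lmr_alpha Significance level in the class-selection rule.
#' @param outdir Optional directory for the report bundle.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1, generator = generator_config(),
                       base_model = "quadratic", Kmax = 4, n_starts = 50,
                       n_norm = 5000, n_retest = 500, lmr_alpha = 0.05,
                       outdir = NULL) {
  structure(list(seed = seed, generator = generator,
                 base_model = base_model, Kmax = Kmax, n_starts = n_starts,
                 n_norm = n_norm, n_retest = n_retest,
                 lmr_alpha = lmr_alpha, outdir = outdir),
            class = "run_config")
}

#' Run the full trajectory-mixture analysis pipeline
#'
#' Executes every stage on a synthetic cohort: cohort generation; normative
#' regression fitting on a synthetic normative sample; practice-effect
#' estimation from a synthetic retest sample; practice correction and
#' peak-age T-scoring of every domain score; global-score panel
#' construction; baseline SA/CN/CI classification; physiologic reserve
#' scoring; covariance-coverage and missingness diagnostics; latent class
#' enumeration with the growth mixture engine; concordance of baseline
#' status with modal class; univariable screening and three-step
#' multinomial regression. Deterministic given `cfg$seed`. A stage failure
#' aborts with an error naming the stage; previously computed stages are
#' attached to the error condition.
#'
#' @param cfg A [run_config()].
#' @return Object of class `pipeline_result`: a list with the cohort,
#'   norm/practice models, scored panel, baseline statuses, reserve
#'   indices, solution table, selected fit, concordance test, screening
#'   and multinomial tables, trajectory-mean export, and a manifest.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  state <- list(config = cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(structure(class = c("pipeline_error", "error", "condition"),
                     list(message = sprintf("stage '%s' failed: %s", name,
                                            conditionMessage(e)),
                          call = NULL, partial = state))))
  }
  set.seed(cfg$seed)

  cohort <- stage("generate", generate_cohort(cfg$generator, seed = cfg$seed))
  state$cohort <- cohort
  gen <- cfg$generator

  norm_sample <- stage("norms", generate_norm_sample(gen, cfg$n_norm))
  nm <- stage("norms", fit_norms(norm_sample,
                                 required_races = unique(cohort$baseline_table$race)))
  state$norm_model <- nm
  pm <- stage("practice", estimate_practice(generate_retest_sample(gen, cfg$n_retest)))
  state$practice_model <- pm

  scored <- stage("scoring", score_cohort(cohort, nm, pm))
  state$scored <- scored
  panel <- stage("scoring", build_panel(scored$visit_table,
                                        value = "global_peak_T"))
  state$panel <- panel

  status <- stage("classify", classify_baseline_all(
    scored$baseline_peak_global, scored$baseline_chron_domains))
  state$status <- status
  reserve <- stage("reserve", score_reserve(cohort$baseline_table))
  state$reserve <- reserve

  coverage <- stage("coverage", covariance_coverage(panel))
  state$coverage <- coverage

  spec <- if (identical(cfg$base_model, "auto"))
    stage("base_model", select_base_model(panel)$best)
  else growth_spec(cfg$base_model, times = panel_times(panel))
  state$spec <- spec

  solutions <- stage("enumerate",
                     enumerate_classes(panel, spec, Kmax = cfg$Kmax,
                                       n_starts = cfg$n_starts,
                                       seed = cfg$seed))
  state$solutions <- solutions
  state$notes <- character(0)

  if (cfg$Kmax == 1) {
    state$selected <- list(K = 1, fit = attr(solutions, "fits")[[1]],
                           reason = "Kmax = 1")
    state$notes <- c(state$notes,
                     "single-class enumeration: concordance and covariate analyses skipped")
  } else {
    # selection and, when multi-class, the downstream covariate stages
    state$selected <- stage("select",
                            select_class_solution(solutions, cfg$lmr_alpha))
  }

  if (state$selected$K == 1 && cfg$Kmax > 1) {
    state$notes <- c(state$notes,
                     "single-class solution selected: concordance and covariate analyses skipped")
  }
  if (state$selected$K > 1) {
    fit <- state$selected$fit
    classes <- modal_assign(fit$posterior)
    state$classes <- classes
    state$concordance <- stage("concordance",
                               crosstab_status_by_class(status, classes))

    cov_tab <- stage("covariates", data.frame(
      age = cohort$baseline_table$age,
      sex = cohort$baseline_table$sex,
      race = cohort$baseline_table$race,
      education = cohort$baseline_table$education,
      wrat4 = cohort$baseline_table$wrat4,
      paofi = cohort$baseline_table$paofi,
      bdi = cohort$baseline_table$bdi,
      lifetime_mdd = factor(cohort$baseline_table$lifetime_mdd),
      substance_use = factor(cohort$baseline_table$substance_use),
      aids = factor(cohort$baseline_table$aids),
      disease_duration = cohort$baseline_table$disease_duration,
      nadir_cd4 = cohort$baseline_table$nadir_cd4,
      current_cd4 = cohort$baseline_table$current_cd4,
      suppressed = factor(cohort$baseline_table$hiv_rna <= 40),
      reserve = reserve,
      stringsAsFactors = FALSE))
    state$missingness <- stage("missingness", missingness_correlates(
      panel, data.frame(education = cohort$baseline_table$education,
                        enroll_date = cohort$baseline_table$enroll_date)))
    state$screen <- stage("screen", univariable_screen(
      cov_tab, classes,
      skewed = c("paofi", "bdi", "nadir_cd4", "current_cd4")))
    selected_vars <- state$screen$variable[state$screen$selected]
    if (length(selected_vars) > 0) {
      state$multinomial <- stage("multinomial", multinomial_fit(
        cov_tab[selected_vars], classes, reference = 1,
        scale_per_sd = intersect(c("wrat4", "reserve"), selected_vars)))
    } else {
      state$notes <- c(state$notes,
                       "no covariate passed univariable screening")
    }
  }

  fit <- state$selected$fit
  L <- growth_loadings(fit$spec, fit$loadings)
  tm <- data.frame(visit = fit$spec$times, L %*% fit$alpha,
                   check.names = FALSE)
  state$trajectory_means <- tm

  state$manifest <- list(package = "trajmix",
                         version = as.character(utils::packageVersion("trajmix")),
                         seed = cfg$seed,
                         n_participants = gen$n_participants,
                         Kmax = cfg$Kmax, n_starts = cfg$n_starts,
                         base_model = state$spec$basis)
  res <- structure(state, class = "pipeline_result")
  if (!is.null(cfg$outdir)) write_bundle(res, cfg$outdir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Trajectory mixture pipeline (seed ", x$config$seed, ")\n", sep = "")
  print(x$solutions)
  cat("\nSelected: K =", x$selected$K, "-", x$selected$reason, "\n")
  if (!is.null(x$concordance))
    cat(sprintf("Status x class chi-square = %.2f (p = %.2g)\n",
                x$concordance$statistic, x$concordance$p_value))
  if (!is.null(x$multinomial)) print(x$multinomial)
  for (nt in x$notes) cat("Note:", nt, "\n")
  invisible(x)
}

# score every observed visit: practice-correct, peak-age T per domain,
# global T; plus baseline chronological-age domain T-scores for SA/CN/CI
score_cohort <- function(cohort, nm, pm) {
  vt <- cohort$visit_table
  bt <- cohort$baseline_table
  domains <- cohort$config$domains
  idx <- match(vt$id, bt$id)
  demog <- data.frame(age = bt$age[idx], education = bt$education[idx],
                      sex = bt$sex[idx], race = bt$race[idx])
  pred25 <- predict_norm(nm, demog, age_override = 25)
  peak <- matrix(NA_real_, nrow(vt), length(domains))
  for (d in seq_along(domains)) {
    raw <- correct_practice(vt[[paste0("raw_", domains[d])]], vt$visit, pm)
    peak[, d] <- 50 + 10 * (raw - pred25) / nm$residual_sd
  }
  vt$global_peak_T <- global_tscore(peak)

  base_rows <- which(vt$visit == 0)
  demog_b <- demog[base_rows, ]
  demog_b$age <- vt$age_at_visit[base_rows]
  pred_age <- predict_norm(nm, demog_b)
  chron <- matrix(NA_real_, length(base_rows), length(domains),
                  dimnames = list(vt$id[base_rows], domains))
  for (d in seq_along(domains)) {
    raw <- vt[[paste0("raw_", domains[d])]][base_rows]
    chron[, d] <- 50 + 10 * (raw - pred_age) / nm$residual_sd
  }
  list(visit_table = vt,
       baseline_peak_global = vt$global_peak_T[base_rows],
       baseline_chron_domains = chron)
}

#' Write a pipeline report bundle
#'
#' CSV/JSON exports of the class solution table, concordance table,
#' predictor table, estimated trajectory means and the provenance
#' manifest.
#'
#' @param res A `pipeline_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(res$solutions),
                   file.path(dir, "class_solutions.csv"), row.names = FALSE)
  utils::write.csv(res$trajectory_means,
                   file.path(dir, "trajectory_means.csv"), row.names = FALSE)
  if (!is.null(res$concordance))
    utils::write.csv(as.data.frame.matrix(res$concordance$counts),
                     file.path(dir, "concordance_counts.csv"))
  if (!is.null(res$screen))
    utils::write.csv(res$screen, file.path(dir, "univariable_screen.csv"),
                     row.names = FALSE)
  if (!is.null(res$multinomial))
    utils::write.csv(res$multinomial$table,
                     file.path(dir, "multinomial_predictors.csv"),
                     row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
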