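#' Enumerate latent class solutions
#'
#' Fits 1..Kmax class growth mixture models and assembles the class
#' solution table: log-likelihood, AIC/BIC/ssBIC, entropy, the
#' Lo-Mendell-Rubin p-value against the (K-1)-class solution, modal class
#' counts, and adequacy flags (every class at least `min_count` members and
#' at least `min_share` of the sample -- the conventional 25-member / 5%
#' recommendations). A solution whose fit fails is retained as a flagged
#' row rather than dropped.
#'
#' @param panel A [visit_panel()].
#' @param spec A [growth_spec()].
#' @param Kmax Largest class count to fit.
#' @param n_starts Random starts per fit.
#' @param seed Seed (start generation).
#' @param min_count,min_share Class-size adequacy thresholds.
#' @param ... Passed to [gmm_fit()].
#' @return An object of class `class_solution_table`: a data frame with one
#'   row per K, with the fitted models in `attr(, "fits")`.
#' @export
enumerate_classes <- function(panel, spec, Kmax = 4, n_starts = 50,
                              seed = NULL, min_count = 25, min_share = 0.05,
                              ...) {
  stopifnot(Kmax >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(unclass(panel))
  fits <- vector("list", Kmax)
  rows <- vector("list", Kmax)
  for (K in seq_len(Kmax)) {
    fit <- tryCatch(gmm_fit(panel, spec, K, n_starts = n_starts, ...),
                    error = function(e) e)
    fits[[K]] <- fit
    if (inherits(fit, "error")) {
      rows[[K]] <- data.frame(K = K, logLik = NA, n_params = NA, AIC = NA,
                              BIC = NA, ssBIC = NA, entropy = NA,
                              LMRT_p = NA, converged = FALSE,
                              adequate = NA,
                              class_sizes = conditionMessage(fit),
                              stringsAsFactors = FALSE)
      next
    }
    idx <- fit_indices(fit)
    lmr_p <- if (K > 1 && !inherits(fits[[K - 1]], "error"))
      lmr_test(fit, fits[[K - 1]])$p_value else NA_real_
    counts <- tabulate(modal_assign(fit$posterior), K)
    adequate <- all(counts >= min_count) && all(counts / n >= min_share)
    rows[[K]] <- data.frame(
      K = K, logLik = idx$logLik, n_params = idx$n_params, AIC = idx$AIC,
      BIC = idx$BIC, ssBIC = idx$ssBIC, entropy = idx$entropy,
      LMRT_p = lmr_p, converged = fit$convergence$converged,
      adequate = adequate,
      class_sizes = paste(sprintf("%d (%.0f%%)", counts, 100 * counts / n),
                          collapse = ", "),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  structure(tab, fits = fits, n = n, min_count = min_count,
            min_share = min_share,
            class = c("class_solution_table", "data.frame"))
}

#' @export
print.class_solution_table <- function(x, digits = 3, ...) {
  cat("Growth mixture model fit statistics\n")
  df <- as.data.frame(x)
  df$logLik <- round(df$logLik, digits)
  for (cl in c("AIC", "BIC", "ssBIC")) df[[cl]] <- round(df[[cl]], digits)
  df$entropy <- round(df$entropy, 3)
  df$LMRT_p <- round(df$LMRT_p, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Pick a class solution from an enumeration table
#'
#' Encodes the holistic enumeration rule as a reproducible default: the
#' smallest K for which the (K+1)-class alternative fails the LMR test at
#' `alpha` and whose own classes are adequate. If no K satisfies both, the
#' adequate solution with the best ssBIC is returned with a note. The rule
#' is intentionally overridable, since enumeration in practice also weighs
#' interpretability and parsimony.
#'
#' @param tab A `class_solution_table`.
#' @param alpha LMR significance level.
#' @return List: `K`, `fit`, `reason`.
#' @export
select_class_solution <- function(tab, alpha = 0.05) {
  fits <- attr(tab, "fits")
  df <- as.data.frame(tab)
  ok <- which(df$adequate %in% TRUE)
  for (K in seq_len(nrow(df))) {
    if (!(K %in% ok)) next
    next_p <- if (K + 1 <= nrow(df)) df$LMRT_p[K + 1] else NA
    if (is.na(next_p) || next_p >= alpha)
      return(list(K = K, fit = fits[[K]],
                  reason = sprintf(
                    "smallest adequate K whose %d-class alternative fails LMRT",
                    K + 1)))
  }
  if (length(ok) == 0)
    stop("no adequate class solution in the table", call. = FALSE)
  K <- ok[which.min(df$ssBIC[ok])]
  list(K = K, fit = fits[[K]],
       reason = "no K passed the LMRT rule; best ssBIC among adequate")
}

#' Select the base growth model
#'
#' Fits each candidate growth basis as a single-class latent growth model
#' and ranks by AIC (ssBIC as tiebreaker), returning the winning spec and
#' the comparison table.
#'
#' @param panel A [visit_panel()].
#' @param candidates Character vector of bases to try.
#' @param random Random-effect structure passed to [growth_spec()].
#' @param ... Passed to [gmm_fit()].
#' @return List: `best` (a [growth_spec()]), `table` (data frame).
#' @export
select_base_model <- function(panel,
                              candidates = c("intercept", "linear",
                                             "quadratic", "cubic"),
                              random = c("intercept", "slope"), ...) {
  times <- panel_times(panel)
  rows <- lapply(candidates, function(b) {
    spec <- growth_spec(b, times = times, random = random)
    fit <- tryCatch(gmm_fit(panel, spec, K = 1, n_starts = 1, ...),
                    error = function(e) e)
    if (inherits(fit, "error"))
      return(data.frame(basis = b, logLik = NA, n_params = NA,
                        AIC = NA, ssBIC = NA, stringsAsFactors = FALSE))
    idx <- fit_indices(fit)
    data.frame(basis = b, logLik = idx$logLik, n_params = idx$n_params,
               AIC = idx$AIC, ssBIC = idx$ssBIC, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$AIC, tab$ssBIC)
  best <- tab$basis[ord[1]]
  list(best = growth_spec(best, times = times, random = random), table = tab)
}

#' Refit excluding the baseline visit
#'
#' Removes the first visit from the panel (keeping the original time
#' codes, so the intercept still refers to baseline) and refits the
#' K-class model on follow-up data only. Reports the cross-tabulation of
#' modal class assignments between the primary and the baseline-free fits,
#' to check that class structure is not an artifact of the baseline
#' indicator.
#'
#' @param panel A [visit_panel()] with at least 5 visits.
#' @param spec A [growth_spec()].
#' @param K Number of classes.
#' @param primary_fit Optional existing fit on the full panel; fitted here
#'   when absent.
#' @param ... Passed to [gmm_fit()].
#' @return List: `fit` (secondary fit), `primary_fit`, `shift_table`
#'   (primary x secondary modal counts over participants retained in
#'   both), `n_shifted`.
#' @export
drop_baseline_refit <- function(panel, spec, K, primary_fit = NULL, ...) {
  Y <- unclass(panel)
  if (ncol(Y) - 1 < 4)
    stop("need at least 4 follow-up visits after dropping baseline",
         call. = FALSE)
  if (is.null(rownames(Y)))
    rownames(Y) <- sprintf("row%d", seq_len(nrow(Y)))
  panel <- visit_panel(Y, times = panel_times(panel))
  times <- panel_times(panel)
  if (is.null(primary_fit)) primary_fit <- gmm_fit(panel, spec, K, ...)
  sub <- suppressWarnings(visit_panel(Y[, -1, drop = FALSE],
                                      times = times[-1],
                                      ids = rownames(Y)))
  spec2 <- growth_spec(spec$basis, times = times[-1], random = spec$random)
  fit2 <- gmm_fit(sub, spec2, K, ...)
  prim <- modal_assign(primary_fit$posterior)
  names(prim) <- rownames(unclass(panel))
  sec <- modal_assign(fit2$posterior)
  names(sec) <- rownames(unclass(sub))
  common <- intersect(names(prim), names(sec))
  shift <- table(primary = prim[common], secondary = sec[common])
  list(fit = fit2, primary_fit = primary_fit, shift_table = shift,
       n_shifted = sum(shift) - sum(diag(as.matrix(shift))))
}

#' Serialize a gmm fit to JSON
#' @param fit A `gmm_fit`.
#' @param path Output path.
#' @param posterior Include the posterior matrix.
#' @return `path`, invisibly.
#' @export
write_gmm_fit <- function(fit, path, posterior = FALSE) {
  out <- list(K = fit$K, pi = fit$pi,
              alpha = apply(fit$alpha, 2, as.numeric, simplify = FALSE),
              Psi = apply(fit$Psi, 1, as.numeric, simplify = FALSE),
              sigma2 = fit$sigma2, loglik = fit$loglik,
              n_params = fit$n_params, n = fit$n,
              basis = fit$spec$basis, times = fit$spec$times,
              convergence = fit$convergence[c("iterations", "converged",
                                              "best_replicated")])
  if (posterior)
    out$posterior <- apply(fit$posterior, 1, as.numeric, simplify = FALSE)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
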