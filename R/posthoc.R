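#' Modal class assignment from a posterior matrix
#'
#' Hard (modal) assignment: the class with the largest posterior
#' probability per participant, ties broken toward the lower class index
#' (with a message). Assigning membership before covariate modelling is
#' the first step of the three-step approach, which prevents covariates
#' from reshaping the latent classes.
#'
#' @param p_ik Posterior matrix; rows must sum to 1 within 1e-6.
#' @return Integer class labels.
#' @export
modal_assign <- function(p_ik) {
  p_ik <- as.matrix(p_ik)
  bad <- abs(rowSums(p_ik) - 1) > 1e-6
  if (any(bad))
    stop(sum(bad), " posterior row(s) do not sum to 1 (within 1e-6)",
         call. = FALSE)
  lab <- max.col(p_ik, ties.method = "first")
  rowmax <- p_ik[cbind(seq_len(nrow(p_ik)), lab)]
  nties <- sum(rowSums(abs(p_ik - rowmax) < 1e-12) > 1)
  if (nties > 0)
    message(nties, " tie(s) broken toward the lower class index")
  lab
}

#' Univariable screening of baseline covariates against class membership
#'
#' Omnibus association test per covariate, dispatching on type: one-way
#' ANOVA for continuous variables (Kruskal-Wallis for variables declared
#' skewed, e.g. symptom counts), chi-square for categorical variables,
#' switching to Fisher's exact test when any expected cell count falls
#' below 5. Covariates with omnibus p below `alpha` (default 0.10) are
#' flagged for inclusion in the multivariable model; constant covariates
#' are excluded with a note.
#'
#' @param covariates Data frame of baseline covariates.
#' @param labels Class labels (vector, same length).
#' @param skewed Covariate names tested by Kruskal-Wallis.
#' @param alpha Selection threshold.
#' @return Data frame: `variable`, `test`, `statistic`, `p_value`,
#'   `selected`, `note`.
#' @export
univariable_screen <- function(covariates, labels,
                               skewed = character(0), alpha = 0.10) {
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    stop("need at least two classes present", call. = FALSE)
  rows <- lapply(names(covariates), function(v) {
    x <- covariates[[v]]
    out <- data.frame(variable = v, test = NA_character_,
                      statistic = NA_real_, p_value = NA_real_,
                      selected = FALSE, note = "", stringsAsFactors = FALSE)
    ok <- !is.na(x) & !is.na(labels)
    if (length(unique(x[ok])) < 2) {
      out$note <- "constant; excluded"
      return(out)
    }
    if (is.numeric(x) && !(v %in% skewed) && length(unique(x[ok])) > 5) {
      fit <- stats::oneway.test(x[ok] ~ labels[ok], var.equal = TRUE)
      out$test <- "ANOVA F"
      out$statistic <- unname(fit$statistic)
      out$p_value <- fit$p.value
    } else if (is.numeric(x) && v %in% skewed) {
      fit <- stats::kruskal.test(x[ok], labels[ok])
      out$test <- "Kruskal-Wallis"
      out$statistic <- unname(fit$statistic)
      out$p_value <- fit$p.value
    } else {
      tab <- table(x[ok], labels[ok])
      expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expct < 5)) {
        fit <- stats::fisher.test(tab, simulate.p.value = nrow(tab) * ncol(tab) > 10,
                                  B = 1e4)
        out$test <- "Fisher exact"
        out$p_value <- fit$p.value
      } else {
        fit <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        out$test <- "chi-square"
        out$statistic <- unname(fit$statistic)
        out$p_value <- fit$p.value
      }
    }
    out$selected <- is.finite(out$p_value) && out$p_value < alpha
    out
  })
  do.call(rbind, rows)
}

#' Multinomial logistic regression of class membership on covariates
#'
#' Maximum-likelihood multinomial logit with a chosen reference class
#' (step three of the three-step approach). Covariates named in
#' `scale_per_sd` are divided by their sample SD before fitting so their
#' odds ratios are per 1-SD-unit increase. With `prune = TRUE`, covariates
#' whose every class contrast has p at or above `prune_alpha` are removed
#' backward -- one per pass, the covariate with the largest minimum p
#' first -- and the model re-estimated. Wald confidence intervals and
#' p-values are reported; coefficients with extreme magnitude trigger a
#' separation warning.
#'
#' @param covariates Data frame of (already screened) covariates.
#' @param labels Class labels.
#' @param reference Reference class label (default: first sorted level).
#' @param scale_per_sd Covariate names expressed per sample SD.
#' @param prune Backward-prune non-discriminating covariates.
#' @param prune_alpha Pruning threshold (default 0.10).
#' @param conf_level Confidence level for the Wald intervals.
#' @return Object of class `multinomial_result`: data frame `table`
#'   (`class`, `term`, `estimate` = log-odds, `OR`, `ci_lo`, `ci_hi`,
#'   `p_value`, `scale`), plus `reference`, `dropped`, `model`.
#' @export
multinomial_fit <- function(covariates, labels, reference = NULL,
                            scale_per_sd = character(0), prune = TRUE,
                            prune_alpha = 0.10, conf_level = 0.95) {
  labels <- factor(labels)
  if (is.null(reference)) reference <- levels(labels)[1]
  if (!reference %in% levels(labels))
    stop("reference class '", reference, "' not present", call. = FALSE)
  labels <- stats::relevel(labels, ref = as.character(reference))
  dat <- as.data.frame(covariates)
  sds <- numeric(0)
  for (v in intersect(scale_per_sd, names(dat))) {
    sds[v] <- stats::sd(dat[[v]], na.rm = TRUE)
    dat[[v]] <- dat[[v]] / sds[v]
  }
  dropped <- character(0)
  repeat {
    if (ncol(dat) == 0)
      stop("all covariates pruned; nothing to report", call. = FALSE)
    fit <- nnet::multinom(labels ~ ., data = dat, trace = FALSE,
                          maxit = 1000, abstol = 1e-12, reltol = 1e-12,
                          Hess = TRUE)
    tab <- wald_table(fit, conf_level)
    if (any(abs(tab$estimate) > 15, na.rm = TRUE))
      warning("very large coefficient magnitude: possible (quasi-)separation; ",
              "consider collapsing sparse categories or penalization")
    if (!prune) break
    ## backward pruning on the minimum p across class contrasts per covariate
    terms_by_var <- term_variable_map(fit, dat)
    minp <- tapply(tab$p_value, terms_by_var[tab$term], min)
    minp <- minp[!is.na(minp) & names(minp) != "(Intercept)"]
    worst <- names(minp)[which.max(minp)]
    if (length(worst) == 0 || minp[worst] < prune_alpha) break
    dropped <- c(dropped, worst)
    dat[[worst]] <- NULL
  }
  tab$scale <- ifelse(tab$term %in% names(sds), "per 1 SD", "raw")
  structure(list(table = tab, reference = as.character(reference),
                 dropped = dropped, scaled_sds = sds, model = fit),
            class = "multinomial_result")
}

# map design-matrix column names back to covariate names (factors expand)
term_variable_map <- function(fit, dat) {
  terms <- colnames(stats::coef(fit))
  if (is.null(terms)) terms <- names(stats::coef(fit))
  map <- stats::setNames(terms, terms)
  for (v in names(dat))
    map[startsWith(terms, v)] <- v
  map
}

wald_table <- function(fit, conf_level) {
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(fit$lev[2], names(cf)))
  se <- tryCatch({
    V <- stats::vcov(fit)
    matrix(sqrt(diag(V)), nrow = nrow(cf), byrow = TRUE,
           dimnames = dimnames(cf))
  }, error = function(e) cf * NA)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- expand.grid(class = rownames(cf), term = colnames(cf),
                     stringsAsFactors = FALSE)
  out$estimate <- cf[cbind(out$class, out$term)]
  out$se <- se[cbind(out$class, out$term)]
  out$OR <- exp(out$estimate)
  out$ci_lo <- exp(out$estimate - z * out$se)
  out$ci_hi <- exp(out$estimate + z * out$se)
  out$p_value <- 2 * stats::pnorm(-abs(out$estimate / out$se))
  out[out$term != "(Intercept)", , drop = FALSE]
}

#' @export
print.multinomial_result <- function(x, ...) {
  cat("Multinomial logistic regression (reference class: ",
      x$reference, ")\n", sep = "")
  tab <- x$table
  tab$OR <- sprintf("%.2f", tab$OR)
  tab$CI <- sprintf("%.2f-%.2f", tab$ci_lo, tab$ci_hi)
  tab$p <- format.pval(tab$p_value, digits = 3, eps = 1e-3)
  print(tab[, c("class", "term", "OR", "CI", "p", "scale")],
        row.names = FALSE)
  if (length(x$dropped) > 0)
    cat("Pruned (all contrasts p >= 0.10):",
        paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one odds ratio from a multinomial result
#' @param x A `multinomial_result`.
#' @param term Covariate (design-matrix) name.
#' @param class Contrast class label.
#' @return Named list `OR`, `ci_lo`, `ci_hi`, `p_value`.
#' @export
get_or <- function(x, term, class) {
  row <- x$table[x$table$term == term & x$table$class == class, ]
  if (nrow(row) != 1)
    stop("no unique entry for term '", term, "', class '", class, "'",
         call. = FALSE)
  as.list(row[, c("OR", "ci_lo", "ci_hi", "p_value")])
}

#' Correlates of missing visits
#'
#' Spearman rank correlation between each candidate covariate and the
#' per-participant count of missing visits; covariates with p below
#' `alpha` are flagged as auxiliary-variable candidates for
#' missing-data-aware estimation.
#'
#' @param panel A [visit_panel()].
#' @param covariates Data frame aligned with the panel rows.
#' @param alpha Flagging threshold (default 0.05).
#' @return Data frame: `variable`, `rho`, `p_value`, `flagged`.
#' @export
missingness_correlates <- function(panel, covariates, alpha = 0.05) {
  miss <- rowSums(is.na(unclass(panel)))
  if (length(miss) != nrow(covariates))
    stop("panel and covariates are not aligned", call. = FALSE)
  if (stats::var(miss) == 0) {
    return(data.frame(variable = names(covariates), rho = NA_real_,
                      p_value = NA_real_, flagged = FALSE,
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(names(covariates), function(v) {
    x <- covariates[[v]]
    if (!is.numeric(x))
      return(data.frame(variable = v, rho = NA_real_, p_value = NA_real_,
                        flagged = FALSE, stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(miss, x, method = "spearman",
                                           exact = FALSE))
    data.frame(variable = v, rho = unname(ct$estimate),
               p_value = ct$p.value,
               flagged = is.finite(ct$p.value) && ct$p.value < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
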