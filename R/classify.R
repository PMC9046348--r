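#' Deficit points for a chronological-age T-score
#'
#' The deficit-score mapping used for global neurocognitive impairment
#' staging in HIV research: T >= 40 carries 0 deficit points, with one
#' additional point per 5-T-point band below 40, capped at 5 points below
#' T = 20. Bands are half-open with the cutoff included in the better band
#' (T = 40 scores 0; T = 39.9 scores 1).
#'
#' @param T Numeric T-score(s); must be finite.
#' @return Integer deficit points in 0..5.
#' @export
deficit_score <- function(T) {
  if (any(!is.finite(T))) stop("T-scores must be finite", call. = FALSE)
  as.integer(pmin(5, pmax(0, ceiling((40 - T) / 5))))
}

#' Classify baseline neurocognitive status (SA / CN / CI)
#'
#' SuperAger (SA): peak-age global T-score within normative expectations
#' for 25-year-olds (>= 40, i.e. no worse than 1 SD below the young-adult
#' mean) AND no isolated domain impairment on traditional
#' chronological-age norms (every domain T >= 40). Non-SA participants are
#' cognitively impaired (CI) when the global deficit score -- the mean of
#' per-domain deficit points from [deficit_score()] -- is at least
#' `gds_cutoff` (default 0.5), and cognitively normal (CN) otherwise.
#'
#' @param peak_global_T Baseline global peak-age T-score (scalar).
#' @param domain_chronological_Ts Numeric vector of per-domain
#'   chronological-age T-scores (NA = domain not administered).
#' @param gds_cutoff Global deficit score impairment cutoff.
#' @param domain_cutoff Domain impairment cutoff on the T scale.
#' @return An object of class `baseline_status`: `label` ("SA", "CN" or
#'   "CI"), `peak_global_T`, `domain_chronological_Ts`, `gds`.
#' @export
classify_baseline <- function(peak_global_T, domain_chronological_Ts,
                              gds_cutoff = 0.5, domain_cutoff = 40) {
  if (length(peak_global_T) != 1 || is.na(peak_global_T))
    stop("peak_global_T must be a single non-missing value", call. = FALSE)
  doms <- domain_chronological_Ts[!is.na(domain_chronological_Ts)]
  if (length(doms) == 0)
    stop("need at least one domain T-score", call. = FALSE)
  gds <- mean(deficit_score(doms))
  label <- if (peak_global_T >= 40 && all(doms >= domain_cutoff)) "SA"
           else if (gds >= gds_cutoff) "CI"
           else "CN"
  structure(list(label = label, peak_global_T = peak_global_T,
                 domain_chronological_Ts = domain_chronological_Ts,
                 gds = gds),
            class = "baseline_status")
}

#' @export
print.baseline_status <- function(x, ...) {
  cat(sprintf("Baseline status: %s (peak-age global T = %.1f, GDS = %.3f)\n",
              x$label, x$peak_global_T, x$gds))
  invisible(x)
}

#' Classify every row of a scored baseline table
#'
#' @param peak_global_T Vector of baseline global peak-age T-scores.
#' @param domain_chronological_Ts Matrix (participants x domains) of
#'   chronological-age domain T-scores.
#' @inheritParams classify_baseline
#' @return Factor with levels SA, CN, CI.
#' @export
classify_baseline_all <- function(peak_global_T, domain_chronological_Ts,
                                  gds_cutoff = 0.5, domain_cutoff = 40) {
  m <- as.matrix(domain_chronological_Ts)
  stopifnot(length(peak_global_T) == nrow(m))
  labels <- vapply(seq_len(nrow(m)), function(i)
    classify_baseline(peak_global_T[i], m[i, ], gds_cutoff,
                      domain_cutoff)$label, character(1L))
  factor(labels, levels = c("SA", "CN", "CI"))
}

#' Cross-tabulate baseline status by latent trajectory class
#'
#' Contingency table of baseline neurocognitive status against modal latent
#' class membership, with row/column percentages and a chi-square test of
#' independence -- the concordance check between cross-sectional SuperAging
#' criteria and longitudinal class structure.
#'
#' @param statuses Vector/factor of baseline labels.
#' @param classes Vector of latent class labels (same length).
#' @return List with `counts`, `row_pct`, `col_pct`, `statistic`, `df`,
#'   `p_value` (statistic/p are `NA` with a warning for degenerate tables).
#' @export
crosstab_status_by_class <- function(statuses, classes) {
  if (length(statuses) == 0 || length(statuses) != length(classes))
    stop("statuses and classes must be non-empty and of equal length",
         call. = FALSE)
  tab <- table(status = statuses, class = classes)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    warning("degenerate contingency table; chi-square not defined")
    return(list(counts = tab, row_pct = prop.table(tab, 1) * 100,
                col_pct = prop.table(tab, 2) * 100,
                statistic = NA_real_, df = NA_integer_, p_value = NA_real_))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(counts = tab,
       row_pct = prop.table(tab, 1) * 100,
       col_pct = prop.table(tab, 2) * 100,
       statistic = unname(ct$statistic),
       df = unname(ct$parameter),
       p_value = ct$p.value)
}
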