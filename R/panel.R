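#' Visit panel of longitudinal scores
#'
#' A `visit_panel` is the indicator data for the growth mixture model: one
#' row per participant, one column per visit, `NA` marking unobserved
#' visits, with the time codes stored as an attribute (visit index units,
#' 6-month spacing, t = 0, 1, ...).
#'
#' @param scores Numeric matrix (participants x visits); `NA` = missing.
#' @param times Numeric time codes, one per column.
#' @param ids Optional participant ids (rownames).
#' @return An object of class `visit_panel`.
#' @export
visit_panel <- function(scores, times = seq_len(ncol(scores)) - 1,
                        ids = rownames(scores)) {
  scores <- as.matrix(scores)
  if (length(times) != ncol(scores))
    stop("times must have one entry per visit column", call. = FALSE)
  if (!is.null(ids)) rownames(scores) <- ids
  zero <- rowSums(!is.na(scores)) == 0
  if (any(zero)) {
    warning(sum(zero), " participant(s) with no observed visits excluded")
    scores <- scores[!zero, , drop = FALSE]
  }
  structure(scores, times = as.numeric(times), class = c("visit_panel", "matrix"))
}

#' @export
print.visit_panel <- function(x, ...) {
  cat(sprintf("Visit panel: %d participants x %d visits (%.1f%% observed)\n",
              nrow(x), ncol(x), 100 * mean(!is.na(x))))
  cat("Time codes:", paste(panel_times(x), collapse = " "), "\n")
  invisible(x)
}

#' @rdname visit_panel
#' @param x A `visit_panel`.
#' @export
panel_times <- function(x) attr(x, "times")

#' Build a visit panel from a cohort or long visit table
#'
#' Reshapes the long visit table to wide, masking visits whose `observed`
#' flag is `FALSE`.
#'
#' @param x A `synthetic_cohort` or a long data frame with columns `id`,
#'   `visit`, `observed`, and the score column.
#' @param value Name of the score column (default `"global_T"`).
#' @return A [visit_panel()].
#' @export
build_panel <- function(x, value = "global_T") {
  vt <- if (inherits(x, "synthetic_cohort")) x$visit_table else x
  stopifnot(all(c("id", "visit", value) %in% names(vt)))
  ids <- unique(vt$id)
  visits <- sort(unique(vt$visit))
  m <- matrix(NA_real_, length(ids), length(visits),
              dimnames = list(ids, paste0("T", visits + 1)))
  obs <- if ("observed" %in% names(vt)) vt$observed else TRUE
  keep <- which(obs)
  m[cbind(match(vt$id[keep], ids), match(vt$visit[keep], visits))] <-
    vt[[value]][keep]
  visit_panel(m, times = visits)
}

#' Read / write a visit panel as wide CSV
#'
#' One row per participant, columns `id`, `T1..TJ`, blanks for missing.
#'
#' @param panel A [visit_panel()].
#' @param path CSV path.
#' @return For `read_panel`, a `visit_panel`; for `write_panel`, `path`.
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(id = rownames(panel) %||% seq_len(nrow(panel)),
                   unclass(panel)[, , drop = FALSE])
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel
#' @param times Time codes for the columns (default 0-based visit index).
#' @export
read_panel <- function(path, times = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- df$id
  m <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  storage.mode(m) <- "double"
  if (is.null(times)) times <- seq_len(ncol(m)) - 1
  visit_panel(m, times = times, ids = as.character(ids))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise covariance coverage of a visit panel
#'
#' For every pair of visits, the fraction of participants observed at both
#' occasions; low coverage signals that a pairwise covariance is estimated
#' from little data. A warning is emitted when the minimum falls below the
#' conventional 0.10 convergence threshold.
#'
#' @param panel A [visit_panel()] or matrix with `NA` for missing.
#' @param warn_below Warning threshold (default 0.10).
#' @return List with `matrix` (J x J coverage) and `minimum`.
#' @export
covariance_coverage <- function(panel, warn_below = 0.10) {
  m <- !is.na(unclass(panel))
  if (ncol(m) < 2) stop("need at least two visits", call. = FALSE)
  cov_mat <- crossprod(m) / nrow(m)
  mn <- min(cov_mat)
  if (mn < warn_below)
    warning(sprintf("minimum covariance coverage %.3f below %.2f",
                    mn, warn_below))
  list(matrix = cov_mat, minimum = mn)
}
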