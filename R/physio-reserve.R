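#' Physiologic reserve criteria table
#'
#' Returns the rules used to dichotomize each of the 39 health variables of
#' the deficit-accumulation physiologic reserve index as normal or deficit.
#' The table is read from a versioned CSV shipped with the package; each row
#' gives the item name, an optional sex restriction, and the open interval of
#' normal values. A measurement is a deficit when it falls strictly below
#' `low` or strictly above `high` (for `triglycerides` the upper bound is
#' inclusive: values at or above the bound are deficits). Flag items
#' (comorbidity diagnoses, weight loss, smoking history) are deficits when
#' positive. `hypertension` is special-cased: a positive diagnosis flag OR
#' systolic pressure above 130 mmHg OR diastolic above 85 mmHg.
#'
#' Note: the hemoglobin cutoffs are kept in the units used by the source
#' criteria table (printed as umol/l) even though g/dl is the conventional
#' laboratory unit; callers must supply measurements on the same scale as the
#' cutoffs.
#'
#' @return A data frame with one row per (item, sex) rule.
#' @export
reserve_criteria <- function() {
  path <- system.file("extdata", "reserve_criteria.csv", package = "trajmix",
                      mustWork = TRUE)
  crit <- utils::read.csv(path, stringsAsFactors = FALSE)
  crit$sex <- ifelse(is.na(crit$sex) | crit$sex == "", NA_character_, crit$sex)
  crit
}

#' Names of the 39 physiologic reserve items
#' @return Character vector of length 39.
#' @export
reserve_items <- function() unique(reserve_criteria()$item)

.find_rule <- function(item, sex, crit) {
  rows <- crit[crit$item == item, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("unknown physiologic reserve item: '", item, "'", call. = FALSE)
  if (all(!is.na(rows$sex))) {
    if (is.null(sex) || is.na(sex))
      stop("item '", item, "' uses sex-specific cutoffs but sex is missing",
           call. = FALSE)
    rows <- rows[rows$sex == sex, , drop = FALSE]
    if (nrow(rows) == 0L)
      stop("no cutoff for item '", item, "' and sex '", sex, "'", call. = FALSE)
  }
  rows[1L, ]
}

#' Dichotomize one physiologic reserve measurement
#'
#' Applies the criteria-table rule for `item` and returns `"normal"` or
#' `"deficit"`. Inequalities are strict, so a value exactly on a printed
#' cutoff is normal, except the inclusive triglycerides bound (>= 150 mg/dl
#' is a deficit). `NA` measurements return `NA` (the item is treated as
#' unavailable by [reserve_index()]).
#'
#' @param item Item name, one of [reserve_items()].
#' @param value The measurement, in the item's units. For `hypertension`,
#'   either a single diagnosis flag or a named vector/list with elements
#'   `flag`, `systolic`, `diastolic` (any subset; missing elements count as
#'   not met).
#' @param sex `"M"` or `"F"`; required only for sex-specific items
#'   (MCHC, hemoglobin, HDL).
#' @param criteria Rules table, defaults to [reserve_criteria()].
#' @return `"normal"`, `"deficit"`, or `NA_character_`.
#' @export
dichotomize <- function(item, value, sex = NULL, criteria = reserve_criteria()) {
  rule <- .find_rule(item, sex, criteria)
  if (identical(rule$special, "bp")) {
    if (is.list(value) || length(value) > 1L) {
      v <- as.list(value)
      flag <- isTRUE(as.logical(v$flag)) ||
        (is.numeric(v$flag) && !is.na(v$flag) && v$flag > 0)
      sbp <- if (!is.null(v$systolic) && !is.na(v$systolic)) v$systolic else -Inf
      dbp <- if (!is.null(v$diastolic) && !is.na(v$diastolic)) v$diastolic else -Inf
      if (all(vapply(v, function(x) is.null(x) || all(is.na(x)), logical(1L))))
        return(NA_character_)
      return(if (flag || sbp > 130 || dbp > 85) "deficit" else "normal")
    }
    if (is.na(value)) return(NA_character_)
    return(if (isTRUE(as.logical(value)) || (is.numeric(value) && value > 0))
      "deficit" else "normal")
  }
  if (length(value) != 1L)
    stop("item '", item, "' expects a single measurement", call. = FALSE)
  if (is.na(value)) return(NA_character_)
  if (isTRUE(rule$is_flag)) {
    return(if (isTRUE(as.logical(value)) || (is.numeric(value) && value > 0))
      "deficit" else "normal")
  }
  value <- as.numeric(value)
  lo <- rule$low
  hi <- rule$high
  deficit <- FALSE
  if (!is.na(lo) && value < lo) deficit <- TRUE
  if (!is.na(hi)) {
    if (isTRUE(rule$high_inclusive)) {
      if (value >= hi) deficit <- TRUE
    } else if (value > hi) deficit <- TRUE
  }
  if (deficit) "deficit" else "normal"
}

#' Construct a physiologic reserve profile
#'
#' A light container for one participant's health measurements keyed to the
#' 39 reserve items. Unmeasured items may be omitted or set `NA`.
#'
#' @param ... Named measurements, names among [reserve_items()]. The
#'   `hypertension` entry may be a list (`flag`, `systolic`, `diastolic`).
#' @param sex `"M"` or `"F"` (required if any sex-specific item is supplied).
#' @return An object of class `reserve_profile`.
#' @export
reserve_profile <- function(..., sex = NULL) {
  vals <- list(...)
  if (length(vals) == 1L && is.null(names(vals)) && is.list(vals[[1L]]))
    vals <- vals[[1L]]
  items <- reserve_items()
  unknown <- setdiff(names(vals), items)
  if (length(unknown) > 0L)
    stop("unknown physiologic reserve item(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(values = vals, sex = sex), class = "reserve_profile")
}

#' Physiologic reserve index
#'
#' The proportion of available health variables scored normal: the number of
#' normal items divided by the number of non-missing items, ranging from 0
#' (every available item a deficit) to 1 (no deficits). Missing items are
#' excluded from both numerator and denominator.
#'
#' @param profile A [reserve_profile()], or a named list of measurements.
#' @param sex Sex override when `profile` is a plain list.
#' @param criteria Rules table, defaults to [reserve_criteria()].
#' @return An object of class `reserve_index` with fields `value`,
#'   `n_available`, `n_normal`.
#' @export
reserve_index <- function(profile, sex = NULL, criteria = reserve_criteria()) {
  if (inherits(profile, "reserve_profile")) {
    vals <- profile$values
    if (is.null(sex)) sex <- profile$sex
  } else {
    vals <- as.list(profile)
  }
  scored <- vapply(names(vals), function(it)
    dichotomize(it, vals[[it]], sex = sex, criteria = criteria),
    character(1L))
  scored <- scored[!is.na(scored)]
  if (length(scored) == 0L)
    stop("no available physiologic reserve items", call. = FALSE)
  n_normal <- sum(scored == "normal")
  structure(list(value = n_normal / length(scored),
                 n_available = length(scored),
                 n_normal = n_normal),
            class = "reserve_index")
}

#' @export
print.reserve_index <- function(x, ...) {
  cat(sprintf("Physiologic reserve index: %.4f (%d normal / %d available)\n",
              x$value, x$n_normal, x$n_available))
  invisible(x)
}

#' Score physiologic reserve for a baseline table
#'
#' Vectorized wrapper: computes the reserve index for each row of a data
#' frame whose columns are named after reserve items (hypertension uses the
#' columns `hypertension`, `systolic`, `diastolic` when present) plus `sex`.
#' Item columns absent from the table, or `NA` in a row, are treated as
#' unavailable for that row.
#'
#' @param baseline Data frame with item columns and a `sex` column.
#' @param criteria Rules table.
#' @return Numeric vector of index values, one per row.
#' @export
score_reserve <- function(baseline, criteria = reserve_criteria()) {
  items <- intersect(reserve_items(), names(baseline))
  if (length(items) == 0L)
    stop("baseline table has no physiologic reserve item columns", call. = FALSE)
  sex <- if ("sex" %in% names(baseline)) as.character(baseline$sex) else
    rep(NA_character_, nrow(baseline))
  vapply(seq_len(nrow(baseline)), function(i) {
    vals <- as.list(baseline[i, items, drop = FALSE])
    if ("hypertension" %in% items &&
        all(c("systolic", "diastolic") %in% names(baseline))) {
      vals$hypertension <- list(flag = baseline$hypertension[i],
                                systolic = baseline$systolic[i],
                                diastolic = baseline$diastolic[i])
    }
    vals <- vals[!vapply(vals, function(v)
      !is.list(v) && length(v) == 1L && is.na(v), logical(1L))]
    if (length(vals) == 0L) return(NA_real_)
    reserve_index(vals, sex = sex[i], criteria = criteria)$value
  }, numeric(1L))
}
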