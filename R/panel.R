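#' Intervention time-series panels
#'
#' A panel bundles a dated focal outcome series with a set of reference
#' (counterfactual) series at a regular weekly or monthly resolution. The
#' focal series is the outcome the counterfactual regression forecasts; the
#' reference series supply the predictors. Panels are ordinary tibbles with a
#' `date` column, a focal column, and one column per reference series, plus
#' attributes recording which column is focal, the sampling frequency, and
#' the outcome kind.
#'
#' @param data A data frame with a `date` column (`Date` or ISO-8601
#'   character), one focal column, and zero or more reference columns.
#' @param focal Name of the focal column. Default `"focal"`.
#' @param frequency `"weekly"` or `"monthly"`.
#' @param outcome_kind `"proportion"` (relative search frequency in `[0, 1]`),
#'   `"count"` (non-negative integers), or `"positive_real"` (e.g. visits).
#'
#' @return A tibble of class `cf_panel`.
#' @examples
#' df <- data.frame(
#'   date = seq(as.Date("2016-01-03"), by = "7 days", length.out = 8),
#'   focal = c(.2, .3, .25, .4, .35, .5, .45, .6),
#'   sp1 = c(.1, .2, .15, .3, .25, .4, .35, .5)
#' )
#' panel(df, frequency = "weekly", outcome_kind = "proportion")
#' @export
panel <- function(data, focal = "focal",
                  frequency = c("weekly", "monthly"),
                  outcome_kind = c("proportion", "count", "positive_real")) {
  frequency <- match.arg(frequency)
  outcome_kind <- match.arg(outcome_kind)
  data <- tibble::as_tibble(data)
  if (!"date" %in% names(data)) {
    abort("panel data must contain a `date` column")
  }
  if (!focal %in% names(data)) {
    abort(paste0("focal column `", focal, "` not found in the data"))
  }
  dates <- data$date
  if (is.character(dates)) dates <- as.Date(dates)
  if (!inherits(dates, "Date")) abort("`date` must be Date or ISO-8601 text")
  if (anyNA(dates)) abort("`date` contains unparseable or missing entries")
  if (is.unsorted(dates, strictly = TRUE)) {
    abort("dates must be strictly increasing with no duplicates")
  }
  data$date <- dates
  refs <- setdiff(names(data), c("date", focal))
  for (col in c(focal, refs)) {
    v <- data[[col]]
    if (!is.numeric(v)) abort(paste0("column `", col, "` is not numeric"))
    if (anyNA(v)) {
      abort(paste0("column `", col, "` has missing values (row ",
                   which(is.na(v))[1], ")"))
    }
  }
  check_outcome_values(data, c(focal, refs), outcome_kind)
  structure(data,
            class = c("cf_panel", class(data)),
            focal_col = focal, ref_cols = refs,
            frequency = frequency, outcome_kind = outcome_kind)
}

check_outcome_values <- function(data, cols, outcome_kind) {
  for (col in cols) {
    v <- data[[col]]
    if (outcome_kind == "proportion" && (any(v < 0) || any(v > 1))) {
      abort(paste0("proportion panel: column `", col,
                   "` has values outside [0, 1]"))
    }
    if (outcome_kind == "count" && (any(v < 0) || any(v != round(v)))) {
      abort(paste0("count panel: column `", col,
                   "` has negative or non-integer values"))
    }
    if (outcome_kind == "positive_real" && col == cols[1] && any(v <= 0)) {
      abort(paste0("positive-real panel: focal column `", col,
                   "` has non-positive values"))
    }
  }
  invisible(TRUE)
}

#' @export
print.cf_panel <- function(x, ...) {
  cat("<cf_panel> ", attr(x, "frequency"), " ", attr(x, "outcome_kind"),
      ", focal = `", attr(x, "focal_col"), "`, ",
      length(attr(x, "ref_cols")), " reference series, ",
      nrow(x), " periods\n", sep = "")
  NextMethod()
}

panel_focal <- function(p) p[[attr(p, "focal_col")]]
panel_refs <- function(p) {
  as.matrix(p[, attr(p, "ref_cols"), drop = FALSE])
}
panel_dates <- function(p) p$date

# rebuild a cf_panel from a row subset, keeping metadata
panel_rows <- function(p, idx) {
  out <- tibble::as_tibble(as.data.frame(p))[idx, , drop = FALSE]
  structure(out,
            class = c("cf_panel", class(tibble::tibble())),
            focal_col = attr(p, "focal_col"), ref_cols = attr(p, "ref_cols"),
            frequency = attr(p, "frequency"),
            outcome_kind = attr(p, "outcome_kind"))
}

# replace a column's values without revalidation side effects
panel_set <- function(p, col, values) {
  p[[col]] <- values
  p
}

#' Read an intervention panel from CSV
#'
#' Expects the header `date,focal,<ref_1>,...,<ref_k>` with ISO-8601 dates and
#' one row per period. Missing values are rejected with the offending row
#' number.
#'
#' @param path Path to the CSV file.
#' @inheritParams panel
#' @return A [panel()] tibble.
#' @export
read_panel <- function(path, focal = "focal",
                       frequency = c("weekly", "monthly"),
                       outcome_kind = c("proportion", "count",
                                        "positive_real")) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  panel(raw, focal = focal, frequency = match.arg(frequency),
        outcome_kind = match.arg(outcome_kind))
}

#' Write a panel to CSV
#'
#' @param p A [panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(p, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(p)), path)
  invisible(path)
}

#' Define an intervention study
#'
#' Couples a panel with the calendar date of the intervention (e.g. a movie
#' release). The counterfactual model is fitted to strictly pre-intervention
#' rows; the period containing the intervention date is the first evaluated
#' post-intervention point.
#'
#' @param panel A [panel()].
#' @param intervention_date `Date` (or ISO-8601 string) strictly inside the
#'   panel's time range.
#' @return An object of class `cf_study`.
#' @export
intervention_study <- function(panel, intervention_date) {
  stopifnot(inherits(panel, "cf_panel"))
  if (is.character(intervention_date)) {
    intervention_date <- as.Date(intervention_date)
  }
  dates <- panel_dates(panel)
  if (!(intervention_date > dates[1] &&
        intervention_date <= dates[length(dates)])) {
    abort("intervention_date must lie strictly inside the panel's time range")
  }
  structure(list(panel = panel, intervention_date = intervention_date),
            class = "cf_study")
}

#' @export
print.cf_study <- function(x, ...) {
  sp <- split_pre_post(x)
  cat("<cf_study> intervention at ", format(x$intervention_date), ": ",
      nrow(sp$pre), " pre / ", nrow(sp$post), " post periods\n", sep = "")
  invisible(x)
}

#' Split a study into pre- and post-intervention panels
#'
#' Rows strictly before the intervention date form the fitting (pre) panel;
#' rows on or after it form the evaluation (post) panel. The two parts
#' partition the original panel exactly.
#'
#' @param study A [intervention_study()].
#' @return A list with elements `pre` and `post`, both panels.
#' @export
split_pre_post <- function(study) {
  stopifnot(inherits(study, "cf_study"))
  dates <- panel_dates(study$panel)
  pre_idx <- which(dates < study$intervention_date)
  post_idx <- which(dates >= study$intervention_date)
  if (length(pre_idx) == 0) abort("empty pre-intervention period")
  if (length(post_idx) == 0) abort("empty post-intervention period")
  list(pre = panel_rows(study$panel, pre_idx),
       post = panel_rows(study$panel, post_idx))
}
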