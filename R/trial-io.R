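trial_schema <- function() {
  c("id", "arm", .FACTORS, "stratum",
    paste0("feature_", .FEATURES), "feature_count",
    "page_views", "minutes_on_site", "return_visits", "unenroll_day")
}

#' Write / read a participant-level trial table
#'
#' The on-disk format is a plain UTF-8 CSV with one row per participant and a
#' fixed, documented header (see [trial_schema()] via
#' `mostscreen:::trial_schema`): identifier, arm, the four 0/1 factor
#' columns, stratum, the six feature indicators, feature count, page views,
#' minutes on site, return visits, unenrollment day. `read_trial()` validates
#' the schema and the record invariants (counts nonnegative, indicators
#' binary, `feature_count` equal to the indicator sum, no missing values) and
#' rejects offending files naming the rows.
#'
#' @param trial Participant tibble, e.g. from [simulate_trial()].
#' @param path File path.
#' @return `write_trial()` returns `path` invisibly; `read_trial()` returns
#'   the validated tibble.
#' @export
write_trial <- function(trial, path) {
  validate_trial(trial)
  readr::write_csv(trial[trial_schema()], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  x <- readr::read_csv(
    path, progress = FALSE, show_col_types = FALSE,
    col_types = readr::cols(
      id = readr::col_character(), stratum = readr::col_character(),
      minutes_on_site = readr::col_double(),
      .default = readr::col_integer())
  )
  validate_trial(x)
}

validate_trial <- function(x) {
  sch <- trial_schema()
  missing_cols <- setdiff(sch, names(x))
  if (length(missing_cols)) {
    abort(paste0("trial table is missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  unknown <- setdiff(names(x), sch)
  if (length(unknown)) {
    abort(paste0("trial table has unknown columns: ", paste(unknown, collapse = ", ")))
  }
  if (nrow(x) == 0L) return(tibble::as_tibble(x[sch]))

  fail <- function(what, rows) {
    abort(sprintf("%s (row%s %s)", what, if (length(rows) > 1) "s" else "",
                  paste(head(rows, 5L), collapse = ", ")))
  }
  num <- sch[!sch %in% c("id", "stratum")]
  na_rows <- which(rowSums(is.na(x[num])) > 0 | is.na(x$id) | is.na(x$stratum))
  if (length(na_rows)) fail("missing values are not allowed", na_rows)
  if (any(bad <- !(x$arm %in% 1:16))) fail("`arm` must be in 1..16", which(bad))
  for (f in c(.FACTORS, paste0("feature_", .FEATURES))) {
    if (any(bad <- !(x[[f]] %in% 0:1))) fail(paste0("`", f, "` must be 0/1"), which(bad))
  }
  if (any(bad <- !(x$stratum %in% c("mobile", "desktop")))) {
    fail("`stratum` must be 'mobile' or 'desktop'", which(bad))
  }
  for (f in c("page_views", "minutes_on_site", "return_visits")) {
    if (any(bad <- x[[f]] < 0)) fail(paste0("`", f, "` must be nonnegative"), which(bad))
  }
  cnt <- rowSums(x[paste0("feature_", .FEATURES)])
  if (any(bad <- x$feature_count != cnt)) {
    fail("`feature_count` must equal the sum of the six feature indicators", which(bad))
  }
  exp_arm <- arm_from_levels(x$personalization, x$integration, x$tailoring, x$intensity)
  if (any(bad <- x$arm != exp_arm)) {
    fail("`arm` is inconsistent with the factor level columns", which(bad))
  }
  tibble::as_tibble(x[sch])
}
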