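#' Feature-use count from the six indicators
#'
#' @param x A data frame (or matrix) whose columns are the six 0/1
#'   interactive-feature indicators, or a numeric vector of six values for a
#'   single participant.
#' @return Integer vector of counts in 0..6.
#' @examples
#' feature_count(c(1, 1, 0, 1, 0, 0))  # 3
#' @export
feature_count <- function(x) {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != 6L) abort("exactly six feature indicators are required.")
  if (anyNA(x) || !all(x %in% 0:1)) abort("feature indicators must be 0/1 with no missing values.")
  as.integer(rowSums(x))
}

new_rule <- function(metric, cut, values, target) {
  structure(list(metric = metric, cut_value = cut,
                 direction = ">=",
                 achieved_high_fraction = mean(values >= cut),
                 n_high = sum(values >= cut), n_total = length(values),
                 target_high_fraction = target),
            class = "dichotomization_rule")
}

#' @export
print.dichotomization_rule <- function(x, ...) {
  cat(sprintf("<dichotomization_rule> %s >= %g: %d/%d high (%.1f%%; target %.1f%%)\n",
              x$metric, x$cut_value, x$n_high, x$n_total,
              100 * x$achieved_high_fraction, 100 * x$target_high_fraction))
  invisible(x)
}

#' Dichotomize a skewed engagement metric near a target split
#'
#' Skewed usage metrics (page views, minutes on site, return visits) are
#' converted to high/low indicators at an observed cut point splitting the
#' sample as close as possible to the target high fraction (the study used an
#' approximately 1:2 split, i.e. a target of 1/3 high). Candidate cuts are the
#' observed values; "high" means `value >= cut`; among equidistant candidates
#' the smaller cut wins.
#'
#' @param values Numeric metric vector, nonempty.
#' @param target_high_fraction Desired fraction with `value >= cut`, in (0,1).
#' @param metric Optional metric name recorded in the rule.
#' @return A `dichotomization_rule`: cut value, achieved high fraction,
#'   counts. Re-applying the rule to `values` (see [apply_rule()]) reproduces
#'   `achieved_high_fraction` exactly.
#' @examples
#' pv <- c(rep(10, 586), rep(40, 278))
#' dichotomize(pv, 1/3, "page_views")  # 278/864 = 32.2% high
#' @export
dichotomize <- function(values, target_high_fraction = 1/3, metric = "metric") {
  if (!length(values) || anyNA(values)) abort("`values` must be nonempty with no missing values.")
  if (target_high_fraction <= 0 || target_high_fraction >= 1) {
    abort("`target_high_fraction` must lie strictly in (0, 1).")
  }
  cand <- sort(unique(values))
  if (length(cand) < 2L) {
    abort("constant metric: no cut point can bifurcate the sample.",
          class = "mostscreen_constant_metric")
  }
  frac <- vapply(cand, function(c) mean(values >= c), numeric(1))
  dist <- abs(frac - target_high_fraction)
  best <- cand[which(dist == min(dist))]   # ties -> smaller cut
  new_rule(metric, min(best), values, target_high_fraction)
}

#' Apply a dichotomization rule
#'
#' @param values Numeric vector.
#' @param rule A `dichotomization_rule`.
#' @return Integer 0/1 vector, 1 = high (`value >= cut`).
#' @export
apply_rule <- function(values, rule) {
  stopifnot(inherits(rule, "dichotomization_rule"))
  as.integer(values >= rule$cut_value)
}

# smallest observed value whose cumulative fraction reaches p/100
percentile_cut <- function(values, p) {
  s <- sort(values)
  s[max(1L, ceiling(p / 100 * length(s) - 1e-9))]
}

#' Sensitivity sweep of dichotomization cut points
#'
#' Recomputes the high/low rule at every percentile of the metric between
#' `pct_low` and `pct_high` (the study swept the 55th to 75th percentiles of
#' page views and time on site). Percentiles are mapped to observed values
#' ("nearest observed value at or above the target rank"), so every cut is an
#' attainable threshold of an integer-valued metric.
#'
#' @inheritParams dichotomize
#' @param pct_low,pct_high Percentile range, `0 < pct_low <= pct_high < 100`.
#' @param step Percentile step (default 1).
#' @return A tibble with one row per percentile: `percentile`, `cut_value`
#'   (nondecreasing), `achieved_high_fraction`, `n_high`, `n_total`.
#' @export
sensitivity_sweep <- function(values, pct_low = 55, pct_high = 75, step = 1,
                              metric = "metric") {
  if (!length(values) || anyNA(values)) abort("`values` must be nonempty with no missing values.")
  if (pct_low <= 0 || pct_high >= 100 || pct_low > pct_high) {
    abort("need 0 < pct_low <= pct_high < 100.")
  }
  if (length(unique(values)) < 2L) {
    abort("constant metric: no cut point can bifurcate the sample.",
          class = "mostscreen_constant_metric")
  }
  pcts <- seq(pct_low, pct_high, by = step)
  tibble::tibble(
    metric = metric,
    percentile = pcts,
    cut_value = vapply(pcts, function(p) percentile_cut(values, p), numeric(1))
  ) |>
    dplyr::mutate(
      achieved_high_fraction = vapply(.data$cut_value, function(c) mean(values >= c), numeric(1)),
      n_high = vapply(.data$cut_value, function(c) sum(values >= c), integer(1)),
      n_total = length(values)
    )
}

#' Prepare analysis outcomes from a raw trial table
#'
#' Adds the dichotomized engagement indicators to a participant table:
#' `high_page_views` (>= cut near the 1:2 split), `high_minutes` (same, for
#' minutes on site) and `returned_to_website` (>= 1 postregistration return
#' visit), and validates `feature_count` against the indicators. The fitted
#' rules are attached as the `"dichotomization_rules"` attribute.
#'
#' @param trial Participant tibble (see [simulate_trial()] / [read_trial()]).
#' @param page_views_target,minutes_target Target high fractions.
#' @return The augmented tibble.
#' @export
prepare_outcomes <- function(trial, page_views_target = 1/3, minutes_target = 1/3) {
  trial <- validate_trial(trial)
  r_pv <- dichotomize(trial$page_views, page_views_target, "page_views")
  r_min <- dichotomize(trial$minutes_on_site, minutes_target, "minutes_on_site")
  out <- trial |>
    dplyr::mutate(
      high_page_views = apply_rule(.data$page_views, r_pv),
      high_minutes = apply_rule(.data$minutes_on_site, r_min),
      returned_to_website = as.integer(.data$return_visits >= 1)
    )
  attr(out, "dichotomization_rules") <- list(page_views = r_pv, minutes_on_site = r_min)
  out
}
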