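default_outcomes <- function() {
  c(paste0("feature_", .FEATURES), "feature_count",
    "high_page_views", "high_minutes", "returned_to_website")
}

#' Configure an end-to-end screening analysis
#'
#' Collects every tunable of the pipeline in one validated object; all of
#' them are recorded in the run manifest so a rerun with the same config and
#' seed is byte-identical.
#'
#' @param input Path to a trial CSV ([read_trial()] schema), or `NULL` to
#'   simulate.
#' @param n,scenario,mobile_fraction Simulation settings when `input` is
#'   `NULL`.
#' @param outcomes Outcome columns to analyze (defaults to the six features,
#'   the feature count, and the three dichotomized engagement metrics).
#' @param max_order Interaction order of the inferential model (2 = main
#'   effects + two-way interactions, the a-priori analysis model).
#' @param alpha Two-sided level for the overlap calibration and reporting.
#' @param multiplicity Bonferroni divisor used in reporting thresholds.
#' @param B Bootstrap replicates for marginal-effect intervals (study
#'   default one million; scale down for interactive runs).
#' @param page_views_target,minutes_target Dichotomization targets.
#' @param seed Root seed for simulation and bootstrap streams.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, n = 864, scenario = default_scenario(),
                            mobile_fraction = 0.834,
                            outcomes = default_outcomes(), max_order = 2,
                            alpha = 0.05, multiplicity = 10, B = 1e4,
                            page_views_target = 1/3, minutes_target = 1/3,
                            seed = 1, out_dir = NULL) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (B < 100) abort("`B` must be at least 100.")
  bad <- setdiff(outcomes, default_outcomes())
  if (length(bad)) {
    abort(paste0("unknown outcome column(s) in config: ", paste(bad, collapse = ", ")))
  }
  structure(list(input = input, n = n, scenario = scenario,
                 mobile_fraction = mobile_fraction, outcomes = outcomes,
                 max_order = max_order, alpha = alpha,
                 multiplicity = multiplicity, B = B,
                 page_views_target = page_views_target,
                 minutes_target = minutes_target, seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full screening-analysis pipeline
#'
#' Simulate (or load) the trial, prepare outcomes, fit the order-2 factorial
#' model per outcome for marginal factor effects with bootstrap intervals and
#' SMDs, fit the saturated model for arm summaries at the overlap level,
#' compute pairwise overlap verdicts and the arm ranking, and (optionally)
#' write the report bundle: `trial.csv`, `marginal_effects.csv`,
#' `marginal_table.csv`, `arm_summaries.csv`, `arm_table.csv`,
#' `overlap_verdicts.csv`, `dichotomization_rules.json` and `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a `most_report` list: `trial`, `rules`, `effects`,
#'   `arms` (per-outcome arm summaries), `verdicts`, `ranking`, `manifest`.
#' @examples
#' rep <- run_pipeline(pipeline_config(n = 256, B = 200,
#'                                     outcomes = "feature_set_quit_date"))
#' rep$effects
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  root <- check_seed(config$seed) %% 1000003L

  trial <- stage("input", {
    if (is.null(config$input)) {
      simulate_trial(config$n, config$scenario, config$mobile_fraction,
                     seed = root)
    } else {
      read_trial(config$input)
    }
  })
  prepped <- stage("outcome_prep",
                   prepare_outcomes(trial, config$page_views_target,
                                    config$minutes_target))
  rules <- attr(prepped, "dichotomization_rules")

  gamma <- overlap_level(config$alpha)
  effects <- list(); arms <- list()
  for (i in seq_along(config$outcomes)) {
    oc <- config$outcomes[i]
    fit2 <- stage(paste0("fit:", oc),
                  fit_factorial(prepped, oc, max_order = config$max_order))
    effects[[oc]] <- stage(paste0("effects:", oc),
                           marginal_effects(fit2, B = config$B,
                                            seed = (root + 101L * i) %% .Machine$integer.max))
    fit4 <- stage(paste0("fit_saturated:", oc),
                  fit_factorial(prepped, oc, max_order = length(fit2$factor_cols)))
    arms[[oc]] <- stage(paste0("arms:", oc), arm_means(fit4, level = gamma))
  }
  effects_tbl <- dplyr::bind_rows(effects)
  verdicts <- purrr::map_dfr(names(arms), function(oc) {
    dplyr::mutate(pairwise_overlap(arms[[oc]]), outcome = oc, .before = 1)
  })
  ranking <- purrr::map_dfr(names(arms), function(oc) {
    dplyr::mutate(tibble::as_tibble(rank_arms(arms[[oc]])), outcome = oc, .before = 1)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("mostscreen")),
    seed = config$seed, n = nrow(trial), outcomes = config$outcomes,
    max_order = config$max_order, alpha = config$alpha,
    multiplicity = config$multiplicity,
    alpha_adjusted = adjusted_alpha(config$alpha, config$multiplicity),
    overlap_level = gamma, B = config$B,
    phi_estimator = "pearson",
    bootstrap_quantile_type = 7,
    cut_points = lapply(rules, function(r)
      list(metric = r$metric, cut_value = r$cut_value,
           achieved_high_fraction = r$achieved_high_fraction)),
    simulated = is.null(config$input),
    missing_data = any(is.na(prepped))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    write_trial(trial, p("trial.csv"))
    readr::write_csv(effects_tbl, p("marginal_effects.csv"), progress = FALSE)
    readr::write_csv(render_marginal_table(effects_tbl), p("marginal_table.csv"),
                     progress = FALSE)
    arm_flat <- purrr::map_dfr(names(arms), function(oc) {
      dplyr::mutate(tibble::as_tibble(arms[[oc]]), outcome = oc, .before = 1)
    })
    readr::write_csv(arm_flat, p("arm_summaries.csv"), progress = FALSE)
    readr::write_csv(render_arm_table(arms), p("arm_table.csv"), progress = FALSE)
    readr::write_csv(verdicts, p("overlap_verdicts.csv"), progress = FALSE)
    jsonlite::write_json(manifest$cut_points, p("dichotomization_rules.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE, digits = NA)
  }

  structure(list(trial = trial, rules = rules, effects = effects_tbl,
                 arms = arms, verdicts = verdicts, ranking = ranking,
                 manifest = manifest),
            class = "most_report")
}

#' @export
print.most_report <- function(x, ...) {
  cat(sprintf("<most_report> n=%d participants, %d outcomes, B=%g\n",
              x$manifest$n, length(x$manifest$outcomes), x$manifest$B))
  cat(sprintf("  overlap level gamma: %.4f (alpha %.3g)\n",
              x$manifest$overlap_level, x$manifest$alpha))
  invisible(x)
}

fmt_num <- function(x, digits) formatC(round(x, digits), format = "f", digits = digits)

#' Render the marginal-effects table in report layout
#'
#' One block of four rows per factor — On, Off, Raw difference, SMD — with
#' "estimate (low to high)" cells, one column per outcome. Proportions are
#' shown as percentages to 1 decimal; count means to 2; SMDs to
#' `digits_smd`. Rendered strings parse back to the rounded estimates.
#'
#' @param effects Tibble from [marginal_effects()] rows (possibly several
#'   outcomes bound together); must be complete (every factor x outcome).
#' @param digits_smd Decimals for SMDs (2 matches feature tables, 3 the
#'   engagement-metric table).
#' @return A tibble: `factor`, `quantity`, one column per outcome.
#' @export
render_marginal_table <- function(effects, digits_smd = 2) {
  need <- c("factor", "outcome", "family", "mean_on", "mean_off")
  if (!all(need %in% names(effects))) abort("`effects` is not a marginal-effects table.")
  counts <- dplyr::count(effects, .data$factor, .data$outcome)
  n_f <- dplyr::n_distinct(effects$factor)
  n_o <- dplyr::n_distinct(effects$outcome)
  if (any(counts$n != 1L) || nrow(effects) != n_f * n_o) {
    abort("partial estimate set: every factor must appear exactly once per outcome.")
  }
  cell <- function(est, lo, hi, digits) {
    sprintf("%s (%s to %s)", fmt_num(est, digits), fmt_num(lo, digits), fmt_num(hi, digits))
  }
  long <- effects |>
    dplyr::rowwise() |>
    dplyr::mutate(
      scale = if (.data$family == "binomial") 100 else 1,
      digits = if (.data$family == "binomial") 1 else 2,
      On = cell(.data$mean_on * .data$scale, .data$mean_on_low * .data$scale,
                .data$mean_on_high * .data$scale, .data$digits),
      Off = cell(.data$mean_off * .data$scale, .data$mean_off_low * .data$scale,
                 .data$mean_off_high * .data$scale, .data$digits),
      `Raw difference` = cell(.data$raw_difference * .data$scale,
                              .data$raw_difference_low * .data$scale,
                              .data$raw_difference_high * .data$scale, .data$digits),
      SMD = cell(.data$smd, .data$smd_low, .data$smd_high, digits_smd)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("factor", "outcome", "On", "Off", "Raw difference", "SMD") |>
    tidyr::pivot_longer(c("On", "Off", "Raw difference", "SMD"),
                        names_to = "quantity", values_to = "cell") |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "cell")
  long$quantity <- factor(long$quantity, levels = c("On", "Off", "Raw difference", "SMD"))
  dplyr::arrange(long, .data$factor, .data$quantity) |>
    dplyr::mutate(quantity = as.character(.data$quantity))
}

#' Render arm summaries in report layout
#'
#' One row per arm with its +/- factor pattern and an "estimate (low-high)"
#' cell per outcome (percentages for binary outcomes, means for counts).
#'
#' @param arms Named list of `arm_summary` tibbles (one per outcome), as in
#'   the `arms` element of a [run_pipeline()] report, or a single summary.
#' @return A tibble: `arm`, `P`, `IG`, `T`, `IS`, one column per outcome.
#' @export
render_arm_table <- function(arms) {
  if (inherits(arms, "arm_summary")) {
    arms <- setNames(list(arms), attr(arms, "outcome"))
  }
  if (!length(arms) || !all(vapply(arms, inherits, logical(1), "arm_summary"))) {
    abort("`arms` must be arm_summary tibbles from arm_means().")
  }
  base <- tibble::tibble(
    arm = 1:16,
    P = substr(arm_pattern(1:16), 1, 1), IG = substr(arm_pattern(1:16), 2, 2),
    T = substr(arm_pattern(1:16), 3, 3), IS = substr(arm_pattern(1:16), 4, 4)
  )
  for (oc in names(arms)) {
    s <- arms[[oc]]
    binom <- attr(s, "family") == "binomial"
    scale <- if (binom) 100 else 1
    digits <- if (binom) 0 else 2
    ord <- match(1:16, s$arm)
    base[[oc]] <- sprintf("%s (%s-%s)",
                          fmt_num(s$estimate[ord] * scale, digits),
                          fmt_num(s$ci_low[ord] * scale, digits),
                          fmt_num(s$ci_high[ord] * scale, digits))
  }
  base
}
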