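#' Confidence level for the pairwise overlap rule
#'
#' For two independent estimates with (approximately) equal standard errors,
#' non-overlap of individual confidence intervals at level
#' `gamma = 2 * Phi(z_{1-alpha/2} / sqrt(2)) - 1` is equivalent to a
#' two-sample z-test rejecting at two-sided level `alpha`. At `alpha = 0.05`
#' this gives `gamma = 0.8342` ("about 83.5%" under normality).
#'
#' @param alpha Two-sided test level in (0, 1).
#' @return The reduced confidence level gamma.
#' @examples
#' overlap_level(0.05)  # 0.8342
#' @export
overlap_level <- function(alpha) {
  if (!is.numeric(alpha) || any(alpha <= 0 | alpha >= 1)) {
    abort("`alpha` must lie strictly in (0, 1).")
  }
  2 * pnorm(qnorm(1 - alpha / 2) / sqrt(2)) - 1
}

#' Model-based arm means with back-transformed confidence intervals
#'
#' Requires the saturated (order-4) fit, whose fitted arm means equal the
#' observed cell statistics. Intervals are computed on the linear-predictor
#' scale (`eta +/- z_{(1+gamma)/2} * SE`, quasi-Poisson SEs phi-scaled) and
#' back-transformed, so back-transformed proportions always stay inside
#' \[0, 1\]. Degenerate binomial cells (0 or all events) get a continuity
#' adjustment (half an event/non-event added) for the interval display only;
#' the point estimate is untouched and the arm is flagged.
#'
#' @param fit A saturated (`max_order = 4`) [fit_factorial()] result whose
#'   data carried an `arm` column.
#' @param level Confidence level gamma (use [overlap_level()] for
#'   overlap-rule comparisons; 0.95 for reporting).
#' @return A tibble of class `arm_summary` with one row per arm: `arm`,
#'   `pattern` (+/- string in P, IG, T, IS order), the four factor columns,
#'   `n`, `estimate`, `ci_low`, `ci_high`, `degenerate`; attributes `level`,
#'   `outcome`, `family`, `dispersion`.
#' @examples
#' tr <- simulate_trial(864, seed = 3)
#' fit <- fit_factorial(tr, "feature_track_triggers", max_order = 4)
#' arm_means(fit, level = overlap_level(0.05))
#' @export
arm_means <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "factorial_fit"))
  if (fit$max_order != length(fit$factor_cols)) {
    abort("arm summaries need the saturated model: refit with `max_order = 4`.")
  }
  if (level <= 0 || level >= 1) abort("`level` must lie strictly in (0, 1).")
  if (is.null(fit$arm)) abort("the fitted data carried no `arm` column.")

  lv <- levels_from_arm(1:16)
  Xa <- build_design(lv, fit$max_order, fit$factor_cols)
  if (fit$stratum_adjust) {
    abort("arm summaries are defined for unadjusted saturated fits.")
  }
  eta <- as.numeric(Xa %*% fit$coefficients)
  se <- sqrt(rowSums((Xa %*% fit$vcov) * Xa))
  z <- qnorm((1 + level) / 2)
  inv <- linkinv_fun(fit)

  n_arm <- as.integer(tabulate(fit$arm, 16))
  est <- inv(eta)
  lo <- inv(eta - z * se)
  hi <- inv(eta + z * se)
  degenerate <- rep(FALSE, 16)

  if (fit$family == "binomial") {
    events <- vapply(1:16, function(a) sum(fit$y[fit$arm == a]), numeric(1))
    degen <- events == 0 | events == n_arm
    if (any(degen)) {
      x_adj <- events + 0.5
      n_adj <- n_arm + 1
      eta_adj <- qlogis(x_adj / n_adj)
      se_adj <- sqrt(1 / x_adj + 1 / (n_adj - x_adj))
      lo[degen] <- plogis(eta_adj[degen] - z * se_adj[degen])
      hi[degen] <- plogis(eta_adj[degen] + z * se_adj[degen])
      degenerate <- degen
    }
  } else {
    cell_tot <- vapply(1:16, function(a) sum(fit$y[fit$arm == a]), numeric(1))
    degen <- cell_tot == 0
    if (any(degen)) {
      mu_adj <- (cell_tot + 0.5) / n_arm
      se_adj <- sqrt(fit$dispersion / (n_arm * mu_adj))
      lo[degen] <- exp(log(mu_adj[degen]) - z * se_adj[degen])
      hi[degen] <- exp(log(mu_adj[degen]) + z * se_adj[degen])
      degenerate <- degen
    }
  }

  out <- dplyr::bind_cols(
    tibble::tibble(arm = 1:16, pattern = arm_pattern(1:16)), lv,
    tibble::tibble(n = n_arm, estimate = est, ci_low = lo, ci_high = hi,
                   degenerate = degenerate)
  )
  class(out) <- c("arm_summary", class(out))
  attr(out, "level") <- level
  attr(out, "outcome") <- fit$outcome
  attr(out, "family") <- fit$family
  attr(out, "dispersion") <- fit$dispersion
  out
}

#' Pairwise overlap verdicts for the 16 arms
#'
#' Applies the overlap rule to every one of the 120 arm pairs: a pair is
#' declared significantly different at the test level used to construct
#' `gamma` (via [overlap_level()]) exactly when its intervals fail to
#' overlap.
#'
#' @param summaries An `arm_summary` tibble from [arm_means()]; all rows must
#'   share one confidence level.
#' @return A tibble with one row per unordered pair: `arm_a`, `arm_b`,
#'   `overlap`, `significant` (`= !overlap`).
#' @export
pairwise_overlap <- function(summaries) {
  stopifnot(inherits(summaries, "arm_summary"))
  if (is.null(attr(summaries, "level"))) {
    abort("summaries carry no common confidence level; rebuild with arm_means().")
  }
  pairs <- t(combn(summaries$arm, 2L))
  i <- match(pairs[, 1], summaries$arm)
  j <- match(pairs[, 2], summaries$arm)
  ov <- summaries$ci_low[i] <= summaries$ci_high[j] &
        summaries$ci_low[j] <= summaries$ci_high[i]
  tibble::tibble(arm_a = pairs[, 1], arm_b = pairs[, 2],
                 overlap = ov, significant = !ov)
}

#' Rank arms and identify the top set
#'
#' Orders arms by their model-based estimate (best first) and marks the "top
#' set": the arms whose interval overlaps the best arm's interval, i.e. the
#' arms not significantly different from the top-ranked arm under the overlap
#' rule.
#'
#' @param summaries An `arm_summary` tibble from [arm_means()].
#' @return The summaries, sorted, with `rank` and `in_top_set` columns.
#' @export
rank_arms <- function(summaries) {
  stopifnot(inherits(summaries, "arm_summary"))
  out <- dplyr::arrange(tibble::as_tibble(summaries), dplyr::desc(.data$estimate))
  out$rank <- seq_len(nrow(out))
  best <- out[1, ]
  out$in_top_set <- out$ci_low <= best$ci_high & best$ci_low <= out$ci_high
  for (a in c("level", "outcome", "family", "dispersion")) {
    attr(out, a) <- attr(summaries, a)
  }
  class(out) <- c("arm_summary", class(out))
  out
}

#' Standardized mean difference between two arms
#'
#' Applies the binary or dispersion-scaled count SMD formula (per the
#' summaries' family) to two arm estimates — e.g. arms 16 vs 1 for the full
#' on-vs-off impact of the intervention.
#'
#' @param summaries An `arm_summary` tibble.
#' @param arm_a,arm_b Arm ids; the SMD is `arm_a` minus `arm_b` (swapping
#'   the arms flips the sign).
#' @param phi Dispersion for the count formula; defaults to the fit's.
#' @return A single SMD.
#' @examples
#' # full-impact contrast: arm_contrast_smd(summ, 16, 1)
#' @export
arm_contrast_smd <- function(summaries, arm_a = 16, arm_b = 1, phi = NULL) {
  stopifnot(inherits(summaries, "arm_summary"))
  fam <- attr(summaries, "family")
  ea <- summaries$estimate[match(arm_a, summaries$arm)]
  eb <- summaries$estimate[match(arm_b, summaries$arm)]
  if (anyNA(c(ea, eb))) abort("arm id not present in the summaries.")
  if (fam == "binomial") {
    smd_binary(ea, eb)
  } else {
    smd_count(ea, eb, phi %||% attr(summaries, "dispersion"))
  }
}
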