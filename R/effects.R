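#' Standardized mean difference for binary outcomes
#'
#' `d = (p1 - p2) / sqrt(p1*q1 + p2*q2)` with `q = 1 - p`: the mean
#' difference scaled by the square root of the summed Bernoulli variances of
#' the two groups. Antisymmetric in its arguments; zero when the proportions
#' agree. Boundary proportions (0 or 1) are rejected because the denominator
#' degenerates.
#'
#' @param p1,p2 Proportions strictly in (0, 1); vectorized.
#' @return The standardized mean difference.
#' @examples
#' smd_binary(0.466, 0.279)  # ~0.28
#' @export
smd_binary <- function(p1, p2) {
  if (any(!is.finite(p1)) || any(!is.finite(p2)) ||
      any(p1 <= 0 | p1 >= 1) || any(p2 <= 0 | p2 >= 1)) {
    abort("proportions must lie strictly in (0, 1): the variance term degenerates at the boundary.",
          class = "mostscreen_degenerate_proportion")
  }
  (p1 - p2) / sqrt(p1 * (1 - p1) + p2 * (1 - p2))
}

#' Standardized mean difference for count outcomes
#'
#' `d = (mu1 - mu2) / sqrt(phi * (mu1 + mu2))`: the quasi-Poisson analogue,
#' with the variance of each group taken as `phi * mean`.
#'
#' @param mu1,mu2 Group means, nonnegative and not both zero; vectorized.
#' @param phi Dispersion parameter, > 0.
#' @return The standardized mean difference.
#' @examples
#' smd_count(2.59, 2.22, 1)  # ~0.169
#' @export
smd_count <- function(mu1, mu2, phi = 1) {
  if (any(!is.finite(mu1)) || any(!is.finite(mu2)) || any(mu1 < 0) || any(mu2 < 0)) {
    abort("count means must be finite and nonnegative.")
  }
  if (any(mu1 + mu2 == 0)) {
    abort("both means are zero: the variance term degenerates.",
          class = "mostscreen_degenerate_proportion")
  }
  if (any(phi <= 0)) abort("`phi` must be positive.")
  (mu1 - mu2) / sqrt(phi * (mu1 + mu2))
}

# collapse the stored design to unique rows + weights, with the named factor
# forced to `value`; returns list(X = unique design rows, w = weights)
forced_design <- function(fit, factor, value) {
  fac <- fit$factors
  fac[[factor]] <- value
  X <- build_design(fac, fit$max_order, fit$factor_cols)
  if (fit$stratum_adjust) {
    X <- cbind(X, stratum_mobile = fit$X[, "stratum_mobile"])
  }
  key <- apply(X, 1L, paste, collapse = ",")
  first <- !duplicated(key)
  list(X = X[first, , drop = FALSE], w = as.vector(table(key)[key[first]]) / nrow(X))
}

mean_response <- function(fit, X, w, beta = fit$coefficients) {
  inv <- linkinv_fun(fit)
  as.numeric(w %*% inv(X %*% beta))
}

#' Marginal on/off means for one factor
#'
#' G-computation (marginal standardization): predict every participant's
#' outcome with the factor forced on, average; repeat with it forced off. In
#' a balanced design with the saturated model these equal the raw subgroup
#' means.
#'
#' @param fit A [fit_factorial()] result.
#' @param factor Factor name present in the design.
#' @return A one-row tibble: `factor`, `outcome`, `mean_on`, `mean_off`
#'   (response scale: proportions for binary outcomes, means for counts).
#' @export
marginal_means <- function(fit, factor) {
  stopifnot(inherits(fit, "factorial_fit"))
  if (!factor %in% fit$factor_cols) {
    abort(paste0("factor `", factor, "` is not in the design."))
  }
  on <- forced_design(fit, factor, 1L)
  off <- forced_design(fit, factor, 0L)
  tibble::tibble(
    factor = factor, outcome = fit$outcome,
    mean_on = mean_response(fit, on$X, on$w),
    mean_off = mean_response(fit, off$X, off$w)
  )
}

draw_betas <- function(fit, B) {
  m <- MASS::mvrnorm(B, fit$coefficients, fit$vcov)
  if (!is.matrix(m)) m <- matrix(m, nrow = B, byrow = TRUE)
  m
}

#' Parametric percentile bootstrap interval for a model functional
#'
#' Draws `B` coefficient vectors from the asymptotic multivariate normal of
#' the estimates, `MVN(beta_hat, Sigma_hat)`, evaluates the functional on
#' each draw, and returns empirical percentiles of the resulting sample.
#' Draws on which the functional is undefined (non-finite, e.g. an SMD whose
#' proportion hits a boundary) are rejected and redrawn; more than 1%
#' rejections raises a warning.
#'
#' @param fit A `factorial_fit` (its covariance must be positive
#'   semidefinite, as returned by [fit_factorial()]).
#' @param functional Function of a coefficient vector returning a scalar, or
#'   of a `B x p` coefficient matrix returning a length-`B` vector (detected
#'   automatically).
#' @param B Number of replicates (study default: one million; use
#'   1e3-1e4 in interactive work and tests).
#' @param level Confidence level in `[0, 1)`; `level = 0` degenerates to the
#'   median draw.
#' @param seed Optional integer seed.
#' @return A list: `point` (functional at the estimates), `ci_low`,
#'   `ci_high`, `level`, `B`, `rejected`.
#' @export
parametric_bootstrap_ci <- function(fit, functional, B = 1e6, level = 0.95,
                                    seed = NULL) {
  stopifnot(inherits(fit, "factorial_fit"))
  if (B < 100) abort("`B` must be at least 100.")
  if (level < 0 || level >= 1) abort("`level` must lie in [0, 1).")
  if (!is.null(seed)) withr::local_seed(check_seed(seed))

  eval_fn <- function(betas) {
    out <- tryCatch(functional(betas), error = function(e) NULL)
    if (!is.null(out) && length(out) == nrow(betas)) return(as.numeric(out))
    apply(betas, 1L, function(b) {
      tryCatch(as.numeric(functional(b)), error = function(e) NA_real_)
    })
  }

  betas <- draw_betas(fit, B)
  vals <- eval_fn(betas)
  rejected <- 0L
  tries <- 0L
  while (anyNA(vals <- replace(vals, !is.finite(vals), NA_real_)) && tries < 50L) {
    bad <- which(is.na(vals))
    rejected <- rejected + length(bad)
    redraw <- draw_betas(fit, length(bad))
    vals[bad] <- eval_fn(redraw)
    tries <- tries + 1L
  }
  if (anyNA(vals)) abort("functional undefined on persistent fraction of bootstrap draws.")
  if (rejected > 0.01 * B) {
    warn(sprintf("%d of %d bootstrap draws rejected (> 1%%); interpret the interval cautiously.", rejected, B))
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- unname(quantile(vals, probs, type = 7))
  list(point = as.numeric(eval_fn(matrix(fit$coefficients, nrow = 1))),
       ci_low = qs[1], ci_high = qs[2], level = level, B = B, rejected = rejected)
}

# vectorized on/off mean draws for one factor: returns list of length-B vectors
boot_margins <- function(fit, factor, betas) {
  on <- forced_design(fit, factor, 1L)
  off <- forced_design(fit, factor, 0L)
  inv <- linkinv_fun(fit)
  list(on = as.numeric(on$w %*% inv(on$X %*% t(betas))),
       off = as.numeric(off$w %*% inv(off$X %*% t(betas))))
}

#' Marginal factor effects with bootstrap confidence intervals
#'
#' For each factor: marginal on/off means by standardization, the raw
#' difference, and the standardized mean difference (binary or
#' dispersion-scaled count formula, per the fit's family), each with a
#' parametric percentile bootstrap interval. The count-SMD dispersion phi is
#' held at its estimate across draws.
#'
#' @param fit A [fit_factorial()] result.
#' @param factors Factors to summarize (default: all in the design).
#' @param B Bootstrap replicates (study default one million).
#' @param level Confidence level.
#' @param seed Optional integer seed.
#' @return A tibble, one row per factor: means with intervals, raw
#'   difference (`raw_difference`, proportions on the 0-1 scale), `smd`, and
#'   interval bounds `*_low`/`*_high`, plus `B` and `level`.
#' @examples
#' tr <- simulate_trial(256, seed = 2)
#' fit <- fit_factorial(tr, "feature_choose_aid")
#' marginal_effects(fit, B = 500, seed = 9)
#' @export
marginal_effects <- function(fit, factors = fit$factor_cols, B = 1e6,
                             level = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "factorial_fit"))
  if (B < 100) abort("`B` must be at least 100.")
  if (!is.null(seed)) withr::local_seed(check_seed(seed))
  bad <- setdiff(factors, fit$factor_cols)
  if (length(bad)) abort(paste0("factor(s) not in design: ", paste(bad, collapse = ", ")))

  smd_fun <- if (fit$family == "binomial") {
    function(m1, m0) smd_binary(pmin(pmax(m1, 1e-12), 1 - 1e-12),
                                pmin(pmax(m0, 1e-12), 1 - 1e-12))
  } else {
    function(m1, m0) smd_count(m1, m0, fit$dispersion)
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  betas <- draw_betas(fit, B)

  purrr::map_dfr(factors, function(f) {
    mm <- marginal_means(fit, f)
    bm <- boot_margins(fit, f, betas)
    q <- function(v) unname(quantile(v, probs, type = 7))
    ci_on <- q(bm$on); ci_off <- q(bm$off)
    ci_rd <- q(bm$on - bm$off); ci_smd <- q(smd_fun(bm$on, bm$off))
    tibble::tibble(
      factor = f, outcome = fit$outcome, family = fit$family,
      mean_on = mm$mean_on, mean_on_low = ci_on[1], mean_on_high = ci_on[2],
      mean_off = mm$mean_off, mean_off_low = ci_off[1], mean_off_high = ci_off[2],
      raw_difference = mm$mean_on - mm$mean_off,
      raw_difference_low = ci_rd[1], raw_difference_high = ci_rd[2],
      smd = smd_fun(mm$mean_on, mm$mean_off),
      smd_low = ci_smd[1], smd_high = ci_smd[2],
      dispersion = fit$dispersion, B = B, level = level
    )
  })
}
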