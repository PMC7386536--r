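#' Specify a 2^k factorial screening design for planning
#'
#' Holds the quantities entering the normal-approximation power calculation:
#' total sample size, number of binary factors, the unadjusted two-sided
#' significance level, the number of tested effects (Bonferroni multiplicity,
#' e.g. 4 main effects + 6 two-way interactions = 10), the target power, and
#' which contrast is planned for (`"main"`: two groups of `n_total/2`;
#' `"two_way"`: the four-cell interaction contrast, whose standard error is
#' twice the main-effect one in a balanced design).
#'
#' @param n_total Total number of participants.
#' @param k Number of binary factors (default 4).
#' @param alpha Two-sided significance level before multiplicity adjustment.
#' @param multiplicity Number of tested effects dividing alpha (Bonferroni).
#' @param power Target power in (0, 1).
#' @param contrast_order `"main"` or `"two_way"`.
#' @return A `design_spec` object.
#' @examples
#' spec <- design_spec(864, alpha = 0.05, multiplicity = 10)
#' detectable_effect(spec)                          # ~ 0.25
#' detectable_effect(design_spec(864, alpha = 0.05, multiplicity = 10,
#'                               contrast_order = "two_way"))  # ~ 0.50
#' @export
design_spec <- function(n_total, k = 4, alpha = 0.05, multiplicity = 10,
                        power = 0.80, contrast_order = c("main", "two_way")) {
  contrast_order <- match.arg(contrast_order)
  if (!is.numeric(n_total) || n_total < 2) abort("`n_total` must be at least 2.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (power <= 0 || power >= 1) abort("`power` must lie in (0, 1).")
  if (multiplicity < 1) abort("`multiplicity` must be >= 1.")
  if (k < 1) abort("`k` must be >= 1.")
  structure(list(n_total = n_total, k = k, alpha = alpha,
                 multiplicity = multiplicity, power = power,
                 contrast_order = contrast_order),
            class = "design_spec")
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha Two-sided level.
#' @param multiplicity Number of tested effects.
#' @return `alpha / multiplicity`.
#' @examples
#' adjusted_alpha(0.05, 10)  # 0.005
#' @export
adjusted_alpha <- function(alpha, multiplicity) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (!is.numeric(multiplicity) || multiplicity < 1) {
    abort("`multiplicity` must be a count >= 1 (0 is not a valid divisor).")
  }
  alpha / multiplicity
}

# standard error of the standardized contrast (unit outcome SD)
contrast_se <- function(spec) {
  se_main <- 2 / sqrt(spec$n_total)        # sqrt(1/(n/2) + 1/(n/2))
  switch(spec$contrast_order, main = se_main, two_way = 2 * se_main)
}

#' Minimum detectable standardized effect
#'
#' Normal-approximation minimum detectable standardized contrast for a
#' balanced factorial design at the Bonferroni-adjusted level:
#' `d = (z_{1-alpha'/2} + z_{power}) * SE`, where the standardized SE is
#' `2/sqrt(n_total)` for a main effect and twice that for a two-way
#' interaction contrast.
#'
#' @param spec A [design_spec()].
#' @return The minimum detectable standardized mean difference.
#' @export
detectable_effect <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  a <- adjusted_alpha(spec$alpha, spec$multiplicity)
  zs <- qnorm(1 - a / 2) + qnorm(spec$power)
  if (zs <= 0) abort("alpha/power combination yields a nonpositive quantile sum.")
  zs * contrast_se(spec)
}

#' Power for a given standardized effect
#'
#' Two-sided normal-approximation power for the planned contrast; exact
#' inverse of [detectable_effect()] up to the negligible opposite-tail term.
#'
#' @param spec A [design_spec()].
#' @param d Standardized effect size, > 0.
#' @return Probability of rejection.
#' @examples
#' power_for_effect(design_spec(864, alpha = 0.005, multiplicity = 1), 0.25)  # ~0.807
#' @export
power_for_effect <- function(spec, d) {
  stopifnot(inherits(spec, "design_spec"))
  if (!is.numeric(d) || any(d <= 0)) abort("`d` must be positive.")
  a <- adjusted_alpha(spec$alpha, spec$multiplicity)
  za <- qnorm(1 - a / 2)
  se <- contrast_se(spec)
  pnorm(d / se - za) + pnorm(-d / se - za)
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "<design_spec> 2^%d factorial, n=%d, alpha=%.4g/%d, power=%.2f, %s contrast\n",
    x$k, x$n_total, x$alpha, x$multiplicity, x$power, x$contrast_order))
  cat(sprintf("  minimum detectable d: %.4f\n", detectable_effect(x)))
  invisible(x)
}
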