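#' Build the factorial model matrix
#'
#' Intercept plus all products of the 0/1 factor indicators up to
#' `max_order`. Column order is deterministic: main effects alphabetically,
#' then interactions of increasing order, lexicographic within order
#' (`a:b` naming). Order 2 with 4 factors gives 1 + 4 + 6 = 11 columns;
#' order 4 is saturated (16 columns).
#'
#' @param factors Data frame holding the 0/1 factor columns.
#' @param max_order Highest interaction order kept (1..number of factors).
#' @param factor_cols Names of the factor columns (default the four
#'   experimental factors).
#' @return Numeric matrix with named columns, one row per participant.
#' @export
build_design <- function(factors, max_order = 2, factor_cols = most_factors()) {
  missing_cols <- setdiff(factor_cols, names(factors))
  if (length(missing_cols)) {
    abort(paste0("missing factor columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (max_order < 1 || max_order > length(factor_cols)) {
    abort("`max_order` must be between 1 and the number of factors.")
  }
  for (f in factor_cols) {
    if (anyNA(factors[[f]]) || !all(factors[[f]] %in% 0:1)) {
      abort(paste0("factor column `", f, "` must be 0/1 with no missing values."))
    }
  }
  fc <- sort(factor_cols)
  n <- nrow(factors)
  cols <- list("(Intercept)" = rep(1, n))
  for (ord in seq_len(max_order)) {
    cmb <- combn(fc, ord)
    for (idx in seq_len(ncol(cmb))) {
      sel <- cmb[, idx]
      cols[[paste(sel, collapse = ":")]] <-
        Reduce(`*`, lapply(sel, function(f) as.numeric(factors[[f]])))
    }
  }
  do.call(cbind, cols)
}

#' Fit a full-factorial generalized linear model
#'
#' Fits the factorial model for one engagement outcome via [stats::glm()]
#' (iteratively reweighted least squares): logistic regression for binary
#' outcomes, quasi-Poisson (log link) for the feature-use count, with the
#' scale parameter phi estimated from the Pearson chi-square. Order 2 is the
#' inferential model (4 main effects + 6 two-way interactions, higher orders
#' excluded a priori); order 4 is the saturated model used for arm-level
#' summaries.
#'
#' @param data Participant tibble containing the outcome and factor columns.
#' @param outcome Name of the outcome column.
#' @param family `"binomial"` (logit) or `"quasipoisson"` (log); `"auto"`
#'   picks quasi-Poisson for `feature_count` and binomial otherwise.
#' @inheritParams build_design
#' @param stratum_adjust Add the enrollment-device stratum as an extra
#'   main-effect column (off by default).
#' @return A `factorial_fit`: coefficients, covariance (phi-scaled for
#'   quasi-Poisson), dispersion, family, design metadata, and the underlying
#'   `glm` object. Methods: [tidy.factorial_fit()], [glance.factorial_fit()].
#' @examples
#' tr <- simulate_trial(256, seed = 1)
#' fit <- fit_factorial(tr, "feature_set_quit_date", max_order = 2)
#' glance(fit)
#' @export
fit_factorial <- function(data, outcome, family = c("auto", "binomial", "quasipoisson"),
                          max_order = 2, factor_cols = most_factors(),
                          stratum_adjust = FALSE) {
  family <- match.arg(family)
  if (!outcome %in% names(data)) abort(paste0("outcome column `", outcome, "` not found."))
  y <- data[[outcome]]
  if (anyNA(y)) abort("the outcome contains missing values.")
  if (family == "auto") {
    family <- if (identical(outcome, "feature_count")) "quasipoisson" else "binomial"
  }
  if (family == "binomial" && !all(y %in% 0:1)) {
    abort("binomial outcomes must be 0/1.")
  }
  if (family == "quasipoisson" && (any(y < 0) || any(y != round(y)))) {
    abort("count outcomes must be nonnegative integers.")
  }

  X <- build_design(data, max_order, factor_cols)
  if (stratum_adjust) {
    if (!"stratum" %in% names(data)) abort("`stratum` column required for stratum_adjust.")
    X <- cbind(X, stratum_mobile = as.numeric(data$stratum == "mobile"))
  }
  fam <- if (family == "binomial") binomial() else quasipoisson()
  df <- data.frame(.y = y, X[, -1, drop = FALSE], check.names = FALSE)
  mod <- glm(.y ~ ., data = df, family = fam,
             control = list(epsilon = 1e-8, maxit = 100))

  cf <- coef(mod)
  if (anyNA(cf)) {
    abort(paste0("rank-deficient design; collinear terms: ",
                 paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  separation <- family == "binomial" &&
    any(fitted(mod) < 1e-8 | fitted(mod) > 1 - 1e-8) &&
    max(abs(cf)) > 10
  if (separation) {
    warn("possible separation: some fitted probabilities are numerically 0/1 and coefficients are extreme; estimates flagged.")
  }
  phi <- if (family == "binomial") 1 else
    sum(residuals(mod, type = "pearson")^2) / df.residual(mod)

  names(cf) <- colnames(X)
  V <- vcov(mod)
  dimnames(V) <- list(colnames(X), colnames(X))

  structure(list(
    coefficients = cf, vcov = V, dispersion = phi,
    family = family, outcome = outcome, max_order = max_order,
    factor_cols = factor_cols, stratum_adjust = stratum_adjust,
    n = nrow(X), converged = mod$converged, separation = separation,
    X = X, y = y, arm = if ("arm" %in% names(data)) data$arm else NULL,
    factors = data[factor_cols], model = mod
  ), class = "factorial_fit")
}

linkinv_fun <- function(fit) {
  if (fit$family == "binomial") plogis else exp
}

#' @export
print.factorial_fit <- function(x, ...) {
  cat(sprintf("<factorial_fit> %s ~ %s factorial (order %d), n=%d\n",
              x$outcome,
              if (x$family == "binomial") "logistic" else "quasi-Poisson",
              x$max_order, x$n))
  cat(sprintf("  dispersion phi: %.3f%s\n", x$dispersion,
              if (x$family == "binomial") " (fixed)" else " (Pearson)"))
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  if (x$separation) cat("  WARNING: possible separation\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Tidy a factorial fit
#'
#' @param x A `factorial_fit`.
#' @param conf_level Wald confidence level for the coefficient intervals.
#' @param ... Unused.
#' @return A tibble with one row per model term: estimate, standard error,
#'   z statistic, p value, Wald interval.
#' @export
#' @method tidy factorial_fit
tidy.factorial_fit <- function(x, conf_level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  q <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std_error = unname(se),
    statistic = unname(z),
    p_value = 2 * pnorm(-abs(z)),
    conf_low = unname(x$coefficients - q * se),
    conf_high = unname(x$coefficients + q * se)
  )
}

#' Glance at a factorial fit
#'
#' @param x A `factorial_fit`.
#' @param ... Unused.
#' @return One-row tibble: outcome, family, order, n, dispersion, residual
#'   deviance and df, convergence and separation flags.
#' @export
#' @method glance factorial_fit
glance.factorial_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, family = x$family, max_order = x$max_order,
    n = x$n, dispersion = x$dispersion,
    deviance = x$model$deviance, df_residual = df.residual(x$model),
    converged = x$converged, separation = x$separation
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
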