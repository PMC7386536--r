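#' Assign participants to the 16 arms by stratified permuted blocks
#'
#' Enrollment device (mobile vs desktop) is drawn per participant, then arms
#' are assigned within each stratum by permuted blocks of size 16. The final,
#' possibly incomplete block of the second stratum is completed against the
#' running overall arm totals, so arm counts differ by at most one within each
#' stratum and, when `n` is a multiple of 16, are exactly `n/16` overall.
#'
#' @param n Number of participants; at least 16.
#' @param mobile_fraction Probability of enrolling on a mobile device
#'   (default 0.834, the observed 721/864).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with one row per participant: `id`, `arm` (1..16, arm 1 =
#'   all factors off, arm 16 = all on), the four 0/1 factor columns
#'   (`personalization`, `integration`, `tailoring`, `intensity`; intensity
#'   1 = tapered, 0 = abrupt), and `stratum` ("mobile"/"desktop").
#' @examples
#' asg <- assign_arms(864, seed = 1)
#' table(asg$arm)          # 54 each
#' @export
assign_arms <- function(n, mobile_fraction = 0.834, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 16) {
    abort("`n` must be a single number >= 16 (one full block of the 16 arms).")
  }
  n <- as.integer(n)
  if (!is.numeric(mobile_fraction) || mobile_fraction <= 0 || mobile_fraction >= 1) {
    abort("`mobile_fraction` must lie strictly in (0, 1).")
  }
  if (!is.null(seed)) withr::local_seed(check_seed(seed))

  stratum <- ifelse(rbinom(n, 1L, mobile_fraction) == 1L, "mobile", "desktop")
  arm <- integer(n)
  totals <- integer(16)  # overall arm counts so far

  for (s in c("mobile", "desktop")) {
    idx <- which(stratum == s)
    ns <- length(idx)
    if (ns == 0L) next
    n_full <- ns %/% 16L
    blocks <- if (n_full > 0L) {
      unlist(lapply(seq_len(n_full), function(i) sample.int(16L)))
    } else integer(0)
    r <- ns - 16L * n_full
    if (r > 0L) {
      # partial block: favour arms with the lowest overall totals so far,
      # random tie-break -- completes the previous stratum's partial block
      cur <- totals + tabulate(blocks, 16L)
      ord <- order(cur, sample.int(16L))
      blocks <- c(blocks, ord[seq_len(r)])
    }
    arm[idx] <- blocks
    totals <- totals + tabulate(blocks, 16L)
  }

  dplyr::bind_cols(
    tibble::tibble(id = sprintf("P%04d", seq_len(n)), arm = arm),
    levels_from_arm(arm)
  ) |>
    dplyr::mutate(stratum = stratum)
}

# calibrate the intercept a so E[plogis(a + lam*Z)] = p, Z ~ N(0,1)
calibrate_logit_intercept <- function(p, lam) {
  if (lam == 0) return(qlogis(p))
  marg <- function(a) {
    stats::integrate(function(z) plogis(a + lam * z) * stats::dnorm(z),
                     -Inf, Inf)$value - p
  }
  stats::uniroot(marg, c(-25, 25), tol = 1e-10)$root
}

#' Simulate engagement outcomes for assigned participants
#'
#' Given arm assignments and an [default_scenario()]-style scenario, draws the
#' six binary feature indicators (with a shared latent propensity inducing
#' their correlation), the feature-use count, negative-binomial page views and
#' return visits, log-normal minutes on site, and a descriptive unenrollment
#' day. Factor effects shift the linear predictor (logit for features, log
#' for the skewed metrics); per-arm marginal feature probabilities equal
#' `plogis(qlogis(baseline) + shift)` exactly, by intercept calibration.
#'
#' @param assignments Tibble from [assign_arms()].
#' @param scenario An `engagement_scenario`.
#' @param seed Optional integer seed.
#' @return The assignment tibble with outcome columns appended: the six
#'   `feature_*` indicators, `feature_count`, `page_views`,
#'   `minutes_on_site`, `return_visits`, `unenroll_day`.
#' @export
simulate_outcomes <- function(assignments, scenario = default_scenario(), seed = NULL) {
  validate_scenario(scenario)
  req <- c("arm", .FACTORS)
  if (!all(req %in% names(assignments))) {
    abort(paste0("`assignments` must contain columns: ", paste(req, collapse = ", ")))
  }
  if (!is.null(seed)) withr::local_seed(check_seed(seed))
  n <- nrow(assignments)
  arm <- assignments$arm
  lam <- scenario$latent_loading
  z <- rnorm(n)

  out <- assignments
  for (j in .FEATURES) {
    shifts <- arm_shifts(scenario, j)             # length 16
    p_arm <- plogis(qlogis(scenario$features[[j]]) + shifts)
    bad <- which(p_arm <= 1e-12 | p_arm >= 1 - 1e-12)
    if (length(bad)) {
      abort(sprintf(
        "scenario implies a degenerate probability for feature '%s' in arm %s",
        j, paste(bad, collapse = ", ")))
    }
    p_uni <- unique(p_arm)
    a_uni <- vapply(p_uni, calibrate_logit_intercept, numeric(1), lam = lam)
    a_arm <- a_uni[match(p_arm, p_uni)]
    p_i <- plogis(a_arm[arm] + lam * z)
    out[[paste0("feature_", j)]] <- rbinom(n, 1L, p_i)
  }
  out$feature_count <- as.integer(rowSums(out[paste0("feature_", .FEATURES)]))

  pv_shift <- arm_shifts(scenario, "page_views")
  out$page_views <- rnbinom(n, mu = scenario$page_views$mu * exp(pv_shift[arm]),
                            size = scenario$page_views$size)
  min_shift <- arm_shifts(scenario, "minutes_on_site")
  out$minutes_on_site <- rlnorm(n, scenario$minutes$meanlog + min_shift[arm],
                                scenario$minutes$sdlog)
  rv_shift <- arm_shifts(scenario, "return_visits")
  out$return_visits <- rnbinom(n, mu = scenario$return_visits$mu * exp(rv_shift[arm]),
                               size = scenario$return_visits$size)

  completed <- rbinom(n, 1L, scenario$completion_rate) == 1L
  day <- pmin(89L, pmax(1L, as.integer(round(
    rlnorm(n, scenario$unenroll$meanlog, scenario$unenroll$sdlog)))))
  out$unenroll_day <- ifelse(completed, 90L, day)
  out
}

#' Simulate a complete factorial screening trial
#'
#' Convenience wrapper: stratified block randomization then outcome
#' generation, both driven by one root seed (stage streams are derived from
#' it, so the whole trial is reproducible from a single integer).
#'
#' @inheritParams assign_arms
#' @inheritParams simulate_outcomes
#' @return A participant-level tibble; see [simulate_outcomes()].
#' @examples
#' trial <- simulate_trial(864, seed = 7)
#' mean(trial$feature_count)   # ~ 2.4 of 6 features
#' @export
simulate_trial <- function(n = 864, scenario = default_scenario(),
                           mobile_fraction = 0.834, seed = NULL) {
  seeds <- if (is.null(seed)) list(NULL, NULL) else {
    root <- check_seed(seed) %% 1000003L
    # two derived stage streams, kept within 32-bit integer range
    list((root * 2011L + 1L) %% .Machine$integer.max,
         (root * 4021L + 9973L) %% .Machine$integer.max)
  }
  asg <- assign_arms(n, mobile_fraction, seed = seeds[[1]])
  simulate_outcomes(asg, scenario, seed = seeds[[2]])
}
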