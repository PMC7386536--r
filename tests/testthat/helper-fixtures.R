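# Shared fixtures built in code.

# a small balanced trial: n participants, outcomes drawn iid (no effects)
tiny_trial <- function(n = 160, seed = 42) {
  simulate_trial(n, scenario = default_scenario(latent_loading = 0), seed = seed)
}

# arbitrary 16-arm data with k per arm and given per-arm event probabilities
cell_trial <- function(p_arm, k = 10, seed = 1) {
  withr::local_seed(seed)
  arm <- rep(1:16, each = k)
  dplyr::bind_cols(tibble::tibble(arm = arm), levels_from_arm_tt(arm)) |>
    dplyr::mutate(y = rbinom(length(arm), 1L, p_arm[arm]))
}

levels_from_arm_tt <- function(arm) {
  a <- as.integer(arm) - 1L
  tibble::tibble(
    personalization = a %/% 8L,
    integration     = (a %/% 4L) %% 2L,
    tailoring       = (a %/% 2L) %% 2L,
    intensity       = a %% 2L
  )
}

# printed marginal percentages and SMDs of the feature-utilization and
# engagement-metric tables (on/off percent, published SMD)
published_binary_grid <- function() {
  tibble::tribble(
    ~table, ~factor, ~outcome, ~on, ~off, ~smd, ~digits,
    1, "personalization", "set_quit_date", 84.5, 85.7, -0.02, 2,
    1, "personalization", "choose_aid", 35.2, 39.3, -0.06, 2,
    1, "personalization", "build_support", 14.6, 12.3, 0.05, 2,
    1, "personalization", "track_triggers", 55.0, 55.7, -0.01, 2,
    1, "personalization", "beat_triggers", 16.8, 15.0, 0.04, 2,
    1, "personalization", "visit_community", 32.5, 35.0, -0.04, 2,
    1, "integration", "set_quit_date", 84.5, 85.7, -0.02, 2,
    1, "integration", "choose_aid", 46.6, 27.9, 0.28, 2,
    1, "integration", "build_support", 19.3, 7.5, 0.25, 2,
    1, "integration", "track_triggers", 58.2, 52.5, 0.08, 2,
    1, "integration", "beat_triggers", 17.7, 14.1, 0.07, 2,
    1, "integration", "visit_community", 32.3, 35.2, -0.04, 2,
    1, "tailoring", "set_quit_date", 87.0, 83.1, 0.08, 2,
    1, "tailoring", "choose_aid", 37.7, 36.8, 0.01, 2,
    1, "tailoring", "build_support", 16.6, 10.3, 0.13, 2,
    1, "tailoring", "track_triggers", 58.7, 52.1, 0.09, 2,
    1, "tailoring", "beat_triggers", 18.6, 13.2, 0.11, 2,
    1, "tailoring", "visit_community", 36.6, 30.9, 0.09, 2,
    1, "intensity", "set_quit_date", 83.4, 86.8, -0.07, 2,
    1, "intensity", "choose_aid", 38.2, 36.4, 0.03, 2,
    1, "intensity", "build_support", 14.6, 12.3, 0.05, 2,
    1, "intensity", "track_triggers", 56.4, 54.3, 0.03, 2,
    1, "intensity", "beat_triggers", 18.2, 13.6, 0.09, 2,
    1, "intensity", "visit_community", 31.4, 36.1, -0.07, 2,
    2, "personalization", "high_page_views", 31.6, 32.9, -0.017, 3,
    2, "personalization", "high_minutes", 31.3, 28.4, 0.045, 3,
    2, "personalization", "returned", 37.9, 39.1, -0.019, 3,
    2, "integration", "high_page_views", 30.8, 33.7, -0.043, 3,
    2, "integration", "high_minutes", 29.7, 29.9, -0.003, 3,
    2, "integration", "returned", 37.0, 40.0, -0.044, 3,
    2, "tailoring", "high_page_views", 35.9, 28.6, 0.110, 3,
    2, "tailoring", "high_minutes", 32.3, 27.3, 0.078, 3,
    2, "tailoring", "returned", 41.6, 35.4, 0.089, 3,
    2, "intensity", "high_page_views", 33.1, 31.4, 0.028, 3,
    2, "intensity", "high_minutes", 31.3, 28.3, 0.047, 3,
    2, "intensity", "returned", 40.0, 36.9, 0.045, 3
  )
}
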