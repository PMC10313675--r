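# Shared simulation studies, computed once per test session and reused by
# several test files (they are the expensive part of the suite).

# Drift-test calibration/power study.  The power arm uses a deliberately
# high-information generator (high heritability, many records per horse,
# a long breeding horizon and truncation selection on true breeding value)
# so that the generator trend exceeds five drift-slope standard deviations,
# which is the regime the power claim concerns; the null arm is the same
# population without selection.
drift_study_config <- function(trend) {
  sim_config(
    n_founders = 80, first_year = 1988, n_years = 16,
    offspring_per_year = 35,
    true_genetic_trend = trend,
    sire_pool_fraction = 0.10, dam_pool_fraction = 0.4,
    V_A = 0.6, V_PE = 0.05, V_T = 0.03, V_R = 0.32,
    mean_records_per_horse = 7, n_trainers = 12
  )
}

drift_study_rep <- function(seed, trend) {
  cfg <- drift_study_config(trend)
  sim <- suppressMessages(simulate_horse_data(cfg, seed = seed))
  rec <- suppressMessages(prepare_records(sim$records))
  des <- suppressWarnings(suppressMessages(
    build_design(rec, model_spec("B"), sim$ped)
  ))
  g <- fit_gibbs(des, sim$ped, chain = chain_plan(1400, 450, 2),
                 seed = seed + 1000)
  tr <- beta_g_posterior(g, sim$ped, 1988, 2003)
  dr <- run_drift_test(g, tr, sim$ped, n_sim = 250, seed = seed + 2000)
  true_slope <- estimate_beta_g(suppressMessages(
    cohort_means(sim$true_bv, sim$ped, 1988, 2003,
                 ids = unique(rec$horse))
  ))
  list(
    true_slope = true_slope,
    beta_g = tr$beta_g,
    p_positive = tr$p_positive,
    p_drift = dr$p_exceeds_drift,
    drift_sd = sd(dr$drift_slopes)
  )
}

drift_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      reps <- 20
      cache <<- list(
        selection = lapply(seq_len(reps), function(r) {
          drift_study_rep(3000 + r, trend = 0.009)
        }),
        null = lapply(seq_len(reps), function(r) {
          drift_study_rep(4000 + r, trend = 0)
        })
      )
    }
    cache
  }
})

# Sprint-like parameter-recovery dataset (one large fit shared by the
# REML/Gibbs recovery checks).
recovery_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_founders = 150, first_year = 1990, n_years = 15,
        offspring_per_year = 100, true_genetic_trend = 0,
        sire_pool_fraction = 0.05, n_trainers = 60,
        mean_records_per_horse = 5.96
      )
      sim <- suppressMessages(simulate_horse_data(cfg, seed = 90210))
      rec <- suppressMessages(prepare_records(sim$records))
      des <- suppressWarnings(suppressMessages(
        build_design(rec, model_spec("B"), sim$ped)
      ))
      fit <- suppressMessages(fit_reml(des, sim$ped))
      g <- fit_gibbs(des, sim$ped, chain = chain_plan(2400, 800, 2),
                     seed = 90211)
      cache <<- list(cfg = cfg, sim = sim, rec = rec, des = des,
                     fit = fit, gibbs = g)
    }
    cache
  }
})
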