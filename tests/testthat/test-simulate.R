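test_that("the generator is reproducible and validates its config", {
  cfg <- sim_config(n_founders = 40, first_year = 1990, n_years = 4,
                    offspring_per_year = 25, true_genetic_trend = 0)
  s1 <- suppressMessages(simulate_horse_data(cfg, seed = 3))
  s2 <- suppressMessages(simulate_horse_data(cfg, seed = 3))
  expect_identical(as.data.frame(s1$ped), as.data.frame(s2$ped))
  expect_identical(s1$true_bv, s2$true_bv)
  expect_identical(as.data.frame(s1$records), as.data.frame(s2$records))

  expect_error(sim_config(V_A = -1), "non-negative")
  expect_error(sim_config(sire_pool_fraction = 0), "\\(0, 1\\]")
  expect_error(sim_config(mean_records_per_horse = 0.5), ">= 1")
  expect_error(sim_config(age_effects = 1:3), "10 values")
})

test_that("generated data pass the package validators cleanly", {
  sim <- small_sim()
  expect_silent(ped2 <- as_pedigree(as.data.frame(sim$ped)))
  rec <- expect_silent(prepare_records(sim$records))
  expect_true(all(rec$category == "sprint"))
  expect_true(all(rec$speed > 0))
  expect_true(all(rec$age >= 2))
  # finish times are consistent with speeds
  expect_equal(rec$speed * rec$finish_time, rec$distance,
               tolerance = 1e-12)
})

test_that("a small sire pool creates large paternal half-sibships", {
  cfg <- sim_config(n_founders = 80, first_year = 1990, n_years = 6,
                    offspring_per_year = 60, true_genetic_trend = 0.009,
                    sire_pool_fraction = 0.04, dam_pool_fraction = 0.9)
  ped <- suppressMessages(simulate_pedigree(cfg, seed = 5))$ped
  s <- summarize_pedigree(ped)
  # dams have at most one foal per year but can be reused across years;
  # the structural claim is paternal sibships dwarfing maternal ones
  expect_gt(s$max_paternal_halfsib, 3 * s$max_maternal_halfsib)
  expect_lte(s$max_maternal_halfsib, cfg$n_years)
})

test_that("true breeding values carry the configured genetic variance", {
  cfg <- sim_config(n_founders = 2000, first_year = 1990, n_years = 1,
                    offspring_per_year = 1, true_genetic_trend = 0,
                    V_A = 0.25)
  sim <- suppressMessages(simulate_pedigree(cfg, seed = 9))
  founders <- sim$ped$id[is.na(sim$ped$sire) & is.na(sim$ped$dam)]
  expect_equal(var(sim$true_bv[founders]), 0.25, tolerance = 0.05)
})

test_that("record noise components match the configured variances", {
  cfg <- sim_config(n_founders = 150, first_year = 1990, n_years = 8,
                    offspring_per_year = 120, true_genetic_trend = 0,
                    mean_records_per_horse = 4)
  sim <- suppressMessages(simulate_horse_data(cfg, seed = 13))
  truth <- sim$truth
  expect_equal(var(truth$pe), cfg$V_PE, tolerance = 0.15)
  expect_equal(var(truth$residuals), cfg$V_R, tolerance = 0.05)
  expect_equal(var(truth$trainer_effects), cfg$V_T, tolerance = 0.5)
  # noiseless check: speed minus all known pieces is the fixed part, and
  # with zero variances speed equals mu + fixed + BV exactly
  cfg0 <- sim_config(n_founders = 40, first_year = 1990, n_years = 3,
                     offspring_per_year = 20, true_genetic_trend = 0,
                     V_PE = 0, V_T = 0, V_R = 0, sex_effect = 0,
                     age_effects = rep(0, 10), beta_distance = 0,
                     beta_distance2 = 0, beta_going = 0, beta_runners = 0,
                     beta_runners2 = 0, timing_effect = 0,
                     racecourse_sd = 0)
  sim0 <- suppressMessages(simulate_horse_data(cfg0, seed = 2))
  expect_equal(sim0$records$speed,
               cfg0$mu + unname(sim0$true_bv[sim0$records$horse]),
               tolerance = 1e-12)
})

test_that("selection produces a positive realised trend in true values", {
  hits <- 0
  for (r in 1:20) {
    cfg <- sim_config(n_founders = 60, first_year = 1990, n_years = 6,
                      offspring_per_year = 30, true_genetic_trend = 0.009,
                      sire_pool_fraction = 0.06, dam_pool_fraction = 0.4,
                      V_A = 1)
    sim <- suppressMessages(simulate_pedigree(cfg, seed = 300 + r))
    tab <- suppressMessages(
      cohort_means(sim$true_bv, sim$ped, 1990, 1995)
    )
    if (estimate_beta_g(tab) > 0) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("a no-selection cohort trend lies within the drift null", {
  cfg <- sim_config(n_founders = 60, first_year = 1990, n_years = 8,
                    offspring_per_year = 40, true_genetic_trend = 0,
                    V_A = 1)
  sim <- suppressMessages(simulate_pedigree(cfg, seed = 21))
  obs <- estimate_beta_g(
    suppressMessages(cohort_means(sim$true_bv, sim$ped, 1990, 1997))
  )
  # drift null from the package's own gene dropper on the same pedigree
  bv <- gene_drop(sim$ped, V_A = 1, seed = 22, n_sim = 400)
  ids <- sim$ped$id[!is.na(sim$ped$birth_year) & sim$ped$birth_year >= 1990]
  slopes <- apply(bv[ids, ], 2, function(v) {
    estimate_beta_g(suppressMessages(
      cohort_means(setNames(v, ids), sim$ped, 1990, 1997)
    ))
  })
  expect_gt(obs, quantile(slopes, 0.005))
  expect_lt(obs, quantile(slopes, 0.995))
})

test_that("bivariate simulation delivers the requested genetic correlation", {
  cfg <- sim_config(n_founders = 500, first_year = 1990, n_years = 2,
                    offspring_per_year = 100, true_genetic_trend = 0,
                    V_A = 0.3)
  biv <- suppressMessages(
    simulate_bivariate_data(cfg, r_G = 0.8, seed = 4)
  )
  founders <- biv$ped$id[is.na(biv$ped$sire) & is.na(biv$ped$dam)]
  expect_equal(cor(biv$true_bv[founders, 1], biv$true_bv[founders, 2]),
               0.8, tolerance = 0.08)
  expect_equal(length(biv$records), 2)
  both <- intersect(biv$records[[1]]$horse, biv$records[[2]]$horse)
  expect_gt(length(both), 0)
})
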