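# Direct dense evaluation of the restricted log-likelihood,
#   logL = -1/2 [ log|V| + log|X' V^-1 X| + y'Py + (n - p) log 2pi ],
# used as an independent oracle for the sparse MME-based evaluation.
dense_reml_loglik <- function(design, A, sigma2, sigma2_e) {
  X <- as.matrix(design$X)
  V <- sigma2[["additive"]] *
    as.matrix(design$Z$additive %*% A %*% t(design$Z$additive)) +
    sigma2[["pe"]] * tcrossprod(as.matrix(design$Z$pe)) +
    sigma2[["trainer"]] * tcrossprod(as.matrix(design$Z$trainer)) +
    diag(sigma2_e, design$n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  y <- design$y
  -0.5 * (as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XtViX)$modulus) +
            drop(t(y) %*% P %*% y) +
            (design$n - design$p) * log(2 * pi))
}

test_that("MME-based restricted likelihood equals the dense formula", {
  cfg <- sim_config(n_founders = 20, first_year = 1990, n_years = 4,
                    offspring_per_year = 15, true_genetic_trend = 0,
                    mean_records_per_horse = 2, n_trainers = 5)
  sim <- suppressMessages(simulate_horse_data(cfg, seed = 2))
  rec <- suppressMessages(prepare_records(sim$records))
  des <- suppressMessages(build_design(rec, model_spec("A"), sim$ped))
  A <- relationship_matrix(sim$ped)
  setup <- equigen:::mm_setup(des, sim$ped, c("additive", "pe", "trainer"))
  for (s2 in list(c(0.02, 0.03, 0.01, 0.08), c(0.1, 0.1, 0.1, 0.1))) {
    sig <- list(additive = s2[1], pe = s2[2], trainer = s2[3])
    ll_mme <- equigen:::mm_loglik(setup, sig, s2[4])$loglik
    ll_dense <- dense_reml_loglik(des, A, sig, s2[4])
    expect_equal(ll_mme, ll_dense, tolerance = 1e-8)
  }
})

test_that("REML matches lme4 when the pedigree carries no relationships", {
  skip_if_not_installed("lme4")
  set.seed(3)
  nH <- 60
  ped <- as_pedigree(tibble::tibble(
    id = sprintf("H%03d", 1:nH), sire = NA_character_, dam = NA_character_,
    birth_year = 2000L, sex = rep(c("male", "female"), nH / 2)
  ))
  nrec <- 4
  u <- rnorm(nH, 0, sqrt(0.3))
  rec <- make_records(
    horse = rep(ped$id, each = nrec),
    speed = 0, race_id = rep(sprintf("R%03d", 1:30), length.out = nH * nrec),
    age = sample(2:5, nH * nrec, TRUE),
    sex = rep(rep(c("male", "female"), nH / 2), each = nrec)
  )
  rec$speed <- 18 + 0.1 * (rec$sex == "male") +
    u[match(rec$horse, ped$id)] + rnorm(nH * nrec, 0, sqrt(0.7))
  rec <- prepare_records(rec)
  des <- suppressWarnings(build_design(rec, model_spec("A"), ped))
  fit <- fit_reml(des, ped, random = "additive")

  lf <- suppressMessages(lme4::lmer(
    speed ~ race_id + age_f + sex + (1 | horse),
    data = data.frame(speed = rec$speed, race_id = factor(rec$race_id),
                      age_f = collapse_age(rec$age), sex = factor(rec$sex),
                      horse = rec$horse),
    REML = TRUE
  ))
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$vc$variance[1], vc$vcov[1], tolerance = 1e-3)
  expect_equal(fit$vc$variance[2], vc$vcov[2], tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(logLik(lf)), tolerance = 1e-6)
})

test_that("balanced half-sib REML agrees with the ANOVA sire model", {
  # 100 sires x 20 offspring, one record each, no PE/trainer variance:
  # h2 = 4 * sire intraclass correlation
  set.seed(8)
  ns <- 100
  k <- 20
  h2_true <- 0.3
  va <- h2_true
  vr <- 1 - h2_true
  sires <- sprintf("S%03d", 1:ns)
  kids <- sprintf("K%04d", 1:(ns * k))
  ped <- as_pedigree(tibble::tibble(
    id = c(sires, kids),
    sire = c(rep(NA_character_, ns), rep(sires, each = k)),
    dam = NA_character_,
    birth_year = c(rep(1990L, ns), rep(1995L, ns * k)),
    sex = c(rep("male", ns), rep("female", ns * k))
  ))
  sire_bv <- rnorm(ns, 0, sqrt(va))
  y <- 16 + rep(sire_bv / 2, each = k) +
    rnorm(ns * k, 0, sqrt(0.75 * va)) + rnorm(ns * k, 0, sqrt(vr))
  rec <- make_records(horse = kids, speed = y,
                      race_id = sprintf("R%04d", rep(1:(ns * k %/% 10),
                                                     length.out = ns * k)))
  rec <- prepare_records(rec)
  des <- suppressWarnings(build_design(rec, model_spec("A"), ped))
  fit <- fit_reml(des, ped, random = "additive")

  sire_f <- factor(rep(sires, each = k))
  av <- anova(lm(y ~ sire_f))
  msb <- av[["Mean Sq"]][1]
  msw <- av[["Mean Sq"]][2]
  t_icc <- (msb - msw) / (msb + (k - 1) * msw)
  h2_anova <- 4 * t_icc
  se_t <- sqrt(2 * (1 - t_icc)^2 * (1 + (k - 1) * t_icc)^2 /
                 (k * (k - 1) * (ns - 1)))
  expect_lt(abs(fit$h2 - h2_anova), 2 * 4 * se_t)
})

test_that("null data give near-zero heritability estimates", {
  # V_A = 0 in the generator: fitted h2 <= 0.02 in at least 95% of reps
  hits <- 0
  n_rep <- 20
  # diffuse mating (no sire concentration): many small families give the
  # boundary estimator its tightest null concentration at this scale
  cfg <- sim_config(n_founders = 150, first_year = 1990, n_years = 8,
                    offspring_per_year = 110, true_genetic_trend = 0,
                    sire_pool_fraction = 1, dam_pool_fraction = 1,
                    V_A = 0, V_PE = 0.07, V_T = 0.016, V_R = 0.09,
                    mean_records_per_horse = 6, n_trainers = 20)
  for (r in seq_len(n_rep)) {
    sim <- suppressMessages(simulate_horse_data(cfg, seed = 100 + r))
    rec <- suppressMessages(prepare_records(sim$records))
    des <- suppressWarnings(
      suppressMessages(build_design(rec, model_spec("B"), sim$ped))
    )
    fit <- suppressMessages(fit_reml(des, sim$ped, se = FALSE))
    if (fit$h2 <= 0.02) hits <- hits + 1
  }
  expect_gte(hits, ceiling(0.95 * n_rep))
})

test_that("variance components are recovered within 2 SE", {
  cfg <- sim_config(n_founders = 80, first_year = 1990, n_years = 8,
                    offspring_per_year = 60, true_genetic_trend = 0,
                    mean_records_per_horse = 5, n_trainers = 20)
  sim <- suppressMessages(simulate_horse_data(cfg, seed = 77))
  rec <- suppressMessages(prepare_records(sim$records))
  des <- suppressMessages(build_design(rec, model_spec("B"), sim$ped))
  fit <- suppressMessages(fit_reml(des, sim$ped))
  truth <- c(cfg$V_A, cfg$V_PE, cfg$V_T, cfg$V_R)
  expect_true(all(abs(fit$vc$variance - truth) <= 2 * fit$vc$se))
})

test_that("the restricted likelihood gradient vanishes at the optimum", {
  sim <- small_sim()
  rec <- suppressMessages(prepare_records(sim$records))
  des <- suppressMessages(build_design(rec, model_spec("B"), sim$ped))
  fit <- suppressMessages(fit_reml(des, sim$ped, se = FALSE))
  setup <- equigen:::mm_setup(des, sim$ped, c("additive", "pe", "trainer"))
  v <- fit$vc$variance
  ll <- function(v) {
    sig <- list(additive = v[1], pe = v[2], trainer = v[3])
    equigen:::mm_loglik(setup, sig, v[4])$loglik
  }
  f0 <- ll(v)
  for (j in seq_along(v)) {
    h <- v[j] * 1e-4
    vp <- v; vp[j] <- v[j] + h
    vm <- v; vm[j] <- v[j] - h
    grad <- (ll(vp) - ll(vm)) / (2 * h)
    # relative to the curvature scale: |grad| * h should be << |logL| change
    expect_lt(abs(grad) * v[j], 1e-4 * abs(f0))
  }
})

test_that("h2 is invariant to location shifts and scale changes", {
  sim <- small_sim()
  rec <- suppressMessages(prepare_records(sim$records))
  des <- suppressMessages(build_design(rec, model_spec("B"), sim$ped))
  f1 <- suppressMessages(fit_reml(des, sim$ped, se = FALSE))

  des_shift <- des
  des_shift$y <- des$y + 5
  f2 <- suppressMessages(fit_reml(des_shift, sim$ped, se = FALSE))
  expect_equal(f2$h2, f1$h2, tolerance = 2e-3)

  des_scale <- des
  des_scale$y <- des$y * 3
  f3 <- suppressMessages(fit_reml(des_scale, sim$ped, se = FALSE))
  expect_equal(f3$h2, f1$h2, tolerance = 2e-3)
  expect_equal(f3$vc$variance, f1$vc$variance * 9, tolerance = 1e-2)
})

test_that("boundary chi-square mixture p-values are correct", {
  expect_equal(mixture_lrt(0)$p_value, 1)
  expect_equal(mixture_lrt(2.706)$p_value, 0.05, tolerance = 1e-3)
  expect_lt(mixture_lrt(1990.8)$p_value, 0.001)
  expect_equal(mixture_lrt(-3)$statistic, 0)
})

test_that("the LRT of V_A detects simulated additive variance", {
  sim <- small_sim()
  rec <- suppressMessages(prepare_records(sim$records))
  des <- suppressMessages(build_design(rec, model_spec("B"), sim$ped))
  full <- suppressMessages(fit_reml(des, sim$ped, se = FALSE))
  red <- suppressMessages(fit_reml(des, sim$ped,
                                   random = c("pe", "trainer"), se = FALSE))
  out <- lrt_va(full, red)
  expect_gte(out$statistic, 0)
  expect_lt(out$p_value, 0.5)
  expect_error(lrt_va(red, full), "additive")
})
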