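test_that("gene dropping respects degenerate and founder cases", {
  ped <- random_pedigree(100, seed = 3)
  expect_true(all(gene_drop(ped, V_A = 0, seed = 1) == 0))
  expect_error(gene_drop(ped, V_A = -1), "non-negative")

  founders <- as_pedigree(tibble::tibble(
    id = sprintf("F%05d", 1:10000), sire = NA_character_,
    dam = NA_character_, birth_year = 1990L, sex = "female"
  ))
  bv <- gene_drop(founders, V_A = 1, seed = 2)
  expect_equal(var(bv), 1, tolerance = 0.05)
})

test_that("gene-dropped values have the quantitative-genetic moments", {
  # non-inbred two-generation pedigree: offspring variance ~ 1 and
  # parent-offspring covariance ~ 0.5 across replicates
  n_par <- 60
  ped <- as_pedigree(tibble::tibble(
    id = c(sprintf("S%02d", 1:n_par), sprintf("D%02d", 1:n_par),
           sprintf("K%02d", 1:n_par)),
    sire = c(rep(NA_character_, 2 * n_par), sprintf("S%02d", 1:n_par)),
    dam = c(rep(NA_character_, 2 * n_par), sprintf("D%02d", 1:n_par)),
    birth_year = rep(c(1990L, 1990L, 1995L), each = n_par),
    sex = rep(c("male", "female", "female"), each = n_par)
  ))
  bv <- gene_drop(ped, V_A = 1, seed = 4, n_sim = 1000)
  kids <- bv[sprintf("K%02d", 1:n_par), ]
  sires <- bv[sprintf("S%02d", 1:n_par), ]
  expect_equal(mean(apply(kids, 2, var)), 1, tolerance = 0.05)
  covs <- vapply(seq_len(1000), function(s) cov(kids[, s], sires[, s]), 0)
  expect_equal(mean(covs), 0.5, tolerance = 0.05)
})

test_that("gene dropping reproduces the full covariance A * V_A", {
  ped <- random_pedigree(40, seed = 6, p_unknown = 0.2)
  A <- relationship_matrix(ped)
  bv <- gene_drop(ped, V_A = 1, seed = 5, n_sim = 4000)
  emp <- tcrossprod(bv) / 4000
  expect_lt(max(abs(emp - A)), 0.25)
  expect_lt(mean(abs(emp - A)), 0.03)
})

make_drift_inputs <- function(va_draws, bg_draws, ped) {
  g <- structure(
    list(
      vc_draws = cbind(V_A = va_draws, V_PE = 0.1, V_T = 0.1, V_R = 0.1),
      bv_draws = matrix(0, length(va_draws), nrow(ped),
                        dimnames = list(NULL, ped$id)),
      chain = list(seed = 1), ped_ids = ped$id, horse_ids = ped$id,
      model = "B"
    ),
    class = "equigen_gibbs"
  )
  tr <- structure(
    list(beta_g = mean(bg_draws), source = "MCMC", draws = bg_draws,
         interval = range(bg_draws), p_positive = mean(bg_draws > 0),
         cohort_range = range(ped$birth_year), ids = ped$id,
         beta_P = NULL, ratio = NULL, cohort_table = NULL,
         cohort_draws = NULL),
    class = "equigen_trend"
  )
  list(g = g, tr = tr)
}

test_that("a separated beta_G posterior yields p near 1", {
  ped <- random_pedigree(200, seed = 8)
  inp <- make_drift_inputs(va_draws = rep(1e-6, 300),
                           bg_draws = rep(10, 300), ped)
  dr <- run_drift_test(inp$g, inp$tr, ped,
                       first = min(ped$birth_year),
                       last = max(ped$birth_year),
                       n_sim = 200, seed = 1)
  expect_equal(dr$p_exceeds_drift, 1)
})

test_that("drift slopes are symmetric about zero", {
  ped <- random_pedigree(300, seed = 10)
  inp <- make_drift_inputs(rep(0.5, 500), rnorm(500, 0, 0.01), ped)
  dr <- run_drift_test(inp$g, inp$tr, ped,
                       first = min(ped$birth_year),
                       last = max(ped$birth_year),
                       n_sim = 1000, seed = 2)
  mc_se <- sd(dr$drift_slopes) / sqrt(dr$n_sim)
  expect_lt(abs(mean(dr$drift_slopes)), 3 * mc_se)
})

test_that("drift-slope spread grows with the additive variance", {
  ped <- random_pedigree(300, seed = 10)
  run_sd <- function(va) {
    inp <- make_drift_inputs(rep(va, 400), rnorm(400, 0, 0.01), ped)
    dr <- run_drift_test(inp$g, inp$tr, ped,
                         first = min(ped$birth_year),
                         last = max(ped$birth_year),
                         n_sim = 1000, seed = 3)
    sd(dr$drift_slopes)
  }
  expect_gt(run_sd(0.8), run_sd(0.2))
})

test_that("the drift test is reproducible and mode options work", {
  ped <- random_pedigree(150, seed = 12)
  inp <- make_drift_inputs(rep(0.3, 300), rnorm(300, 0.002, 0.004), ped)
  args <- list(inp$g, inp$tr, ped, first = min(ped$birth_year),
               last = max(ped$birth_year), n_sim = 200, seed = 7)
  d1 <- do.call(run_drift_test, args)
  d2 <- do.call(run_drift_test, args)
  expect_identical(d1$drift_slopes, d2$drift_slopes)
  expect_identical(d1$p_exceeds_drift, d2$p_exceeds_drift)
  d3 <- do.call(run_drift_test, c(args, list(mode = "distribution")))
  expect_true(abs(d3$p_exceeds_drift - d1$p_exceeds_drift) < 0.2)
  expect_error(do.call(run_drift_test,
                       c(args[-6], list(n_sim = 50))), "100")
})
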