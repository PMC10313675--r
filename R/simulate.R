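#' Configuration for the synthetic-data generator
#'
#' Defines the population and sampling structure the generator emulates: a
#' multi-generation overlapping pedigree with large paternal half-sibships
#' (a small pool of heavily used sires), repeated race records per horse,
#' race-level covariates, and additive genetic + permanent environment +
#' trainer + residual variance structure.  Defaults describe a sprint-like
#' population: phenotypic variance 0.16 (SD 0.4 yards/s around a mean speed
#' of 18 yards/s) partitioned so that h2 = 0.124, repeatability = 0.35 and
#' the trainer fraction is 0.10, with a mean of 5.96 records per horse and
#' mean parental age 9.5 years.
#'
#' @param n_founders Number of founders (born before the first cohort year).
#' @param first_year First offspring cohort year.
#' @param n_years Number of cohort years.
#' @param offspring_per_year Offspring born per year (capped by available
#'   dams; one foal per dam per year).
#' @param sire_pool_fraction Fraction of eligible males available as sires;
#'   small values create large paternal half-sibships.
#' @param dam_pool_fraction Fraction of eligible females available as dams.
#' @param true_genetic_trend If positive, sires and dams are truncation-
#'   selected on true breeding value (top fractions above); if zero,
#'   parents are drawn uniformly (no selection).
#' @param V_A,V_PE,V_T,V_R True variance components (yards^2 s^-2).
#' @param mu Mean speed (yards/s).
#' @param mean_records_per_horse Mean race records per horse (min 1).
#' @param mean_runners Target mean runners per race.
#' @param category Race-distance category for generated races.
#' @param n_racecourses,n_trainers Numbers of racecourse and trainer levels.
#' @param trainer_confound If `TRUE`, trainers are assigned by sire
#'   breeding-value rank with trainer effects sorted to match ("better bred
#'   horses go to better trainers"), creating the confounding that inflates
#'   heritability when trainer is omitted from the model.
#' @param going_mean,going_sd Numeric going-score distribution.
#' @param prob_hand_timing Probability a race is hand timed.
#' @param sex_effect Male fixed effect (yards/s).
#' @param age_effects Fixed effects for age levels 2..11+ (yards/s).
#' @param beta_distance,beta_distance2,beta_going,beta_runners,beta_runners2
#'   Fixed-effect coefficients on the standardised race covariates.
#' @param timing_effect Hand-timing fixed effect.
#' @param racecourse_sd SD of fixed racecourse effects.
#' @param parent_ages,parent_age_weights Support and weights of the
#'   parental-age-at-offspring-birth distribution (defaults mean 9.5 y).
#' @return A validated `equigen_sim_config` list.
#' @export
sim_config <- function(n_founders = 250,
                       first_year = 1988,
                       n_years = 25,
                       offspring_per_year = 120,
                       sire_pool_fraction = 0.05,
                       dam_pool_fraction = 0.85,
                       true_genetic_trend = 0.009,
                       V_A = 0.124 * 0.16,
                       V_PE = (0.35 - 0.124) * 0.16,
                       V_T = 0.10 * 0.16,
                       V_R = 0.16 - (0.35 * 0.16) - (0.10 * 0.16),
                       mu = 18,
                       mean_records_per_horse = 5.96,
                       mean_runners = 10,
                       category = "sprint",
                       n_racecourses = 12,
                       n_trainers = 60,
                       trainer_confound = FALSE,
                       going_mean = 7, going_sd = 1.5,
                       prob_hand_timing = 0.15,
                       sex_effect = 0.05,
                       age_effects = c(-0.30, -0.08, 0, 0.02, 0, -0.03,
                                       -0.06, -0.10, -0.14, -0.18),
                       beta_distance = -0.35, beta_distance2 = -0.02,
                       beta_going = 0.20, beta_runners = -0.02,
                       beta_runners2 = -0.01,
                       timing_effect = 0.08,
                       racecourse_sd = 0.05,
                       parent_ages = 4:15,
                       parent_age_weights = dnorm(4:15, 9.5, 3)) {
  cfg <- as.list(environment())
  if (any(unlist(cfg[c("V_A", "V_PE", "V_T", "V_R")]) < 0)) {
    abort("variance components must be non-negative")
  }
  for (f in c("sire_pool_fraction", "dam_pool_fraction")) {
    if (cfg[[f]] <= 0 || cfg[[f]] > 1) abort(paste0(f, " must be in (0, 1]"))
  }
  for (cnt in c("n_founders", "n_years", "offspring_per_year",
                "n_racecourses", "n_trainers")) {
    if (cfg[[cnt]] < 1) abort(paste0(cnt, " must be >= 1"))
  }
  if (cfg$mean_records_per_horse < 1) {
    abort("mean_records_per_horse must be >= 1")
  }
  if (length(cfg$age_effects) != 10) {
    abort("age_effects must have 10 values (ages 2..11+)")
  }
  cfg$parent_age_weights <- cfg$parent_age_weights /
    sum(cfg$parent_age_weights)
  structure(cfg, class = "equigen_sim_config")
}

category_distance_range <- function(category,
                                    categories = distance_categories()) {
  row <- categories[categories$name == category, ]
  if (nrow(row) != 1) abort(paste0("unknown category '", category, "'"))
  c(row$min_furlongs, row$max_furlongs) * YARDS_PER_FURLONG
}

#' Simulate a pedigree with known breeding values
#'
#' Builds an overlapping-generation pedigree year by year.  Parents are
#' drawn from the eligible age window with ages weighted by the configured
#' parental-age distribution; when `true_genetic_trend > 0`, sires come
#' from the top `sire_pool_fraction` (and dams from the top
#' `dam_pool_fraction`) of eligible animals ranked by true breeding value
#' (truncation selection on the genotype), otherwise uniformly.  True
#' breeding values follow exactly the Mendelian transmission rule of
#' [gene_drop()], including the parental-inbreeding correction, so their
#' covariance is `A * V_A` by construction.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A list: `ped` (a sorted [as_pedigree()]), `true_bv` (named
#'   vector) and `F` (named inbreeding coefficients).
#' @export
simulate_pedigree <- function(cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "equigen_sim_config"))
  set.seed(derive_seed(seed, "pedigree"))
  n_total <- cfg$n_founders + cfg$n_years * cfg$offspring_per_year
  if (n_total > 20000) {
    abort("configuration implies > 20,000 individuals; reduce the scale")
  }
  id <- character(n_total)
  sire <- rep(NA_integer_, n_total)
  dam <- rep(NA_integer_, n_total)
  by <- integer(n_total)
  sex <- character(n_total)
  bv <- numeric(n_total)
  A <- matrix(0, n_total, n_total)

  nf <- cfg$n_founders
  id[1:nf] <- pad_id("F", 1:nf)
  by[1:nf] <- sample(seq(cfg$first_year - 13, cfg$first_year - 4),
                     nf, replace = TRUE)
  sex[1:nf] <- rep_len(c("male", "female"), nf)
  bv[1:nf] <- rnorm(nf, 0, sqrt(cfg$V_A))
  diag(A)[1:nf] <- 1

  m <- nf
  agew <- setNames(cfg$parent_age_weights, cfg$parent_ages)
  resample <- function(x, size, replace, prob) {
    x[sample.int(length(x), size, replace = replace, prob = prob)]
  }
  # the pool restriction models the concentration of matings on few
  # stallions; under selection the pool is the top fraction by true
  # breeding value (truncation selection on the genotype), otherwise a
  # random fraction of the same size (no selection, same family structure)
  pick_pool <- function(cand, frac, y) {
    k <- max(2L, ceiling(frac * length(cand)))
    k <- min(k, length(cand))
    if (cfg$true_genetic_trend > 0) {
      cand[order(bv[cand], decreasing = TRUE)][seq_len(k)]
    } else {
      # age-weighted pool draw so the random pool represents the
      # configured parental-age distribution, not cohort sizes
      a <- as.character(y - by[cand])
      w <- agew[a] / table(a)[a]
      cand[sample.int(length(cand), k, prob = w)]
    }
  }
  years <- seq(cfg$first_year, cfg$first_year + cfg$n_years - 1)
  for (y in years) {
    age_of <- function(i) y - by[i]
    males <- which(sex[1:m] == "male" &
                     age_of(1:m) %in% cfg$parent_ages)
    females <- which(sex[1:m] == "female" &
                       age_of(1:m) %in% cfg$parent_ages)
    if (length(males) == 0 || length(females) == 0) {
      abort(paste0("no eligible parents in year ", y,
                   "; infeasible configuration"))
    }
    sire_pool <- pick_pool(males, cfg$sire_pool_fraction, y)
    dam_pool <- pick_pool(females, cfg$dam_pool_fraction, y)
    n_off <- min(cfg$offspring_per_year, length(dam_pool))
    # weight pool members so the realised parental-age distribution follows
    # the configured one, not the pool's age composition
    pool_w <- function(pool) {
      a <- as.character(age_of(pool))
      agew[a] / table(a)[a]
    }
    w_s <- pool_w(sire_pool)
    w_d <- pool_w(dam_pool)
    sires_y <- resample(sire_pool, n_off, replace = TRUE, prob = w_s)
    dams_y <- resample(dam_pool, n_off, replace = FALSE, prob = w_d)
    for (j in seq_len(n_off)) {
      m <- m + 1L
      s <- sires_y[j]
      d <- dams_y[j]
      id[m] <- pad_id("H", m - nf)
      sire[m] <- s
      dam[m] <- d
      by[m] <- y
      sex[m] <- if (runif(1) < 0.5) "male" else "female"
      prev <- seq_len(m - 1L)
      arow <- 0.5 * (A[s, prev] + A[d, prev])
      A[m, prev] <- arow
      A[prev, m] <- arow
      A[m, m] <- 1 + 0.5 * A[s, d]
      dm <- 0.5 - 0.25 * ((A[s, s] - 1) + (A[d, d] - 1))
      bv[m] <- 0.5 * (bv[s] + bv[d]) + rnorm(1, 0, sqrt(cfg$V_A * dm))
    }
  }

  ped_df <- tibble(
    id = id[1:m],
    sire = ifelse(is.na(sire[1:m]), NA_character_, id[sire[1:m]]),
    dam = ifelse(is.na(dam[1:m]), NA_character_, id[dam[1:m]]),
    birth_year = by[1:m],
    sex = sex[1:m]
  )
  ped <- suppressMessages(as_pedigree(ped_df))
  ord <- match(ped$id, id[1:m])
  list(
    ped = ped,
    true_bv = setNames(bv[ord], ped$id),
    F = setNames(diag(A)[ord] - 1, ped$id)
  )
}

#' Simulate race records for a pedigree
#'
#' Each horse born in or after the first cohort year receives
#' `1 + Poisson(mean - 1)` race records at ages drawn from a front-loaded
#' career-age distribution over 2..11.  Records are grouped into races
#' within years (targeting `mean_runners` runners per race); each race
#' carries a distance inside the configured category window, a numeric going
#' score, a racecourse, and a timing method.  The observed speed is
#'
#' `speed = mu + fixed(covariates) + BV + PE + trainer + residual`
#'
#' with `PE ~ N(0, V_PE)` per horse, trainer effects `N(0, V_T)` and
#' residuals `N(0, V_R)`; finish time is back-computed from speed and
#' distance.
#'
#' @param ped A pedigree from [simulate_pedigree()].
#' @param true_bv Named true breeding values for the pedigree.
#' @param cfg The [sim_config()] used to build the pedigree.
#' @param seed Integer seed.
#' @return A record tibble (the format [prepare_records()] accepts) with a
#'   `truth` attribute carrying the per-horse permanent environment and
#'   trainer effects and the per-record residuals.
#' @export
simulate_records <- function(ped, true_bv, cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "equigen_sim_config"))
  set.seed(derive_seed(seed, "records"))
  ped <- ensure_sorted(ped)
  horses <- ped$id[!is.na(ped$birth_year) &
                     ped$birth_year >= cfg$first_year]
  if (length(horses) == 0) abort("no horses born in the cohort window")
  nh <- length(horses)
  by <- setNames(ped$birth_year, ped$id)[horses]
  sex <- setNames(ped$sex, ped$id)[horses]

  n_rec <- 1L + rpois(nh, cfg$mean_records_per_horse - 1)
  career_w <- c(0.24, 0.24, 0.17, 0.12, 0.08, 0.05, 0.04, 0.03, 0.02, 0.01)
  ages <- lapply(n_rec, function(k) {
    sample(2:11, k, replace = TRUE, prob = career_w)
  })

  pe <- setNames(rnorm(nh, 0, sqrt(cfg$V_PE)), horses)
  tr_eff <- rnorm(cfg$n_trainers, 0, sqrt(cfg$V_T))
  if (cfg$trainer_confound) {
    sire_bv <- true_bv[setNames(ped$sire, ped$id)[horses]]
    sire_bv[is.na(sire_bv)] <- 0
    grp <- ceiling(rank(sire_bv, ties.method = "first") /
                     (nh / cfg$n_trainers))
    grp <- pmin(pmax(grp, 1L), cfg$n_trainers)
    trainer_of <- setNames(order(tr_eff)[grp], horses)
  } else {
    trainer_of <- setNames(sample(cfg$n_trainers, nh, replace = TRUE),
                           horses)
  }

  rec <- tibble(
    horse = rep(horses, n_rec),
    age = unlist(ages)
  )
  rec$year <- as.integer(by[rec$horse] + rec$age)
  rec$sex <- unname(sex[rec$horse])
  rec$trainer <- pad_id("T", unname(trainer_of[rec$horse]), 3)

  # group records into races within years
  drange <- category_distance_range(cfg$category)
  rec <- rec[order(rec$year), ]
  race_tabs <- list()
  race_of <- integer(nrow(rec))
  offset <- 0L
  for (y in sort(unique(rec$year))) {
    ii <- which(rec$year == y)
    n_races <- max(1L, round(length(ii) / cfg$mean_runners))
    race_of[ii] <- offset + sample(n_races, length(ii), replace = TRUE)
    race_tabs[[as.character(y)]] <- tibble(
      race = offset + seq_len(n_races),
      distance = round(runif(n_races, drange[1], drange[2]) / 10) * 10,
      going = rnorm(n_races, cfg$going_mean, cfg$going_sd),
      racecourse = pad_id("RC", sample(cfg$n_racecourses, n_races,
                                       replace = TRUE), 2),
      timing = ifelse(runif(n_races) < cfg$prob_hand_timing,
                      "hand", "automatic")
    )
    offset <- offset + n_races
  }
  races <- bind_rows(race_tabs)
  rec$race_id <- pad_id("R", race_of, 6)
  ri <- match(race_of, races$race)
  rec$distance <- races$distance[ri]
  rec$going <- races$going[ri]
  rec$racecourse <- races$racecourse[ri]
  rec$timing <- races$timing[ri]
  rec$n_runners <- as.integer(table(race_of)[as.character(race_of)])

  zs <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  dz <- zs(rec$distance)
  gz <- zs(rec$going)
  rz <- zs(rec$n_runners)
  course_eff <- setNames(rnorm(cfg$n_racecourses, 0, cfg$racecourse_sd),
                         pad_id("RC", seq_len(cfg$n_racecourses), 2))
  age_idx <- pmin(rec$age, 11L) - 1L
  fixed <- cfg$mu +
    cfg$age_effects[age_idx] +
    cfg$sex_effect * (rec$sex == "male") +
    cfg$beta_distance * dz + cfg$beta_distance2 * dz^2 +
    cfg$beta_going * gz +
    cfg$beta_runners * rz + cfg$beta_runners2 * rz^2 +
    cfg$timing_effect * (rec$timing == "hand") +
    course_eff[rec$racecourse]

  resid <- rnorm(nrow(rec), 0, sqrt(cfg$V_R))
  rec$speed <- as.numeric(fixed + true_bv[rec$horse] + pe[rec$horse] +
                            tr_eff[trainer_of[rec$horse]] + resid)
  rec$finish_time <- rec$distance / rec$speed
  out <- rec[, c("horse", "race_id", "finish_time", "speed", "distance",
                 "going", "n_runners", "timing", "racecourse", "year",
                 "age", "sex", "trainer")]
  attr(out, "truth") <- list(
    pe = pe, trainer_effects = tr_eff, trainer_of = trainer_of,
    residuals = resid, course_effects = course_eff
  )
  out
}

#' Simulate a complete dataset with known ground truth
#'
#' Convenience wrapper: pedigree + records + truth sidecar.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer root seed (pedigree and record streams are derived
#'   from it deterministically).
#' @return A list with `ped`, `records`, `true_bv`, `F`, `truth` (the true
#'   variance components and effects) and the `config` and `seed` used.
#' @export
simulate_horse_data <- function(cfg = sim_config(), seed = 1) {
  pedsim <- simulate_pedigree(cfg, seed)
  records <- simulate_records(pedsim$ped, pedsim$true_bv, cfg, seed)
  vp <- cfg$V_A + cfg$V_PE + cfg$V_T + cfg$V_R
  list(
    ped = pedsim$ped, records = records, true_bv = pedsim$true_bv,
    F = pedsim$F,
    truth = c(attr(records, "truth"),
              list(V_A = cfg$V_A, V_PE = cfg$V_PE, V_T = cfg$V_T,
                   V_R = cfg$V_R, V_P = vp, h2 = cfg$V_A / vp,
                   repeatability = (cfg$V_A + cfg$V_PE) / vp)),
    config = cfg, seed = seed
  )
}

#' Simulate two genetically correlated distance-category traits
#'
#' Drops bivariate breeding values down a no-selection pedigree (founders
#' `MVN(0, Sigma_A)`, Mendelian deviations `MVN(0, d_i Sigma_A)` with
#' `Sigma_A` built from the per-trait variances and genetic correlation
#' `r_G`), then simulates an independent record set for each trait over a
#' random subset of horses, so some horses carry records for both traits.
#' Permanent environment, trainer and residual effects are independent
#' across traits.
#'
#' @param cfg A [sim_config()]; selection is disabled internally so the
#'   bivariate drop matches the pedigree's neutral transmission.
#' @param r_G True genetic correlation between the two traits.
#' @param prob_trait Length-2 probabilities that a horse has records for
#'   trait 1 / trait 2.
#' @param categories Distance categories of the two traits.
#' @param seed Integer seed.
#' @return A list: `ped`, `records` (list of two record tibbles),
#'   `true_bv` (matrix, individuals by 2) and `Sigma_A`.
#' @export
simulate_bivariate_data <- function(cfg = sim_config(), r_G = 0.8,
                                    prob_trait = c(0.7, 0.7),
                                    categories = c("sprint", "middle"),
                                    seed = 1) {
  cfg$true_genetic_trend <- 0
  pedsim <- simulate_pedigree(cfg, seed)
  ped <- pedsim$ped
  set.seed(derive_seed(seed, "bivariate-bv"))
  Sigma <- matrix(c(cfg$V_A, r_G * cfg$V_A, r_G * cfg$V_A, cfg$V_A), 2)
  L <- chol(Sigma)
  n <- nrow(ped)
  d <- mendelian_d(ped, pedsim$F)
  pi <- parent_index(ped)
  bv <- matrix(0, n, 2, dimnames = list(ped$id, categories))
  for (i in seq_len(n)) {
    mu <- c(0, 0)
    if (!is.na(pi$sire[i])) mu <- mu + 0.5 * bv[pi$sire[i], ]
    if (!is.na(pi$dam[i])) mu <- mu + 0.5 * bv[pi$dam[i], ]
    bv[i, ] <- mu + sqrt(d[i]) * as.numeric(crossprod(L, rnorm(2)))
  }
  set.seed(derive_seed(seed, "bivariate-subset"))
  horses <- ped$id[!is.na(ped$birth_year) &
                     ped$birth_year >= cfg$first_year]
  records <- vector("list", 2)
  for (k in 1:2) {
    has <- horses[runif(length(horses)) < prob_trait[k]]
    cfg_k <- cfg
    cfg_k$category <- categories[k]
    recs <- simulate_records(ped, bv[, k], cfg_k,
                             seed = derive_seed(seed, paste0("trait", k)))
    records[[k]] <- recs[recs$horse %in% has, ]
  }
  list(ped = ped, records = records, true_bv = bv, Sigma_A = Sigma,
       r_G = r_G)
}
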