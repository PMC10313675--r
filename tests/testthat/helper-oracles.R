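# Independent oracles and fixture builders used across the suite.

# Recursive coefficient-of-kinship oracle (memoised).  Entirely independent
# of the tabular relationship-matrix code: classic recursion
#   f(i, i) = (1 + f(s_i, d_i)) / 2
#   f(i, j) = (f(i, s_j) + f(i, d_j)) / 2   for j later in pedigree order
# with unknown parents contributing zero.
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    a <- min(i, j); b <- max(i, j)
    key <- paste(a, b)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (a == b) {
      0.5 * (1 + f(si[a], di[a]))
    } else {
      # b is later in pedigree order, so recurse through b's parents
      0.5 * (f(a, si[b]) + f(a, di[b]))
    }
    memo[[key]] <- val
    val
  }
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) K[j, i] <- K[i, j] <- f(i, j)
  dimnames(K) <- list(ped$id, ped$id)
  K
}

# Brute-force ancestor closure by repeated parent lookup (graph oracle,
# independent of trim_pedigree's single reverse sweep).
ancestor_closure_oracle <- function(ped, ids) {
  keep <- unique(ids)
  repeat {
    rows <- ped[ped$id %in% keep, ]
    more <- setdiff(stats::na.omit(c(rows$sire, rows$dam)), keep)
    if (length(more) == 0) break
    keep <- c(keep, more)
  }
  sort(keep)
}

# Random valid pedigree: founders plus individuals whose parents are drawn
# from earlier animals of the right sex (or unknown).
random_pedigree <- function(n, n_founders = max(4, n %/% 5), seed = 1,
                            p_unknown = 0.1) {
  set.seed(seed)
  id <- sprintf("X%04d", seq_len(n))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    males <- which(sex[seq_len(i - 1)] == "male")
    females <- which(sex[seq_len(i - 1)] == "female")
    if (length(males) > 0 && stats::runif(1) > p_unknown) {
      sire[i] <- id[males[sample.int(length(males), 1)]]
    }
    if (length(females) > 0 && stats::runif(1) > p_unknown) {
      dam[i] <- id[females[sample.int(length(females), 1)]]
    }
  }
  as_pedigree(tibble::tibble(
    id = id, sire = sire, dam = dam,
    birth_year = 1990L + (seq_len(n) - 1L) %/% max(1, n %/% 20),
    sex = sex
  ))
}

trio_pedigree <- function() {
  as_pedigree(data.frame(
    id = c("A", "B", "C"), sire = c(NA, NA, "A"), dam = c(NA, NA, "B"),
    birth_year = c(1990L, 1990L, 1995L),
    sex = c("male", "female", "male")
  ))
}

fullsib_mating_pedigree <- function() {
  as_pedigree(data.frame(
    id = c("P", "Q", "S1", "S2", "O"),
    sire = c(NA, NA, "P", "P", "S1"),
    dam = c(NA, NA, "Q", "Q", "S2"),
    birth_year = c(1980L, 1980L, 1985L, 1986L, 1992L),
    sex = c("male", "female", "male", "female", "male")
  ))
}

# Minimal record table for hand-built fixtures.
make_records <- function(horse, speed, race_id = NULL, year = 2000L,
                         age = 4L, sex = "male", trainer = "T1",
                         distance = 1320, going = 7, n_runners = 8L,
                         timing = "automatic", racecourse = "RC1") {
  n <- length(horse)
  tibble::tibble(
    horse = horse,
    race_id = race_id %||% sprintf("R%03d", seq_len(n)),
    speed = speed,
    distance = rep_len(distance, n), going = rep_len(going, n),
    n_runners = rep_len(n_runners, n), timing = rep_len(timing, n),
    racecourse = rep_len(racecourse, n), year = rep_len(year, n),
    age = rep_len(age, n), sex = rep_len(sex, n),
    trainer = rep_len(trainer, n)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Small simulated dataset shared by several test files (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_founders = 60, first_year = 1990, n_years = 8,
        offspring_per_year = 40, true_genetic_trend = 0,
        mean_records_per_horse = 3, n_trainers = 12
      )
      cache <<- suppressMessages(simulate_horse_data(cfg, seed = 421))
    }
    cache
  }
})
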