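#' Generation interval from a pedigree
#'
#' Mean parental age at offspring birth, taken over all parent-offspring
#' pairs (sire and dam pairs jointly) with known birth years for both
#' members, optionally restricted to offspring in `subset`.
#'
#' @param ped A pedigree with birth years.
#' @param subset Optional ids of offspring to include.
#' @return Mean parental age in years.
#' @export
generation_interval <- function(ped, subset = NULL) {
  ped <- ensure_sorted(ped)
  by <- setNames(ped$birth_year, ped$id)
  off <- if (is.null(subset)) ped$id else intersect(as.character(subset),
                                                    ped$id)
  rows <- as_tibble(ped)[ped$id %in% off, ]
  ages <- c(
    rows$birth_year - by[rows$sire],
    rows$birth_year - by[rows$dam]
  )
  ages <- ages[!is.na(ages)]
  if (length(ages) == 0) {
    abort("no parent-offspring pairs with known birth years")
  }
  mean(ages)
}

#' Realised selection intensity from a genetic trend
#'
#' Under the breeder's equation for a trait under truncation selection with
#' repeated records per individual, the realised selection intensity is
#'
#' `i = beta_G * L / (h * sigma_A * sqrt(n / (1 + (n - 1) * R)))`
#'
#' where `beta_G` is the per-annum rate of genetic improvement, `L` the
#' generation interval in years, `h` the square root of the heritability,
#' `sigma_A` the additive genetic standard deviation, `n` the mean number of
#' records per individual, and `R` the trait repeatability.  The square-root
#' term is the accuracy gain from averaging `n` repeated records.
#'
#' @param beta_G Genetic trend, trait units per year.
#' @param L Generation interval, years (> 0).
#' @param h Square root of heritability, in `[0, 1]`.
#' @param sigma_A Additive genetic standard deviation (>= 0).
#' @param n Mean number of records per individual (>= 1).
#' @param R Trait repeatability, in `[0, 1]`, with `h^2 <= R`.
#' @return The selection intensity `i` (standard-normal units).
#' @export
realised_intensity <- function(beta_G, L, h, sigma_A, n, R) {
  if (L <= 0) abort("L must be positive")
  if (h < 0 || h > 1) abort("h must be in [0, 1]")
  if (sigma_A < 0) abort("sigma_A must be non-negative")
  if (n < 1) abort("n must be >= 1")
  if (R < 0 || R > 1) abort("R must be in [0, 1]")
  if (h^2 > R + 1e-12) abort("repeatability cannot be below heritability")
  if (h * sigma_A == 0) {
    abort("h * sigma_A is zero; selection intensity is undefined")
  }
  beta_G * L / (h * sigma_A * sqrt(n / (1 + (n - 1) * R)))
}

#' Selection intensity of truncation selection at proportion p
#'
#' For truncation selection on a standard normal trait, selecting the top
#' proportion `p` gives mean selected deviation `i = phi(z) / p` with
#' `z = qnorm(1 - p)`.
#'
#' @param p Selected proportion in (0, 1).
#' @return The selection intensity.
#' @export
proportion_to_intensity <- function(p) {
  if (any(p <= 0 | p >= 1)) abort("p must be in (0, 1)")
  dnorm(qnorm(1 - p)) / p
}

#' Selected proportion implied by a selection intensity
#'
#' Inverts [proportion_to_intensity()] by bracketed root-finding on
#' `(1e-8, 1 - 1e-8)`; the function is strictly decreasing in `p`, so the
#' root is unique.
#'
#' @param i Selection intensity (> 0 and below the numerically attainable
#'   maximum, about 5.85 at `p = 1e-8`).
#' @param tol Root-finding tolerance in `p`.
#' @return The implied selected proportion (fraction of the population).
#' @export
#' @examples
#' intensity_to_proportion(1.202) # about 0.28
intensity_to_proportion <- function(i, tol = 1e-10) {
  if (i <= 0) abort("selection intensity must be positive")
  lo <- 1e-8
  hi <- 1 - 1e-8
  imax <- proportion_to_intensity(lo)
  if (i >= imax) {
    abort(paste0("intensity above attainable range (max ",
                 format(imax, digits = 6), " at p = 1e-8)"))
  }
  uniroot(function(p) proportion_to_intensity(p) - i,
          interval = c(lo, hi), tol = tol)$root
}

#' Realised selection intensity from fitted results
#'
#' Convenience wrapper assembling the inputs of [realised_intensity()] from
#' a REML fit, a trend, a pedigree and a record table: `L` from
#' [generation_interval()] over the phenotyped horses, `h`, `sigma_A` and
#' `R` from the variance components, `n` as the mean record count per
#' phenotyped horse, and `beta_G` from the trend.
#'
#' @param fit An `equigen_reml` fit.
#' @param trend An `equigen_trend`.
#' @param ped The pedigree.
#' @param records The record tibble the fit used.
#' @return A one-row tibble with the inputs, `i` and the implied selected
#'   proportion.
#' @export
selection_summary <- function(fit, trend, ped, records) {
  stopifnot(inherits(fit, "equigen_reml"), inherits(trend, "equigen_trend"))
  va <- fit$vc$variance[fit$vc$component == "V_A"]
  L <- generation_interval(ped, subset = fit$horse_ids)
  n_bar <- nrow(records) / length(unique(records$horse))
  i <- realised_intensity(
    beta_G = trend$beta_g, L = L, h = sqrt(fit$h2),
    sigma_A = sqrt(va), n = n_bar, R = fit$repeatability
  )
  tibble(
    beta_G = trend$beta_g, L = L, h2 = fit$h2, sigma_A = sqrt(va),
    n = n_bar, R = fit$repeatability, i = i,
    p_selected = if (i > 0) intensity_to_proportion(i) else NA_real_
  )
}
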