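#' Gene-drop breeding values down a pedigree
#'
#' Simulates neutral (no-selection) breeding values under the infinitesimal
#' model: founders and unknown-parent contributions are drawn from
#' `N(0, V_A)`, and each non-founder receives the mean of its known parents'
#' values plus a Mendelian sampling deviation with variance `d_i * V_A`,
#' where `d_i` is 1/2 minus the parental-inbreeding correction
#' (`d_i = 1/2 - (F_s + F_d)/4` with both parents known, `3/4 - F_p/4` with
#' one, 1 for founders).  The simulated values therefore have covariance
#' exactly `A * V_A`.
#'
#' @param ped A sorted pedigree.
#' @param V_A Additive genetic variance; a scalar, or a vector of length
#'   `n_sim` giving one variance per replicate.
#' @param F Optional precomputed inbreeding coefficients (pedigree order).
#' @param seed Optional integer seed.
#' @param n_sim Number of replicates.
#' @return For `n_sim = 1` a named vector of breeding values; otherwise a
#'   matrix (individuals by replicates) with ids as row names.
#' @export
gene_drop <- function(ped, V_A, F = NULL, seed = NULL, n_sim = 1) {
  ped <- ensure_sorted(ped)
  if (any(V_A < 0)) abort("V_A must be non-negative")
  if (!length(V_A) %in% c(1, n_sim)) {
    abort("V_A must have length 1 or n_sim")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  d <- mendelian_d(ped, F)
  pi <- parent_index(ped)
  va <- rep(V_A, length.out = n_sim)
  bv <- matrix(0, n, n_sim, dimnames = list(ped$id, NULL))
  for (i in seq_len(n)) {
    mu <- numeric(n_sim)
    if (!is.na(pi$sire[i])) mu <- mu + 0.5 * bv[pi$sire[i], ]
    if (!is.na(pi$dam[i])) mu <- mu + 0.5 * bv[pi$dam[i], ]
    bv[i, ] <- mu + rnorm(n_sim, 0, sqrt(d[i] * va))
  }
  if (n_sim == 1) bv[, 1] else bv
}

#' Test an estimated genetic trend against drift
#'
#' Temporal change in mean breeding value arises even under neutrality, so
#' a significant `P(beta_G > 0)` is not by itself evidence of selection.
#' This test simulates breeding values down the actual pedigree under no
#' selection (gene dropping), once per replicate with an additive variance
#' drawn from the posterior of V_A, computes for each replicate the
#' regression of cohort-mean simulated breeding value on birth year (over
#' the same individuals and year window as the observed trend), and pairs
#' each drift slope with an independent resample of the `beta_G` posterior.
#' `p_exceeds_drift` is the fraction of pairs in which the posterior draw of
#' `beta_G` exceeds the drift slope; selection is conventionally declared
#' when it exceeds 0.95.  Alternatively, `mode = "distribution"` compares
#' every `beta_G` draw against the whole drift-slope distribution.
#'
#' @param samples The `equigen_gibbs` fit providing the V_A posterior.
#' @param trend The `equigen_trend` (MCMC source) providing the `beta_G`
#'   posterior; must come from the same fit and pedigree.
#' @param ped The pedigree.
#' @param first,last Cohort window (defaults to the trend's window).
#' @param n_sim Number of gene-dropping replicates (>= 100).
#' @param seed Integer seed.
#' @param mode Pairing rule, see above.
#' @return An `equigen_drift` object with the drift slopes,
#'   `p_exceeds_drift`, `n_sim` and `seed`.
#' @export
run_drift_test <- function(samples, trend, ped, first = NULL, last = NULL,
                           n_sim = 1000, seed = 1,
                           mode = c("paired", "distribution")) {
  stopifnot(inherits(samples, "equigen_gibbs"),
            inherits(trend, "equigen_trend"))
  mode <- match.arg(mode)
  if (is.null(trend$draws)) {
    abort("trend must carry a beta_G posterior (MCMC source)")
  }
  if (n_sim < 100) abort("n_sim must be >= 100")
  ped <- ensure_sorted(ped)
  if (!identical(samples$ped_ids, ped$id)) {
    abort("samples and pedigree cover different individuals")
  }
  first <- first %||% trend$cohort_range[1]
  last <- last %||% trend$cohort_range[2]
  set.seed(seed)
  va_sim <- sample(samples$vc_draws[, "V_A"], n_sim, replace = TRUE)
  F <- inbreeding(ped)
  bv <- gene_drop(ped, va_sim, F = F, n_sim = n_sim)
  cm <- cohort_matrix(ped, first, last, trend$ids)
  means <- as.matrix(cm$M %*% bv)
  drift_slopes <- as.numeric(crossprod(means, ols_slope_weights(cm$years)))
  p <- if (mode == "paired") {
    bg <- sample(trend$draws, n_sim, replace = TRUE)
    mean(bg > drift_slopes)
  } else {
    ecdf_d <- stats::ecdf(drift_slopes)
    mean(ecdf_d(trend$draws))
  }
  structure(
    list(drift_slopes = drift_slopes, p_exceeds_drift = p,
         n_sim = n_sim, seed = seed, mode = mode,
         cohort_range = c(first, last)),
    class = "equigen_drift"
  )
}

#' @export
#' @method print equigen_drift
print.equigen_drift <- function(x, ...) {
  cat("# Gene-dropping drift test (", x$n_sim, " replicates, seed ",
      x$seed, ", ", x$mode, " comparison)\n", sep = "")
  cat(sprintf("drift slope SD = %.5f per year; P(beta_G > drift) = %.3f%s\n",
              sd(x$drift_slopes), x$p_exceeds_drift,
              if (x$p_exceeds_drift > 0.95) "  [exceeds drift]" else ""))
  invisible(x)
}

#' @export
tidy.equigen_drift <- function(x, ...) {
  tibble(replicate = seq_along(x$drift_slopes),
         drift_slope = x$drift_slopes)
}

#' @export
glance.equigen_drift <- function(x, ...) {
  tibble(p_exceeds_drift = x$p_exceeds_drift, n_sim = x$n_sim,
         drift_sd = sd(x$drift_slopes), seed = x$seed, mode = x$mode)
}
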