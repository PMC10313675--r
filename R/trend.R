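#' Kernel-density posterior mode
#'
#' Mode of a posterior sample located by a Gaussian-kernel density with
#' Silverman's rule-of-thumb bandwidth.
#'
#' @param x Numeric draws.
#' @return The abscissa of the density maximum.
#' @export
kde_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(unique(x)) == 1) return(x[1])
  d <- density(x, bw = "nrd0", kernel = "gaussian")
  d$x[which.max(d$y)]
}

#' Highest-density interval of a sample
#'
#' Shortest interval containing a `prob` fraction of the draws.
#'
#' @param x Numeric draws.
#' @param prob Coverage probability (default 0.95).
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  m <- max(1, floor(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  i <- which.min(x[(m + 1):n] - x[1:(n - m)])
  c(x[i], x[i + m])
}

#' Cohort means of predicted breeding values
#'
#' Arithmetic mean PBV by year of birth, over the supplied individuals born
#' in `[first, last]`.  Cohorts with no individuals are simply absent (a
#' message reports how many years were empty).
#'
#' @param pbv Named numeric vector of breeding values (names are ids).
#' @param ped The pedigree supplying birth years.
#' @param first,last First and last birth year (inclusive).
#' @param ids Individuals defining the cohorts; defaults to all names of
#'   `pbv`.  Pass the phenotyped ids to restrict cohorts to horses with
#'   records.
#' @return Tibble with columns `year`, `mean_pbv`, `n`.
#' @export
cohort_means <- function(pbv, ped, first, last, ids = NULL) {
  if (first > last) abort("first must be <= last")
  ids <- ids %||% names(pbv)
  ids <- intersect(ids, names(pbv))
  by <- setNames(ped$birth_year, ped$id)[ids]
  keep <- !is.na(by) & by >= first & by <= last
  if (!any(keep)) abort("no individuals with birth years in range")
  tab <- tibble(year = as.integer(by[keep]),
                pbv = unname(pbv[ids][keep])) |>
    group_by(.data$year) |>
    summarise(mean_pbv = mean(.data$pbv), n = dplyr::n(), .groups = "drop") |>
    arrange(.data$year)
  empty <- setdiff(first:last, tab$year)
  if (length(empty) > 0) {
    message(length(empty), " cohort year(s) without individuals omitted")
  }
  tab
}

#' Rate of genetic change from cohort means
#'
#' Ordinary least-squares slope of cohort mean breeding value on year of
#' birth.  Unweighted by default; set `weighted = TRUE` to weight cohorts by
#' size.
#'
#' @param cohort_table Output of [cohort_means()] (needs >= 3 cohorts).
#' @param weighted Weight cohorts by their size `n`.
#' @return The slope `beta_G` in trait units per year.
#' @export
estimate_beta_g <- function(cohort_table, weighted = FALSE) {
  if (nrow(cohort_table) < 3) abort("need at least 3 cohorts")
  w <- if (weighted) cohort_table$n else rep(1, nrow(cohort_table))
  fit <- lm(mean_pbv ~ year, data = cohort_table, weights = w)
  unname(coef(fit)[2])
}

cohort_matrix <- function(ped, first, last, ids) {
  by <- setNames(ped$birth_year, ped$id)[ids]
  keep <- !is.na(by) & by >= first & by <= last
  if (!any(keep)) abort("no individuals with birth years in range")
  years <- sort(unique(as.integer(by[keep])))
  idk <- ids[keep]
  M <- sparseMatrix(
    i = match(as.integer(by[keep]), years),
    j = match(idk, ped$id),
    x = 1, dims = c(length(years), nrow(ped))
  )
  M <- Diagonal(x = 1 / rowSums(M)) %*% M
  list(M = M, years = years)
}

ols_slope_weights <- function(years, weighted_n = NULL) {
  yc <- years - mean(years)
  yc / sum(yc^2)
}

#' Posterior of the genetic trend from MCMC breeding values
#'
#' For each retained draw of the breeding values, computes cohort means by
#' birth year and the OLS slope on year, giving a posterior for `beta_G`.
#' The point estimate is the kernel-density mode, the interval the 95%
#' highest-density interval, and `p_positive` the posterior probability that
#' `beta_G > 0` (a "significant" genetic trend is conventionally declared
#' when this exceeds 0.95).
#'
#' @param samples An `equigen_gibbs` fit with breeding-value draws.
#' @param ped The pedigree (for birth years).
#' @param first,last Cohort window (years of birth, inclusive).
#' @param ids Individuals defining the cohorts; defaults to the phenotyped
#'   horses of the fit.
#' @param beta_P Optional phenotypic trend (same units) for the
#'   `beta_G / beta_P` ratio.
#' @return An `equigen_trend` object.
#' @export
beta_g_posterior <- function(samples, ped, first, last, ids = NULL,
                             beta_P = NULL) {
  stopifnot(inherits(samples, "equigen_gibbs"))
  if (is.null(samples$bv_draws)) {
    abort("fit has no breeding-value draws (additive term absent)")
  }
  ped <- ensure_sorted(ped)
  if (!identical(samples$ped_ids, ped$id)) {
    abort("samples and pedigree cover different individuals")
  }
  ids <- ids %||% samples$horse_ids
  cm <- cohort_matrix(ped, first, last, ids)
  if (length(cm$years) < 3) abort("need at least 3 cohorts")
  cohort_draws <- tcrossprod(samples$bv_draws, as.matrix(cm$M))
  slopes <- as.numeric(cohort_draws %*% ols_slope_weights(cm$years))
  new_trend(
    beta_g = kde_mode(slopes), source = "MCMC", draws = slopes,
    interval = hpd_interval(slopes), p_positive = mean(slopes > 0),
    cohort_range = c(first, last), ids = ids, beta_P = beta_P,
    cohort_table = tibble(
      year = cm$years,
      mean_pbv = apply(cohort_draws, 2, kde_mode),
      lower = apply(cohort_draws, 2, function(v) hpd_interval(v)[1]),
      upper = apply(cohort_draws, 2, function(v) hpd_interval(v)[2])
    ),
    cohort_draws = cohort_draws
  )
}

#' Genetic trend from a REML fit
#'
#' Point estimate of `beta_G`: BLUP breeding values are averaged by birth
#' cohort and regressed on year.  No uncertainty is attached (REML breeding
#' values are treated as known); use [beta_g_posterior()] for full
#' uncertainty propagation.
#'
#' @param fit An `equigen_reml` fit.
#' @param ped The pedigree.
#' @param first,last Cohort window (birth years, inclusive).
#' @param ids Cohort individuals; defaults to the phenotyped horses.
#' @param beta_P Optional phenotypic trend for the ratio.
#' @return An `equigen_trend` object with `source = "REML"`.
#' @export
trend_from_reml <- function(fit, ped, first, last, ids = NULL,
                            beta_P = NULL) {
  stopifnot(inherits(fit, "equigen_reml"))
  if (is.null(fit$pbv)) abort("fit has no breeding values")
  ids <- ids %||% fit$horse_ids
  tab <- cohort_means(fit$pbv, ped, first, last, ids = ids)
  new_trend(
    beta_g = estimate_beta_g(tab), source = "REML", draws = NULL,
    interval = c(NA_real_, NA_real_), p_positive = NA_real_,
    cohort_range = c(first, last), ids = ids, beta_P = beta_P,
    cohort_table = tab, cohort_draws = NULL
  )
}

new_trend <- function(beta_g, source, draws, interval, p_positive,
                      cohort_range, ids, beta_P, cohort_table,
                      cohort_draws) {
  structure(
    list(
      beta_g = beta_g, source = source, draws = draws, interval = interval,
      p_positive = p_positive, cohort_range = cohort_range, ids = ids,
      beta_P = beta_P,
      ratio = if (!is.null(beta_P)) beta_g / beta_P else NULL,
      cohort_table = cohort_table, cohort_draws = cohort_draws
    ),
    class = "equigen_trend"
  )
}

#' @export
#' @method print equigen_trend
print.equigen_trend <- function(x, ...) {
  cat("# Genetic trend (", x$source, "), cohorts ",
      x$cohort_range[1], "-", x$cohort_range[2], "\n", sep = "")
  cat(sprintf("beta_G = %.5f per year", x$beta_g))
  if (!is.na(x$interval[1])) {
    cat(sprintf(" (95%% HPD %.5f, %.5f; P(beta_G > 0) = %.3f)",
                x$interval[1], x$interval[2], x$p_positive))
  }
  cat("\n")
  if (!is.null(x$ratio)) {
    cat(sprintf("beta_G / beta_P = %.3f (beta_P = %.5f supplied)\n",
                x$ratio, x$beta_P))
  }
  invisible(x)
}

#' @export
tidy.equigen_trend <- function(x, ...) x$cohort_table

#' @export
glance.equigen_trend <- function(x, ...) {
  tibble(
    beta_g = x$beta_g, source = x$source,
    lower = x$interval[1], upper = x$interval[2],
    p_positive = x$p_positive,
    first = x$cohort_range[1], last = x$cohort_range[2],
    beta_P = x$beta_P %||% NA_real_,
    ratio = x$ratio %||% NA_real_
  )
}

#' Plot a genetic trend
#'
#' Cohort point estimates of mean breeding value by birth year with 95%
#' intervals; for MCMC trends a grey spaghetti of per-draw cohort
#' trajectories (a subsample) shows the posterior spread.
#'
#' @param object An `equigen_trend`.
#' @param n_spaghetti Number of posterior trajectories to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.equigen_trend <- function(object, n_spaghetti = 100, ...) {
  tab <- object$cohort_table
  g <- ggplot(tab, aes(x = .data$year, y = .data$mean_pbv))
  if (!is.null(object$cohort_draws)) {
    nd <- min(n_spaghetti, nrow(object$cohort_draws))
    idx <- round(seq(1, nrow(object$cohort_draws), length.out = nd))
    sub <- object$cohort_draws[idx, , drop = FALSE]
    sp <- tibble(
      draw = rep(seq_len(nd), times = ncol(sub)),
      year = rep(tab$year, each = nd),
      mean_pbv = as.numeric(sub)
    )
    g <- g + geom_line(data = sp,
                       aes(group = .data$draw), colour = "grey80",
                       linewidth = 0.2)
  }
  if ("lower" %in% names(tab)) {
    g <- g + geom_errorbar(aes(ymin = .data$lower, ymax = .data$upper),
                           width = 0.2)
  }
  g + geom_point() +
    labs(x = "Year of birth", y = "Mean predicted breeding value",
         title = paste0("Genetic trend (", object$source, "): beta_G = ",
                        signif(object$beta_g, 3), " per year"))
}
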