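#' Plan an MCMC chain
#'
#' Book-keeping for a Gibbs chain: with `n_iter` total iterations, a burn-in
#' of `burn_in` and a thinning interval of `thin`, the retained posterior
#' has `floor((n_iter - burn_in) / thin)` samples (iterations
#' `burn_in + thin`, `burn_in + 2 thin`, ...).
#'
#' @param n_iter Total iterations (must exceed `burn_in`).
#' @param burn_in Burn-in iterations discarded from the front.
#' @param thin Thinning interval (>= 1).
#' @return A list with `n_iter`, `burn_in`, `thin`, `n_retained`.
#' @export
#' @examples
#' chain_plan(2e6, 8e5, 1200)$n_retained # 1000
chain_plan <- function(n_iter, burn_in, thin = 1) {
  if (n_iter <= burn_in) abort("n_iter must exceed burn_in")
  if (thin < 1) abort("thin must be >= 1")
  list(n_iter = as.numeric(n_iter), burn_in = as.numeric(burn_in),
       thin = as.numeric(thin),
       n_retained = floor((n_iter - burn_in) / thin))
}

#' Prior for variance components
#'
#' Inverse-Wishart prior in the univariate parameterisation used by common
#' animal-model MCMC software: each variance has a scaled inverse
#' chi-squared prior with belief parameter `nu` and scale `V`, i.e.
#' `sigma^2 ~ nu V / chi2_nu`.  The default `nu = 0.002`, `V = 1` is the
#' conventional weakly informative choice.
#'
#' @param nu Degree-of-belief parameter.
#' @param V Prior scale.
#' @return A list with `nu` and `V`.
#' @export
gibbs_prior <- function(nu = 0.002, V = 1) {
  list(nu = nu, V = V)
}

#' Fit the animal model by Gibbs-sampling MCMC
#'
#' Blocked Gibbs sampler for the same model as [fit_reml()].  Each iteration
#' draws (1) the full location vector (fixed effects and all random effect
#' vectors jointly) from its multivariate normal full conditional via a
#' sparse Cholesky factorisation of the mixed-model equations, and (2) each
#' variance from its scaled inverse chi-squared full conditional,
#' `(S + nu V) / chi2_{q + nu}` where S is the relevant quadratic form
#' (`a' A^-1 a` for the additive term, sums of squares otherwise).  The
#' chain is fully reproducible given `seed`.
#'
#' @param design An [build_design()] result.
#' @param ped The pedigree used to build the design.
#' @param chain A [chain_plan()].
#' @param prior A [gibbs_prior()].
#' @param seed Integer seed for the chain.
#' @param random Random terms to include.
#' @return An `equigen_gibbs` object with `vc_draws` (retained draws by
#'   component, columns `V_A`, `V_PE`, `V_T`, `V_R` as applicable),
#'   `bv_draws` (retained draws by pedigree individual) and `chain`
#'   metadata.
#' @export
fit_gibbs <- function(design, ped, chain = chain_plan(6000, 1000, 5),
                      prior = gibbs_prior(), seed = 1,
                      random = c("additive", "pe", "trainer")) {
  ped <- ensure_sorted(ped)
  setup <- mm_setup(design, ped, random)
  k <- length(setup$terms)
  n <- setup$n
  ncols <- ncol(setup$W)
  set.seed(seed)

  vars <- rep(var(setup$y) / (k + 1), k + 1)
  names(vars) <- c(names(setup$terms), "residual")
  nret <- chain$n_retained
  if (nret < 1) abort("chain plan retains no samples")
  vc_draws <- matrix(NA_real_, nret, k + 1,
                     dimnames = list(NULL, vc_label(names(vars))))
  qa <- if ("additive" %in% names(setup$terms)) setup$terms$additive$q else 0
  bv_draws <- if (qa > 0) matrix(NA_real_, nret, qa,
                                 dimnames = list(NULL, design$ped_ids))
  ridx <- 0L

  for (iter in seq_len(chain$n_iter)) {
    sigma2 <- setNames(as.list(vars[seq_len(k)]), names(setup$terms))
    C <- mm_C(setup, sigma2, vars[k + 1])
    ch <- Matrix::update(setup$chol, C)
    m <- solve(ch, setup$Wty / vars[k + 1], system = "A")
    z <- rnorm(ncols)
    dev <- solve(ch, solve(ch, z, system = "Lt"), system = "Pt")
    theta <- as.numeric(m) + as.numeric(dev)

    for (i in seq_len(k)) {
      t <- setup$terms[[i]]
      u <- theta[term_slice(setup, i)]
      S <- as.numeric(crossprod(u, t$Kinv %*% u))
      vars[i] <- (S + prior$nu * prior$V) / rchisq(1, df = t$q + prior$nu)
    }
    e <- setup$y - as.numeric(setup$W %*% theta)
    vars[k + 1] <- (sum(e^2) + prior$nu * prior$V) /
      rchisq(1, df = n + prior$nu)
    if (any(!is.finite(vars)) || any(vars <= 0)) {
      abort(paste0("divergent chain at iteration ", iter,
                   ": variance draw not finite/positive (",
                   paste(sprintf("%s=%.3g", names(vars), vars),
                         collapse = ", "), ")"))
    }

    past_burn <- iter - chain$burn_in
    if (past_burn > 0 && past_burn %% chain$thin == 0 && ridx < nret) {
      ridx <- ridx + 1L
      vc_draws[ridx, ] <- vars
      if (qa > 0) {
        ia <- which(names(setup$terms) == "additive")
        bv_draws[ridx, ] <- theta[term_slice(setup, ia)]
      }
    }
  }

  structure(
    list(
      vc_draws = vc_draws[seq_len(ridx), , drop = FALSE],
      bv_draws = if (qa > 0) bv_draws[seq_len(ridx), , drop = FALSE],
      chain = c(chain, list(seed = seed, prior = prior)),
      ped_ids = design$ped_ids,
      horse_ids = design$horse_ids,
      model = design$spec$name
    ),
    class = "equigen_gibbs"
  )
}

#' @export
#' @method print equigen_gibbs
print.equigen_gibbs <- function(x, ...) {
  cat("# Animal model (Model ", x$model, ") fitted by Gibbs MCMC: ",
      nrow(x$vc_draws), " retained draws (n_iter ", x$chain$n_iter,
      ", burn-in ", x$chain$burn_in, ", thin ", x$chain$thin,
      ", seed ", x$chain$seed, ")\n", sep = "")
  print(as.data.frame(tidy(x)), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.equigen_gibbs <- function(x, ...) {
  draws <- x$vc_draws
  vp <- rowSums(draws)
  h2 <- if ("V_A" %in% colnames(draws)) draws[, "V_A"] / vp else NULL
  all_draws <- cbind(draws, V_P = vp)
  if (!is.null(h2)) all_draws <- cbind(all_draws, h2 = h2)
  tibble(
    component = colnames(all_draws),
    mean = colMeans(all_draws),
    mode = apply(all_draws, 2, kde_mode),
    lower = apply(all_draws, 2, function(v) hpd_interval(v)[1]),
    upper = apply(all_draws, 2, function(v) hpd_interval(v)[2])
  )
}

#' @export
glance.equigen_gibbs <- function(x, ...) {
  tibble(
    n_retained = nrow(x$vc_draws), n_iter = x$chain$n_iter,
    burn_in = x$chain$burn_in, thin = x$chain$thin, seed = x$chain$seed
  )
}

# ---- chain diagnostics -----------------------------------------------------

# Asymptotic distribution function of the Cramer-von Mises statistic
# (series expansion; standard in MCMC stationarity testing).
pcramer <- function(q, eps = 1e-5) {
  log_eps <- log(eps)
  y <- matrix(0, nrow = 4, ncol = length(q))
  for (kk in 0:3) {
    z <- gamma(kk + 0.5) * sqrt(4 * kk + 1) /
      (gamma(kk + 1) * pi^(3 / 2) * sqrt(q))
    u <- (4 * kk + 1)^2 / (16 * q)
    y[kk + 1, ] <- ifelse(u > -log_eps, 0,
                          z * exp(-u) * besselK(x = u, nu = 1 / 4))
  }
  colSums(y)
}

# Spectral density of a chain at frequency zero, via an AIC-selected AR fit.
spectrum0_ar <- function(x) {
  x <- as.numeric(x)
  if (var(x) == 0) return(0)
  fit <- try(ar(x, aic = TRUE,
                order.max = min(30, floor(length(x) / 4))), silent = TRUE)
  if (inherits(fit, "try-error")) return(var(x))
  if (fit$order == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Heidelberger-Welch stationarity test for one chain
#'
#' Cramer-von Mises test on the standardised cumulative sums of the chain,
#' applied to the full chain and then iteratively after discarding the
#' initial 10%, 20%, ... up to 50%.  The chain passes if some window with
#' at most half the draws discarded is consistent with stationarity at the
#' given level.  The long-run variance is estimated from the second half of
#' the chain via the spectral density at zero.
#'
#' @param x Numeric chain of retained draws.
#' @param pvalue Significance level (default 0.05).
#' @return A list: `p_value` (at the first passing window, or the last
#'   tested), `passed`, `frac_discarded`.  A constant chain passes with
#'   `p_value = NA`.
#' @export
heidel_stationarity <- function(x, pvalue = 0.05) {
  x <- as.numeric(x)
  n_all <- length(x)
  if (n_all < 50) abort("need at least 50 draws for a stationarity test")
  if (var(x) == 0) {
    return(list(p_value = NA_real_, passed = TRUE, frac_discarded = 0))
  }
  s0 <- spectrum0_ar(x[(n_all %/% 2 + 1):n_all])
  if (!is.finite(s0) || s0 <= 0) s0 <- var(x)
  p_last <- NA_real_
  for (frac in seq(0, 0.5, by = 0.1)) {
    y <- x[(floor(frac * n_all) + 1):n_all]
    ny <- length(y)
    B <- cumsum(y) - mean(y) * seq_len(ny)
    cvm <- sum(B^2 / (ny * s0)) / ny
    p_last <- 1 - pcramer(cvm)
    if (p_last > pvalue) {
      return(list(p_value = p_last, passed = TRUE, frac_discarded = frac))
    }
  }
  list(p_value = p_last, passed = FALSE, frac_discarded = 0.5)
}

#' MCMC convergence diagnostics
#'
#' Per-component Heidelberger-Welch stationarity p-value and lag-1
#' autocorrelation of the retained draws, with pass flags at `p > 0.05` and
#' `|autocorrelation| < 0.1`.  A constant chain has undefined
#' autocorrelation (reported as `NA`, pass) and passes stationarity.
#'
#' @param samples An `equigen_gibbs` object, or a matrix of retained draws.
#' @param pvalue Stationarity significance level.
#' @param max_autocorr Autocorrelation pass threshold.
#' @return A tibble with one row per component.
#' @export
diagnostics <- function(samples, pvalue = 0.05, max_autocorr = 0.1) {
  draws <- if (inherits(samples, "equigen_gibbs")) {
    samples$vc_draws
  } else {
    as.matrix(samples)
  }
  if (nrow(draws) < 50) abort("need at least 50 retained draws")
  if (is.null(colnames(draws))) {
    colnames(draws) <- paste0("chain", seq_len(ncol(draws)))
  }
  res <- lapply(colnames(draws), function(nm) {
    x <- draws[, nm]
    st <- heidel_stationarity(x, pvalue)
    rho <- if (var(x) == 0) {
      NA_real_
    } else {
      as.numeric(acf(x, lag.max = 1, plot = FALSE)$acf[2])
    }
    tibble(
      component = nm,
      stationarity_p = st$p_value,
      frac_discarded = st$frac_discarded,
      stationary = st$passed,
      autocorr_lag1 = rho,
      autocorr_ok = is.na(rho) || abs(rho) < max_autocorr
    )
  })
  bind_rows(res)
}
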