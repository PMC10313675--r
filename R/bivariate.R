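#' Genetic correlation between two traits by bivariate Gibbs sampling
#'
#' Fits a two-trait animal model to two record sets sharing one pedigree
#' (e.g. speed in two race-distance categories).  The additive genetic
#' effects of the two traits have covariance `Sigma_A (x) A` with an
#' unstructured 2x2 `Sigma_A`.  Permanent-environment effects likewise
#' carry an unstructured 2x2 covariance over the union of phenotyped
#' horses by default (`pe_covariance = "unstructured"`): without a
#' non-genetic cross-trait pathway, any between-trait covariance of
#' repeated-record horses is forced through the genetic component and the
#' genetic correlation is biased towards one whenever the additive /
#' permanent-environment split is weakly identified.  A diagonal PE
#' restriction is available.  Trainer effects are independent across
#' traits, and the residual covariance between traits is zero (records for
#' different traits come from different races).
#'
#' Each iteration samples the full location vector from its Gaussian full
#' conditional via a sparse Cholesky factorisation, the 2x2 covariance
#' matrices from their inverse-Wishart full conditionals
#' (`IW(nu + q, S + nu I)` with `S` the relevant cross-product), and the
#' remaining variances from scaled inverse chi-squared full conditionals.
#' The genetic correlation draw is
#' `r_G = Sigma_12 / sqrt(Sigma_11 Sigma_22)`; the point estimate is the
#' kernel-density posterior mode with a 95% highest-density interval.
#'
#' @param design1,design2 [build_design()] results for the two traits,
#'   built against the same pedigree.
#' @param ped The shared pedigree.
#' @param chain A [chain_plan()].
#' @param nu Inverse-Wishart degree of belief for the 2x2 covariance
#'   blocks (default `0.002 * 2`); univariate components use `nu = 0.002`.
#' @param pe_covariance `"unstructured"` (default) or `"diagonal"`
#'   cross-trait permanent-environment covariance.
#' @param seed Integer seed.
#' @return An `equigen_rg` object: `r_G`, `interval`, `rg_draws`, per-trait
#'   additive variance summaries and chain metadata.
#' @export
fit_bivariate_gibbs <- function(design1, design2, ped,
                                chain = chain_plan(4000, 1000, 3),
                                nu = 0.004,
                                pe_covariance = c("unstructured",
                                                  "diagonal"),
                                seed = 1) {
  pe_covariance <- match.arg(pe_covariance)
  ped <- ensure_sorted(ped)
  for (d in list(design1, design2)) {
    if (!identical(d$ped_ids, ped$id)) {
      abort("both designs must be built against the shared pedigree")
    }
  }
  shared <- intersect(design1$horse_ids, design2$horse_ids)
  if (length(shared) == 0) {
    anc1 <- trim_pedigree(ped, design1$horse_ids)$id
    anc2 <- trim_pedigree(ped, design2$horse_ids)$id
    if (length(intersect(anc1, anc2)) == 0) {
      abort(paste0("no cross-classified individuals and no shared ",
                   "ancestry between trait record sets; ",
                   "r_G is unidentifiable"))
    }
  }

  Ainv <- ainverse(ped)
  q <- nrow(ped)
  pe_ids <- sort(union(design1$horse_ids, design2$horse_ids))
  nU <- length(pe_ids)
  dims <- c(
    p1 = design1$p, p2 = design2$p, a1 = q, a2 = q,
    pe1 = nU, pe2 = nU,
    t1 = length(design1$trainer_ids), t2 = length(design2$trainer_ids)
  )
  off <- cumsum(c(0, dims))
  slice <- function(k) (off[k] + 1):off[k + 1]
  ncols <- sum(dims)
  z0 <- function(n, k) sparseMatrix(i = integer(0), j = integer(0),
                                    dims = c(n, k))
  n1 <- design1$n
  n2 <- design2$n
  # permanent-environment incidence over the union horse set
  pe_map1 <- match(design1$horse_ids, pe_ids)
  pe_map2 <- match(design2$horse_ids, pe_ids)
  Zpe1 <- design1$Z$pe %*%
    sparseMatrix(i = seq_along(pe_map1), j = pe_map1, x = 1,
                 dims = c(length(pe_map1), nU))
  Zpe2 <- design2$Z$pe %*%
    sparseMatrix(i = seq_along(pe_map2), j = pe_map2, x = 1,
                 dims = c(length(pe_map2), nU))
  W1 <- cbind(design1$X, z0(n1, dims["p2"]), design1$Z$additive,
              z0(n1, q), Zpe1, z0(n1, nU),
              design1$Z$trainer, z0(n1, dims["t2"]))
  W2 <- cbind(z0(n2, dims["p1"]), design2$X, z0(n2, q),
              design2$Z$additive, z0(n2, nU), Zpe2,
              z0(n2, dims["t1"]), design2$Z$trainer)
  M1 <- forceSymmetric(crossprod(W1))
  M2 <- forceSymmetric(crossprod(W2))
  Wty1 <- as.numeric(crossprod(W1, design1$y))
  Wty2 <- as.numeric(crossprod(W2, design2$y))

  nu1 <- 0.002
  set.seed(seed)
  vy <- c(var(design1$y), var(design2$y))
  Sigma <- diag(vy / 4)
  Spe <- diag(vy / 4)
  vt <- vy / 4
  ve <- vy / 4
  Ipe <- Diagonal(nU)

  build_C <- function() {
    Sinv <- solve(Sigma)
    Gad <- rbind(
      cbind(Sinv[1, 1] * Ainv, Sinv[1, 2] * Ainv),
      cbind(Sinv[2, 1] * Ainv, Sinv[2, 2] * Ainv)
    )
    Pinv <- solve(Spe)
    Gpe <- rbind(
      cbind(Pinv[1, 1] * Ipe, Pinv[1, 2] * Ipe),
      cbind(Pinv[2, 1] * Ipe, Pinv[2, 2] * Ipe)
    )
    Gprior <- bdiag(
      Diagonal(dims["p1"] + dims["p2"], x = 0), Gad, Gpe,
      Diagonal(dims["t1"], x = 1 / vt[1]),
      Diagonal(dims["t2"], x = 1 / vt[2])
    )
    forceSymmetric(M1 / ve[1] + M2 / ve[2] + Gprior)
  }
  ch_sym <- Cholesky(build_C(), LDL = FALSE, perm = TRUE)

  nret <- chain$n_retained
  if (nret < 1) abort("chain plan retains no samples")
  rg_draws <- numeric(nret)
  rpe_draws <- numeric(nret)
  va_draws <- matrix(NA_real_, nret, 2,
                     dimnames = list(NULL, c("V_A1", "V_A2")))
  ridx <- 0L

  draw_iw <- function(S, df, scale_prior) {
    scale_post <- S + scale_prior
    Wd <- rWishart(1, df = df, Sigma = solve(scale_post))[, , 1]
    out <- solve(Wd)
    (out + t(out)) / 2
  }

  for (iter in seq_len(chain$n_iter)) {
    C <- build_C()
    ch <- Matrix::update(ch_sym, C)
    rhs <- Wty1 / ve[1] + Wty2 / ve[2]
    m <- solve(ch, rhs, system = "A")
    z <- rnorm(ncols)
    dev <- solve(ch, solve(ch, z, system = "Lt"), system = "Pt")
    theta <- as.numeric(m) + as.numeric(dev)

    U <- cbind(theta[slice(3)], theta[slice(4)])
    Sigma <- draw_iw(as.matrix(crossprod(U, Ainv %*% U)),
                     df = q + nu, scale_prior = nu * diag(2))
    P <- cbind(theta[slice(5)], theta[slice(6)])
    if (pe_covariance == "unstructured") {
      Spe <- draw_iw(crossprod(P), df = nU + nu,
                     scale_prior = nu * diag(2))
    } else {
      Spe <- diag(c(
        (sum(P[, 1]^2) + nu1) / rchisq(1, df = nU + nu1),
        (sum(P[, 2]^2) + nu1) / rchisq(1, df = nU + nu1)
      ))
    }
    for (k in 1:2) {
      tk <- theta[slice(6 + k)]
      vt[k] <- (sum(tk^2) + nu1) / rchisq(1, df = length(tk) + nu1)
    }
    e1 <- design1$y - as.numeric(W1 %*% theta)
    e2 <- design2$y - as.numeric(W2 %*% theta)
    ve[1] <- (sum(e1^2) + nu1) / rchisq(1, df = n1 + nu1)
    ve[2] <- (sum(e2^2) + nu1) / rchisq(1, df = n2 + nu1)
    if (any(!is.finite(c(Sigma, Spe, vt, ve)))) {
      abort(paste0("divergent bivariate chain at iteration ", iter))
    }

    past <- iter - chain$burn_in
    if (past > 0 && past %% chain$thin == 0 && ridx < nret) {
      ridx <- ridx + 1L
      rg_draws[ridx] <- Sigma[1, 2] / sqrt(Sigma[1, 1] * Sigma[2, 2])
      rpe_draws[ridx] <- Spe[1, 2] / sqrt(Spe[1, 1] * Spe[2, 2])
      va_draws[ridx, ] <- diag(Sigma)
    }
  }

  rg_draws <- rg_draws[seq_len(ridx)]
  va_draws <- va_draws[seq_len(ridx), , drop = FALSE]
  structure(
    list(
      r_G = kde_mode(rg_draws),
      interval = hpd_interval(rg_draws),
      rg_draws = rg_draws,
      r_PE_draws = rpe_draws[seq_len(ridx)],
      va = tibble(
        trait = c(1, 2),
        V_A_mean = colMeans(va_draws),
        V_A_lower = apply(va_draws, 2, function(v) hpd_interval(v)[1]),
        V_A_upper = apply(va_draws, 2, function(v) hpd_interval(v)[2])
      ),
      va_draws = va_draws,
      pe_covariance = pe_covariance,
      chain = c(chain, list(seed = seed, nu = nu))
    ),
    class = "equigen_rg"
  )
}

#' @export
#' @method print equigen_rg
print.equigen_rg <- function(x, ...) {
  cat("# Bivariate animal model (Gibbs MCMC), ",
      length(x$rg_draws), " retained draws, ", x$pe_covariance,
      " PE covariance\n", sep = "")
  cat(sprintf("r_G = %.3f (95%% HPD %.3f, %.3f)\n",
              x$r_G, x$interval[1], x$interval[2]))
  invisible(x)
}

#' @export
glance.equigen_rg <- function(x, ...) {
  tibble(r_G = x$r_G, lower = x$interval[1], upper = x$interval[2],
         n_retained = length(x$rg_draws), seed = x$chain$seed)
}
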