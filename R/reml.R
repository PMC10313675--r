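#' Control parameters for REML fitting
#'
#' @param max_iter Maximum likelihood evaluations for the optimiser.
#' @param reltol Relative tolerance on the restricted log-likelihood; the
#'   fit is declared converged when the optimiser's relative improvement
#'   falls below this (default well inside 1e-8).
#' @param bound_frac A variance component below `bound_frac * V_P` is
#'   flagged as pinned at the boundary.
#' @return A list of control values.
#' @export
reml_control <- function(max_iter = 2000, reltol = 1e-10,
                         bound_frac = 1e-8) {
  list(max_iter = max_iter, reltol = reltol, bound_frac = bound_frac)
}

# Assemble the building blocks shared by the REML and Gibbs engines:
# W = [X | Z_terms], its cross-products, and the per-term prior precision
# structures (A^-1 for the additive term, identity for the others).
mm_setup <- function(design, ped, random) {
  stopifnot(inherits(design, "equigen_design"))
  random <- match.arg(random, c("additive", "pe", "trainer"),
                      several.ok = TRUE)
  if (!identical(design$ped_ids, ped$id)) {
    abort("design and pedigree are inconsistent (different individuals)")
  }
  terms <- list()
  if ("additive" %in% random) {
    Ainv <- ainverse(ped)
    terms$additive <- list(Z = design$Z$additive, Kinv = Ainv,
                           logdet = attr(Ainv, "logdet"),
                           q = ncol(design$Z$additive))
  }
  if ("pe" %in% random) {
    terms$pe <- list(Z = design$Z$pe, Kinv = Diagonal(ncol(design$Z$pe)),
                     logdet = 0, q = ncol(design$Z$pe))
  }
  if ("trainer" %in% random) {
    terms$trainer <- list(Z = design$Z$trainer,
                          Kinv = Diagonal(ncol(design$Z$trainer)),
                          logdet = 0, q = ncol(design$Z$trainer))
  }
  W <- do.call(cbind, c(list(design$X), lapply(terms, `[[`, "Z")))
  y <- design$y
  p <- ncol(design$X)
  setup <- list(
    W = W, WtW = forceSymmetric(crossprod(W)),
    Wty = as.numeric(crossprod(W, y)), yty = sum(y^2),
    y = y, n = length(y), p = p, terms = terms,
    offsets = cumsum(c(p, vapply(terms, `[[`, 0, "q")))
  )
  # symmetric prior-precision template with constant sparsity pattern
  blocks <- c(list(Diagonal(p, x = 0)), lapply(terms, `[[`, "Kinv"))
  setup$Gtemplate <- forceSymmetric(bdiag(blocks))
  C0 <- forceSymmetric(setup$WtW + setup$Gtemplate +
                         Diagonal(ncol(W), x = 1))
  setup$chol <- Cholesky(C0, LDL = FALSE, perm = TRUE)
  setup
}

# indices of each random term's slice of the solution vector
term_slice <- function(setup, k) {
  (setup$offsets[k] + 1):setup$offsets[k + 1]
}

mm_C <- function(setup, sigma2, sigma2_e) {
  blocks <- c(
    list(Diagonal(setup$p, x = 0)),
    purrr::imap(setup$terms, function(t, nm) t$Kinv / sigma2[[nm]])
  )
  forceSymmetric(setup$WtW / sigma2_e + bdiag(blocks))
}

# Restricted log-likelihood evaluated through the mixed-model equations:
# -2 logL_R = (n - p) log(2 pi) + log|R| + log|G| + log|C| + y'Py
mm_loglik <- function(setup, sigma2, sigma2_e) {
  C <- mm_C(setup, sigma2, sigma2_e)
  ch <- Matrix::update(setup$chol, C)
  rhs <- setup$Wty / sigma2_e
  sol <- as.numeric(solve(ch, rhs, system = "A"))
  yPy <- (setup$yty - sum(sol * setup$Wty)) / sigma2_e
  logdetC <- 2 * as.numeric(determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
  logG <- sum(vapply(names(setup$terms), function(nm) {
    t <- setup$terms[[nm]]
    t$q * log(sigma2[[nm]]) + t$logdet
  }, 0))
  logR <- setup$n * log(sigma2_e)
  ll <- -0.5 * ((setup$n - setup$p) * log(2 * pi) +
                  logR + logG + logdetC + yPy)
  list(loglik = unname(as.numeric(ll)), sol = sol, chol = ch)
}

#' Fit the animal model by REML
#'
#' Maximises the restricted log-likelihood of the mixed model
#' `y = X b + Z_a a + Z_pe p + Z_t t + e`, with `a ~ N(0, A V_A)`,
#' `p ~ N(0, I V_PE)`, `t ~ N(0, I V_T)` and `e ~ N(0, I V_R)`, where A is
#' the pedigree numerator relationship matrix.  Each likelihood evaluation
#' solves the mixed-model equations with a sparse Cholesky factorisation
#' (A enters through its sparse inverse); the likelihood is maximised over
#' log-variances by Nelder-Mead, which is robust when components approach
#' the zero boundary.  Breeding values (BLUP) and fixed-effect solutions are
#' recovered at the converged components, and standard errors come from the
#' inverse of the observed information (numerical Hessian on the variance
#' scale) with a delta-method standard error for the heritability.
#'
#' @param design An [build_design()] result.
#' @param ped The pedigree used to build the design.
#' @param random Random terms to include; dropping `"additive"` gives the
#'   reduced model used in the likelihood-ratio test of V_A.
#' @param opts A [reml_control()] list.
#' @param se Compute standard errors (numerical Hessian; disable for speed
#'   in simulations).
#' @return An `equigen_reml` object: variance components with standard
#'   errors, heritability `h2`, repeatability, fixed effects, predicted
#'   breeding values `pbv` for every pedigree individual, restricted
#'   log-likelihood, convergence flag and evaluation count.
#' @export
fit_reml <- function(design, ped, random = c("additive", "pe", "trainer"),
                     opts = reml_control(), se = TRUE) {
  ped <- ensure_sorted(ped)
  setup <- mm_setup(design, ped, random)
  k <- length(setup$terms)
  vp0 <- var(setup$y)
  par0 <- log(rep(vp0 / (k + 1), k + 1))

  # components are bounded below at a tiny fraction of the phenotypic
  # variance so the likelihood stays defined on the boundary
  lo <- log(1e-10 * vp0)
  nll <- function(par) {
    par <- pmax(par, lo)
    sigma2 <- setNames(as.list(exp(par[seq_len(k)])), names(setup$terms))
    out <- tryCatch(
      -mm_loglik(setup, sigma2, exp(par[k + 1]))$loglik,
      error = function(e) Inf
    )
    if (!is.finite(out)) 1e10 else out
  }
  opt <- optim(par0, nll, method = "Nelder-Mead",
               control = list(maxit = opts$max_iter,
                              reltol = opts$reltol))
  vars <- exp(pmax(opt$par, lo))
  names(vars) <- c(names(setup$terms), "residual")
  # final solve; if a component sits on the numerical boundary, lift it
  # just enough for the factorisation to succeed
  fit <- NULL
  floor_v <- 1e-10 * vp0
  for (attempt in 1:6) {
    sigma2 <- setNames(as.list(pmax(vars[seq_len(k)], floor_v)),
                       names(setup$terms))
    fit <- tryCatch(
      mm_loglik(setup, sigma2, max(vars[k + 1], floor_v)),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
    floor_v <- floor_v * 100
  }
  if (is.null(fit)) abort("mixed-model equations could not be factorised")
  vars <- pmax(vars, floor_v / 100)

  vp <- sum(vars)
  boundary <- vars < opts$bound_frac * vp
  if (any(boundary)) {
    message("variance component(s) at lower boundary: ",
            paste(names(vars)[boundary], collapse = ", "))
  }

  ses <- rep(NA_real_, k + 1)
  h2_se <- NA_real_
  vcov_vc <- NULL
  if (se) {
    f_v <- function(v) {
      s2 <- setNames(as.list(v[seq_len(k)]), names(setup$terms))
      -mm_loglik(setup, s2, v[k + 1])$loglik
    }
    H <- try(pracma::hessian(f_v, vars), silent = TRUE)
    if (!inherits(H, "try-error")) {
      Vmat <- try(solve(H), silent = TRUE)
      if (!inherits(Vmat, "try-error") && all(diag(Vmat) > 0)) {
        vcov_vc <- Vmat
        ses <- sqrt(diag(Vmat))
        if ("additive" %in% names(setup$terms)) {
          ia <- which(names(vars) == "additive")
          g <- -vars[ia] / vp^2 + ifelse(seq_along(vars) == ia, 1 / vp, 0)
          h2_se <- sqrt(drop(t(g) %*% Vmat %*% g))
        }
      }
    }
  }

  sol <- fit$sol
  fixed <- tibble(term = design$labels, estimate = sol[seq_len(setup$p)])
  pbv <- NULL
  u <- list()
  for (i in seq_along(setup$terms)) {
    u[[names(setup$terms)[i]]] <- sol[term_slice(setup, i)]
  }
  if ("additive" %in% names(u)) {
    pbv <- setNames(u$additive, design$ped_ids)
  }

  h2 <- if ("additive" %in% names(vars)) unname(vars["additive"] / vp) else 0
  rep_r <- unname(sum(vars[names(vars) %in% c("additive", "pe")]) / vp)

  structure(
    list(
      vc = tibble(
        component = vc_label(names(vars)),
        variance = unname(vars),
        se = ses
      ),
      V_P = vp, h2 = h2, h2_se = h2_se, repeatability = rep_r,
      fixed_effects = fixed, pbv = pbv, u = u,
      loglik = fit$loglik, converged = opt$convergence == 0,
      n_iter = unname(opt$counts[1]), boundary = boundary,
      vcov_vc = vcov_vc,
      random = names(setup$terms),
      n = setup$n, p = setup$p,
      model = design$spec$name,
      horse_ids = design$horse_ids
    ),
    class = "equigen_reml"
  )
}

vc_label <- function(nm) {
  map <- c(additive = "V_A", pe = "V_PE", trainer = "V_T",
           residual = "V_R")
  unname(map[nm])
}

#' @export
#' @method print equigen_reml
print.equigen_reml <- function(x, ...) {
  cat("# Animal model (Model ", x$model, ") fitted by REML\n", sep = "")
  cat("#  records: ", x$n, ", fixed-effect columns: ", x$p,
      ", logLik: ", format(x$loglik, digits = 8),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  print(as.data.frame(x$vc), row.names = FALSE)
  cat(sprintf("h2 = %.4f (se %.4f), repeatability = %.4f, V_P = %.5f\n",
              x$h2, x$h2_se, x$repeatability, x$V_P))
  invisible(x)
}

#' @export
tidy.equigen_reml <- function(x, ...) {
  vc <- x$vc
  vp <- x$V_P
  bind_rows(
    mutate(vc, proportion = .data$variance / vp),
    tibble(component = "h2", variance = x$h2, se = x$h2_se,
           proportion = NA_real_),
    tibble(component = "repeatability", variance = x$repeatability,
           se = NA_real_, proportion = NA_real_)
  )
}

#' @export
glance.equigen_reml <- function(x, ...) {
  tibble(
    logLik = x$loglik, converged = x$converged, n_iter = x$n_iter,
    nobs = x$n, h2 = x$h2, repeatability = x$repeatability, V_P = x$V_P
  )
}

#' Likelihood-ratio test of the additive genetic variance
#'
#' Because V_A is tested on the boundary of its parameter space, twice the
#' difference in restricted log-likelihoods between the model with and
#' without the additive term is referred to a 50:50 mixture of a
#' point mass at zero and a chi-squared with one degree of freedom:
#' `p = P(chi2_1 >= stat) / 2` for a positive statistic and `p = 1` at zero.
#'
#' @param full REML fit including the additive genetic term.
#' @param reduced REML fit of the same data and fixed effects omitting only
#'   the additive term.
#' @return A one-row tibble with `statistic` and `p_value`.
#' @export
lrt_va <- function(full, reduced) {
  stopifnot(inherits(full, "equigen_reml"), inherits(reduced, "equigen_reml"))
  if (!"additive" %in% full$random || "additive" %in% reduced$random) {
    abort("'full' must include the additive term and 'reduced' must omit it")
  }
  if (!setequal(setdiff(full$random, "additive"), reduced$random)) {
    abort("models differ by more than the additive term")
  }
  if (full$n != reduced$n || full$p != reduced$p) {
    abort("full and reduced models were fitted to different designs")
  }
  mixture_lrt(2 * (full$loglik - reduced$loglik))
}

#' Boundary chi-squared mixture p-value
#'
#' @param statistic Likelihood-ratio statistic (floored at zero).
#' @return Tibble with the floored statistic and its mixture p-value.
#' @export
mixture_lrt <- function(statistic) {
  statistic <- max(0, statistic)
  p <- if (statistic == 0) 1 else 0.5 * pchisq(statistic, df = 1,
                                               lower.tail = FALSE)
  tibble(statistic = statistic, p_value = p)
}
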