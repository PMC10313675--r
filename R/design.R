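#' Built-in animal-model specifications
#'
#' Two fixed-effect structures are provided, both with the same random
#' structure (additive genetic, permanent environment, trainer):
#'
#' * **Model A** conditions on race identity directly: fixed factors of
#'   `race_id`, age (10-level factor, see [collapse_age()]) and sex.
#' * **Model B** replaces the race factor with race-level covariates:
#'   a year factor (detrending the phenotype against environmentally driven
#'   linear change), factors of timing method and racecourse, quadratics in
#'   distance, number of runners and going, first-order interactions of
#'   distance with continuous year, going and number of runners, the
#'   interaction of distance-squared with continuous year, plus the age and
#'   sex factors.  Continuous year enters only through its interactions with
#'   distance; its main effect is absorbed by the year factor.
#'
#' @param name `"A"` or `"B"`.
#' @return A `equigen_model_spec` list.
#' @export
model_spec <- function(name = c("A", "B")) {
  name <- match.arg(name)
  fixed <- if (name == "A") {
    "~ race_id + age_f + sex"
  } else {
    paste(
      "~ year_f + timing + racecourse",
      "+ distance_s + distance_sq + runners_s + runners_sq",
      "+ going_s + going_sq",
      "+ distance_s:year_c + distance_s:going_s + distance_s:runners_s",
      "+ distance_sq:year_c + age_f + sex"
    )
  }
  structure(
    list(
      name = name,
      fixed_formula = fixed,
      random_terms = c("additive", "pe", "trainer")
    ),
    class = "equigen_model_spec"
  )
}

scale_covariate <- function(x) {
  mu <- mean(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  structure((x - mu) / s, center = mu, scale = s)
}

#' Build fixed- and random-effect design matrices
#'
#' Constructs the response vector (speed), the sparse fixed-effect matrix X
#' (treatment coding, alphabetically first level as reference; continuous
#' covariates centred and scaled before polynomial and interaction terms are
#' formed), and sparse incidence matrices mapping records to pedigree
#' individuals (additive genetic), to horses (permanent environment) and to
#' trainers.  Factors left with fewer than two levels are dropped with a
#' warning, as are rank-deficient columns.
#'
#' @param records A prepared record tibble (see [prepare_records()]); every
#'   horse must be present in the pedigree.
#' @param spec A [model_spec()].
#' @param ped The pedigree the additive effects map to.
#' @return An `equigen_design` list with elements `X`, `Z` (list `additive`,
#'   `pe`, `trainer`), `y`, `labels`, `ped_ids`, `horse_ids`, `trainer_ids`,
#'   `horse`, `birth_year` lookup and scaling metadata.
#' @export
build_design <- function(records, spec, ped) {
  stopifnot(inherits(spec, "equigen_model_spec"))
  ped <- ensure_sorted(ped)
  records <- as_tibble(records)
  if (!"speed" %in% names(records)) {
    abort("records must be prepared (no speed column); see prepare_records()")
  }
  absent <- setdiff(unique(records$horse), ped$id)
  if (length(absent) > 0) {
    abort(paste0("record horse(s) missing from pedigree: ",
                 paste(head(absent, 5), collapse = ", ")))
  }

  df <- tibble(
    race_id = factor(records$race_id),
    age_f = collapse_age(records$age),
    sex = factor(records$sex),
    year_f = factor(records$year),
    timing = factor(records$timing),
    racecourse = factor(records$racecourse)
  )
  df$age_f <- droplevels(df$age_f)
  scaling <- list()
  for (v in c("distance", "n_runners", "going", "year")) {
    s <- scale_covariate(as.numeric(records[[v]]))
    scaling[[v]] <- c(center = attr(s, "center"), scale = attr(s, "scale"))
    df[[paste0(substr(v, 1, 1), "_tmp")]] <- as.numeric(s)
  }
  df$distance_s <- df$d_tmp
  df$runners_s <- df$n_tmp
  df$going_s <- df$g_tmp
  df$year_c <- df$y_tmp
  df$distance_sq <- df$distance_s^2
  df$runners_sq <- df$runners_s^2
  df$going_sq <- df$going_s^2

  form_txt <- spec$fixed_formula
  factor_terms <- c("race_id", "age_f", "sex", "year_f", "timing",
                    "racecourse")
  for (f in factor_terms) {
    if (grepl(paste0("\\b", f, "\\b"), form_txt) &&
        nlevels(droplevels(df[[f]])) < 2) {
      warn(paste0("factor '", f, "' has a single level and was dropped"))
      form_txt <- gsub(paste0("\\+\\s*", f, "\\b|\\b", f, "\\s*\\+"),
                       "", form_txt)
    }
  }
  form <- stats::as.formula(form_txt)
  X <- Matrix::sparse.model.matrix(form, data = df)
  if (nrow(X) == 0 || ncol(X) == 0) abort("empty fixed-effect design")

  # drop aliased columns via pivoted QR (on X when affordable, else on the
  # cross-product)
  qrd <- if (as.numeric(nrow(X)) * ncol(X) <= 5e7) {
    qr(as.matrix(X), tol = 1e-7, LAPACK = FALSE)
  } else {
    qr(as.matrix(crossprod(X)), tol = 1e-9, LAPACK = FALSE)
  }
  if (qrd$rank < ncol(X)) {
    drop_idx <- sort(qrd$pivot[(qrd$rank + 1):ncol(X)])
    warn(paste0("dropping ", length(drop_idx),
                " rank-deficient fixed-effect column(s): ",
                paste(head(colnames(X)[drop_idx], 5), collapse = ", ")))
    X <- X[, -drop_idx, drop = FALSE]
  }

  n <- nrow(records)
  horse_ids <- sort(unique(records$horse))
  trainer_ids <- sort(unique(records$trainer))
  Z <- list(
    additive = sparseMatrix(i = seq_len(n),
                            j = match(records$horse, ped$id),
                            x = 1, dims = c(n, nrow(ped)),
                            dimnames = list(NULL, ped$id)),
    pe = sparseMatrix(i = seq_len(n), j = match(records$horse, horse_ids),
                      x = 1, dims = c(n, length(horse_ids)),
                      dimnames = list(NULL, horse_ids)),
    trainer = sparseMatrix(i = seq_len(n),
                           j = match(records$trainer, trainer_ids),
                           x = 1, dims = c(n, length(trainer_ids)),
                           dimnames = list(NULL, trainer_ids))
  )
  structure(
    list(
      X = X, Z = Z, y = as.numeric(records$speed),
      labels = colnames(X),
      spec = spec,
      ped_ids = ped$id,
      horse_ids = horse_ids,
      trainer_ids = trainer_ids,
      horse = records$horse,
      scaling = scaling,
      n = n, p = ncol(X)
    ),
    class = "equigen_design"
  )
}

#' @export
#' @method print equigen_design
print.equigen_design <- function(x, ...) {
  cat("# Animal-model design (Model ", x$spec$name, "): ",
      x$n, " records, ", x$p, " fixed-effect columns, ",
      length(x$ped_ids), " pedigree individuals, ",
      length(x$horse_ids), " phenotyped horses, ",
      length(x$trainer_ids), " trainers\n", sep = "")
  invisible(x)
}
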