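#' Build a validated pedigree from a data frame
#'
#' A pedigree is a tibble with columns `id`, `sire`, `dam`, `birth_year` and
#' `sex`, topologically sorted so that every parent precedes its offspring.
#' Unknown parents are recorded as `NA` and are treated as founders drawn
#' from the base population.  Parents that are referenced but have no row of
#' their own are added as founders (with a message), so the returned object
#' is always closed under the parent relation.
#'
#' Validation enforces acyclicity (no individual is its own ancestor), unique
#' ids, and that no individual is used both as a sire and as a dam.  Sex is
#' taken from the `sex` column when present and otherwise inferred from
#' parental usage (`male` for sires, `female` for dams, `unknown` otherwise).
#'
#' @param x A data frame with at least `id`, `sire`, `dam` columns; optional
#'   `birth_year` (integer) and `sex` (`"male"`, `"female"`, `"unknown"`).
#'   Empty strings, `"0"` and `"NA"` in the parent columns all denote an
#'   unknown parent.
#' @param sort Topologically sort the rows (default `TRUE`).  Sorting is
#'   stable: ties are broken by input order, so output order is reproducible.
#' @return A `pedigree` tibble (parents before offspring) with an integer
#'   `generation` attribute: founders are generation 1, and each offspring is
#'   one more than its deepest parent.
#' @export
#' @examples
#' as_pedigree(data.frame(id = c("A", "B", "C"),
#'                        sire = c(NA, NA, "A"),
#'                        dam  = c(NA, NA, "B")))
as_pedigree <- function(x, sort = TRUE) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(c("id", "sire", "dam"), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("pedigree is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ped <- as_tibble(x)
  ped$id <- as.character(ped$id)
  ped$sire <- normalize_parent(ped$sire)
  ped$dam <- normalize_parent(ped$dam)
  ped$birth_year <- if ("birth_year" %in% names(ped)) {
    as.integer(ped$birth_year)
  } else {
    NA_integer_
  }
  ped$sex <- if ("sex" %in% names(ped)) as.character(ped$sex) else NA_character_
  ped <- ped[, c("id", "sire", "dam", "birth_year", "sex")]

  dup <- unique(ped$id[duplicated(ped$id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate pedigree id(s): ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  if (any(ped$id == ped$sire, na.rm = TRUE) ||
      any(ped$id == ped$dam, na.rm = TRUE)) {
    bad <- ped$id[which(ped$id == ped$sire | ped$id == ped$dam)][1]
    abort(paste0("pedigree cycle detected: '", bad, "' is its own parent"))
  }

  implicit <- setdiff(c(na.omit(ped$sire), na.omit(ped$dam)), ped$id)
  if (length(implicit) > 0) {
    message(length(implicit),
            " parent(s) without their own row added as founders")
    ped <- bind_rows(
      tibble(id = implicit, sire = NA_character_, dam = NA_character_,
             birth_year = NA_integer_, sex = NA_character_),
      ped
    )
  }

  both <- intersect(unique(na.omit(ped$sire)), unique(na.omit(ped$dam)))
  if (length(both) > 0) {
    abort(paste0("individual(s) used as both sire and dam: ",
                 paste(head(both, 5), collapse = ", ")))
  }

  sex <- ped$sex
  sex[is.na(sex) | !(sex %in% c("male", "female"))] <- NA_character_
  sex[is.na(sex) & ped$id %in% ped$sire] <- "male"
  sex[is.na(sex) & ped$id %in% ped$dam] <- "female"
  conflict <- (ped$id %in% ped$sire & sex == "female") |
    (ped$id %in% ped$dam & sex == "male")
  if (any(conflict, na.rm = TRUE)) {
    abort(paste0("recorded sex conflicts with parental usage for: ",
                 paste(head(ped$id[which(conflict)], 5), collapse = ", ")))
  }
  sex[is.na(sex)] <- "unknown"
  ped$sex <- sex

  if (sort) ped <- sort_pedigree(ped) else ped <- add_generations(ped)
  new_pedigree(ped)
}

new_pedigree <- function(df) {
  class(df) <- unique(c("pedigree", class(as_tibble(df))))
  df
}

normalize_parent <- function(p) {
  p <- as.character(p)
  p[p %in% c("", "0", "NA", "na", ".")] <- NA_character_
  p
}

#' @export
#' @method print pedigree
print.pedigree <- function(x, ...) {
  cat("# Pedigree:", nrow(x), "individuals,",
    sum(is.na(x$sire) & is.na(x$dam)), "founders, max depth",
    if (is.null(attr(x, "generation"))) "?" else max(attr(x, "generation")),
    "\n")
  NextMethod()
}

parent_index <- function(ped) {
  list(sire = match(ped$sire, ped$id), dam = match(ped$dam, ped$id))
}

#' Topologically sort a pedigree
#'
#' Kahn-style layered sort: round r places every unplaced individual whose
#' parents are already placed, preserving input order within a round.  The
#' round number is the individual's generation (founders are generation 1).
#'
#' @param ped A pedigree-shaped data frame (already validated).
#' @return The sorted pedigree with a `generation` attribute.
#' @keywords internal
sort_pedigree <- function(ped) {
  n <- nrow(ped)
  pi <- parent_index(ped)
  si <- pi$sire
  di <- pi$dam
  placed <- logical(n)
  gen <- integer(n)
  ord <- integer(0)
  parent_ok <- function(ix) {
    ok <- rep(TRUE, n)
    known <- !is.na(ix)
    ok[known] <- placed[ix[known]]
    ok
  }
  round <- 0L
  while (length(ord) < n) {
    round <- round + 1L
    ready <- !placed & parent_ok(si) & parent_ok(di)
    if (!any(ready)) {
      bad <- ped$id[!placed][1]
      abort(paste0("pedigree cycle detected involving '", bad, "'"))
    }
    idx <- which(ready)
    gen[idx] <- round
    placed[idx] <- TRUE
    ord <- c(ord, idx)
  }
  out <- ped[ord, ]
  attr(out, "generation") <- gen[ord]
  out
}

add_generations <- function(ped) {
  pi <- parent_index(ped)
  gen <- integer(nrow(ped))
  for (i in seq_len(nrow(ped))) {
    gp <- c(
      if (!is.na(pi$sire[i])) gen[pi$sire[i]] else 0L,
      if (!is.na(pi$dam[i])) gen[pi$dam[i]] else 0L
    )
    gen[i] <- max(gp, 0L) + 1L
  }
  attr(ped, "generation") <- gen
  ped
}

is_sorted_pedigree <- function(ped) {
  pi <- parent_index(ped)
  pos <- seq_len(nrow(ped))
  all(pi$sire < pos, na.rm = TRUE) && all(pi$dam < pos, na.rm = TRUE)
}

ensure_sorted <- function(ped) {
  if (!is.data.frame(ped)) abort("expected a pedigree data frame")
  if (!inherits(ped, "pedigree")) ped <- as_pedigree(ped)
  if (!is_sorted_pedigree(ped)) {
    message("pedigree was not parent-first sorted; sorting internally")
    ped <- new_pedigree(sort_pedigree(ped))
  }
  if (is.null(attr(ped, "generation"))) ped <- add_generations(ped)
  ped
}

#' Read a pedigree file
#'
#' Delimited text with a header naming at least `id`, `sire` and `dam`;
#' `birth_year` and `sex` are used when present.  Empty fields, `"0"` and
#' `"NA"` in the parent columns all denote an unknown parent.
#'
#' @param path Path to the file.
#' @param delim Field delimiter (default comma).
#' @return A validated, topologically sorted [as_pedigree()] tibble.
#' @export
read_pedigree <- function(path, delim = ",") {
  if (!file.exists(path)) abort(paste0("pedigree file not found: ", path))
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  as_pedigree(raw)
}

#' Write a pedigree file
#'
#' Inverse of [read_pedigree()]: unknown parents are written as empty fields.
#'
#' @param ped A pedigree.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, delim = ",") {
  out <- as_tibble(ped)[, c("id", "sire", "dam", "birth_year", "sex")]
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Trim a pedigree to informative individuals
#'
#' Keeps every phenotyped individual together with all of its ancestors (the
#' individuals providing pedigree links between phenotyped animals), and
#' drops everything else.  This is the standard pruning used before variance
#' component estimation, and it is idempotent.
#'
#' @param ped A pedigree.
#' @param phenotyped Character vector of ids with performance records; must
#'   all be present in the pedigree.
#' @return The trimmed pedigree (still sorted).
#' @export
trim_pedigree <- function(ped, phenotyped) {
  ped <- ensure_sorted(ped)
  phenotyped <- unique(as.character(phenotyped))
  missing_ids <- setdiff(phenotyped, ped$id)
  if (length(missing_ids) > 0) {
    abort(paste0("phenotyped id(s) absent from pedigree: ",
                 paste(head(missing_ids, 10), collapse = ", ")))
  }
  pi <- parent_index(ped)
  keep <- ped$id %in% phenotyped
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      if (!is.na(pi$sire[i])) keep[pi$sire[i]] <- TRUE
      if (!is.na(pi$dam[i])) keep[pi$dam[i]] <- TRUE
    }
  }
  out <- as_tibble(ped)[keep, ]
  attr(out, "generation") <- NULL
  new_pedigree(add_generations(out))
}

#' Numerator relationship matrix
#'
#' Computes the additive (numerator) relationship matrix A by the tabular
#' method: for individual i with parents s and d,
#' `a_ii = 1 + a_sd / 2` and `a_ij = (a_js + a_jd) / 2` for j preceding i,
#' with unknown parents contributing zero.  Entries are twice the
#' coefficients of kinship, so diagonals are `1 + F_i` where `F_i` is the
#' inbreeding coefficient.
#'
#' A dense matrix is returned; the implementation targets desk-scale
#' pedigrees (up to a few thousand individuals).
#'
#' @param ped A pedigree (sorted parents-first; unsorted input is sorted
#'   internally with a message).
#' @return A symmetric dense matrix with ids as dimnames.
#' @export
relationship_matrix <- function(ped) {
  ped <- ensure_sorted(ped)
  n <- nrow(ped)
  pi <- parent_index(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- pi$sire[i]
    d <- pi$dam[i]
    A[i, i] <- if (!is.na(s) && !is.na(d)) 1 + 0.5 * A[s, d] else 1
    if (i > 1L) {
      j <- seq_len(i - 1L)
      r <- numeric(i - 1L)
      if (!is.na(s)) r <- r + 0.5 * A[s, j]
      if (!is.na(d)) r <- r + 0.5 * A[d, j]
      A[i, j] <- r
      A[j, i] <- r
    }
  }
  A
}

#' Inbreeding coefficients
#'
#' `F_i = a_ii - 1` from the numerator relationship matrix.  Founders (and
#' any individual with no known parents) have `F = 0`.
#'
#' @param ped A pedigree.
#' @return Named numeric vector of inbreeding coefficients, in pedigree order.
#' @export
inbreeding <- function(ped) {
  ped <- ensure_sorted(ped)
  diag(relationship_matrix(ped)) - 1
}

#' Mendelian sampling variance scalars
#'
#' The scaled Mendelian sampling variances d_i such that the breeding value
#' of i is the parental mean plus a deviation with variance `d_i * V_A`:
#' `d = 1/2 - (F_s + F_d)/4` with both parents known,
#' `d = 3/4 - F_p/4` with one known parent p, and `d = 1` for founders.
#' These are the diagonal entries of D in the factorisation A = T D T'.
#'
#' @param ped A sorted pedigree.
#' @param F Optional precomputed inbreeding coefficients (pedigree order).
#' @return Numeric vector of d_i in pedigree order.
#' @keywords internal
mendelian_d <- function(ped, F = NULL) {
  ped <- ensure_sorted(ped)
  if (is.null(F)) F <- inbreeding(ped)
  pi <- parent_index(ped)
  d <- rep(1, nrow(ped))
  ks <- !is.na(pi$sire)
  kd <- !is.na(pi$dam)
  d[ks] <- d[ks] - 0.25 * (1 + F[pi$sire[ks]])
  d[kd] <- d[kd] - 0.25 * (1 + F[pi$dam[kd]])
  d
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Uses the factorisation A = T D T' implied by Mendelian transmission
#' (T lower-triangular gene flow, D diagonal Mendelian sampling variances),
#' so that `A^-1 = (I - P/2)' D^-1 (I - P/2)` where P is the parent
#' incidence matrix.  The result is very sparse and carries
#' `log|A| = sum(log d_i)` as an attribute, both of which the mixed-model
#' machinery needs.
#'
#' @param ped A sorted pedigree.
#' @param F Optional precomputed inbreeding coefficients.
#' @return A `dsCMatrix` with attributes `logdet` and `d`.
#' @export
ainverse <- function(ped, F = NULL) {
  ped <- ensure_sorted(ped)
  n <- nrow(ped)
  d <- mendelian_d(ped, F)
  pi <- parent_index(ped)
  ii <- c(which(!is.na(pi$sire)), which(!is.na(pi$dam)))
  jj <- c(pi$sire[!is.na(pi$sire)], pi$dam[!is.na(pi$dam)])
  Tinv <- Diagonal(n)
  if (length(ii) > 0) {
    Tinv <- Tinv + sparseMatrix(i = ii, j = jj, x = rep(-0.5, length(ii)),
                                dims = c(n, n))
  }
  Ainv <- forceSymmetric(crossprod(Diagonal(x = 1 / sqrt(d)) %*% Tinv))
  dimnames(Ainv) <- list(ped$id, ped$id)
  attr(Ainv, "logdet") <- sum(log(d))
  attr(Ainv, "d") <- d
  Ainv
}

#' Structural summary of a pedigree
#'
#' One-row tibble of the counts used to describe pedigree structure:
#' individuals, distinct sires and dams, maximum generational depth
#' (founders count as generation 1), maximum paternal and maternal half-sib
#' family sizes (offspring per sire / per dam), and, when a record table is
#' supplied, the number of sires with at least one offspring that has
#' performance records.
#'
#' @param ped A pedigree.
#' @param records Optional performance-record tibble with a `horse` column.
#' @return A one-row tibble.
#' @export
summarize_pedigree <- function(ped, records = NULL) {
  ped <- ensure_sorted(ped)
  sire_tab <- table(ped$sire[!is.na(ped$sire)])
  dam_tab <- table(ped$dam[!is.na(ped$dam)])
  n_sires_rec <- NA_integer_
  if (!is.null(records)) {
    rec_ids <- unique(as.character(records$horse))
    n_sires_rec <- length(unique(ped$sire[!is.na(ped$sire) &
                                            ped$id %in% rec_ids]))
  }
  tibble(
    n_individuals = nrow(ped),
    n_sires = length(sire_tab),
    n_dams = length(dam_tab),
    max_depth = if (nrow(ped) > 0) max(attr(ped, "generation")) else 0L,
    max_paternal_halfsib = if (length(sire_tab) > 0) {
      as.integer(max(sire_tab))
    } else {
      0L
    },
    max_maternal_halfsib = if (length(dam_tab) > 0) {
      as.integer(max(dam_tab))
    } else {
      0L
    },
    n_sires_with_offspring_records = n_sires_rec
  )
}
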