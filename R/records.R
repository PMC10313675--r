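#' Convert finish time to average speed
#'
#' Speed in yards per second is the race distance (yards) divided by the
#' finish time (seconds).  This assumes every horse in a race runs the same
#' known distance.
#'
#' @param finish_time Finish time in seconds (positive).
#' @param distance Race distance in yards (positive).
#' @return Speed in yards per second; vectorised.
#' @export
#' @examples
#' time_to_speed(60, 1320) # 6 furlongs in a minute -> 22 yards/s
time_to_speed <- function(finish_time, distance) {
  if (any(!is.finite(finish_time)) || any(!is.finite(distance)) ||
      any(finish_time <= 0) || any(distance <= 0)) {
    abort("finish_time and distance must be positive and finite")
  }
  distance / finish_time
}

#' Yards per furlong (racing convention)
#' @keywords internal
YARDS_PER_FURLONG <- 220

#' Default race-distance categories
#'
#' Sprint 5-7 furlongs, middle-distance 8-12 furlongs, long-distance 14-20
#' furlongs (1 furlong = 220 yards).  Windows are inclusive at both ends;
#' 13-furlong races fall in the gap and belong to no category.
#'
#' @return A tibble with columns `name`, `min_furlongs`, `max_furlongs`.
#' @export
distance_categories <- function() {
  tibble(
    name = c("sprint", "middle", "long"),
    min_furlongs = c(5, 8, 14),
    max_furlongs = c(7, 12, 20)
  )
}

#' Assign race distances to distance categories
#'
#' @param distance Race distance(s) in yards.
#' @param categories Category table as from [distance_categories()].
#' @return Character vector of category names, `NA` for distances in a gap.
#' @export
assign_category <- function(distance, categories = distance_categories()) {
  if (any(distance <= 0)) abort("distance must be positive")
  lo <- categories$min_furlongs * YARDS_PER_FURLONG
  hi <- categories$max_furlongs * YARDS_PER_FURLONG
  ord <- order(lo)
  if (any(lo[ord][-1] <= hi[ord][-length(ord)])) {
    abort("distance category windows overlap")
  }
  out <- rep(NA_character_, length(distance))
  for (k in seq_len(nrow(categories))) {
    out[distance >= lo[k] & distance <= hi[k]] <- categories$name[k]
  }
  out
}

#' Collapse horse age into a 10-level factor
#'
#' Ages 2-10 map to themselves; 11 and older collapse to `"11+"` (very few
#' horses race beyond 11), giving a factor with exactly 10 levels.
#'
#' @param age Integer age(s) in years, at least 2.
#' @return Factor with levels `"2"` ... `"10"`, `"11+"`.
#' @export
collapse_age <- function(age) {
  if (any(!is.finite(age)) || any(age < 2)) {
    abort("age must be >= 2 (racehorses first race as two-year-olds)")
  }
  lev <- c(as.character(2:10), "11+")
  factor(ifelse(age >= 11, "11+", as.character(as.integer(age))),
         levels = lev)
}

required_record_cols <- c(
  "horse", "race_id", "distance", "going", "n_runners", "timing",
  "racecourse", "year", "age", "sex", "trainer"
)

#' Validate and prepare a performance-record table
#'
#' Ensures a `speed` column exists (computing it from `finish_time` and
#' `distance` when absent, and vice versa), drops rows with missing required
#' covariates (count reported via a message), checks invariants (positive
#' speed and distance, age >= 2, at least one runner, and
#' `speed * finish_time == distance` when both are present), and optionally
#' restricts to a single distance category.
#'
#' @param records A data frame of race records with columns `horse`,
#'   `race_id`, `distance`, `going`, `n_runners`, `timing`, `racecourse`,
#'   `year`, `age`, `sex`, `trainer` and at least one of `finish_time`,
#'   `speed`.
#' @param category Optional category name (`"sprint"`, `"middle"`, `"long"`)
#'   to subset to.
#' @param categories Category table, see [distance_categories()].
#' @return A tibble of validated records with `speed`, `finish_time` and
#'   `category` columns.
#' @export
prepare_records <- function(records, category = NULL,
                            categories = distance_categories()) {
  records <- as_tibble(records)
  missing_cols <- setdiff(required_record_cols, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("records are missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!any(c("finish_time", "speed") %in% names(records))) {
    abort("records need a finish_time or a speed column")
  }
  if (!"speed" %in% names(records)) records$speed <- NA_real_
  if (!"finish_time" %in% names(records)) records$finish_time <- NA_real_
  records$horse <- as.character(records$horse)
  records$trainer <- as.character(records$trainer)
  records$race_id <- as.character(records$race_id)
  records$racecourse <- as.character(records$racecourse)
  for (col in c("distance", "going", "speed", "finish_time")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  for (col in c("n_runners", "year", "age")) {
    records[[col]] <- as.integer(records[[col]])
  }

  need_speed <- is.na(records$speed) & !is.na(records$finish_time)
  records$speed[need_speed] <- time_to_speed(
    records$finish_time[need_speed], records$distance[need_speed]
  )
  need_time <- is.na(records$finish_time) & !is.na(records$speed)
  records$finish_time[need_time] <-
    records$distance[need_time] / records$speed[need_time]

  complete <- !Reduce(`|`, lapply(
    records[, c(required_record_cols, "speed")], is.na
  ))
  if (any(!complete)) {
    message(sum(!complete), " record(s) dropped for missing covariates")
    records <- records[complete, ]
  }
  if (nrow(records) == 0) abort("no complete records remain")

  if (any(records$speed <= 0) || any(records$distance <= 0)) {
    abort("speed and distance must be positive")
  }
  if (any(records$age < 2)) abort("age must be >= 2")
  if (any(records$n_runners < 1)) abort("n_runners must be >= 1")
  both <- !is.na(records$finish_time)
  bad <- abs(records$speed[both] * records$finish_time[both] -
               records$distance[both]) > 1e-9 * records$distance[both]
  if (any(bad)) {
    abort("speed * finish_time does not equal distance for some records")
  }

  records$category <- assign_category(records$distance, categories)
  if (!is.null(category)) {
    category <- match.arg(category, categories$name)
    records <- records[!is.na(records$category) &
                         records$category == category, ]
    if (nrow(records) == 0) {
      abort(paste0("no records in category '", category, "'"))
    }
  }
  records
}

#' Read a performance-record file
#'
#' Delimited text with a header; see [prepare_records()] for the required
#' columns.  Either `finish_time` or `speed` may be supplied.
#'
#' @inheritParams prepare_records
#' @param path Path to the file.
#' @param delim Field delimiter (default comma).
#' @return A validated record tibble.
#' @export
read_records <- function(path, delim = ",", category = NULL) {
  if (!file.exists(path)) abort(paste0("records file not found: ", path))
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  prepare_records(raw, category = category)
}

#' Write a performance-record file
#'
#' @param records A record tibble.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, delim = ",") {
  cols <- intersect(
    c("horse", "race_id", "finish_time", "speed", "distance", "going",
      "n_runners", "timing", "racecourse", "year", "age", "sex", "trainer"),
    names(records)
  )
  readr::write_delim(as_tibble(records)[, cols], path, delim = delim, na = "")
  invisible(path)
}
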