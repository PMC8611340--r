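.RATINGS_COLS <- c("participant_id", "block_index", "block_type",
                   "rating_index", "trial_index", "valence_std",
                   "arousal_std", "valence_raw", "arousal_raw")
.SCHEDULE_COLS <- c("participant_id", "block_index", "block_type",
                    "trial_index", "window", "position", "stimulus_id",
                    "category", "relevance", "target", "is_rating_trial",
                    "s_valence", "s_arousal")
.CATALOG_COLS <- c("stimulus_id", "category", "valence_raw", "arousal_raw",
                   "valence_std", "arousal_std")

.check_schema <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " file is missing required column(s): ",
         paste(missing, collapse = ", "))
}

#' Read and write ratings tables
#'
#' Long-format UTF-8 CSV, one row per rating; `write_ratings()` then
#' [read_ratings()] reproduces values to full precision. Reading validates
#' the header and rejects duplicate `(participant_id, block_index,
#' rating_index)` keys.
#'
#' @param ratings A `ratings_table`.
#' @param path File path.
#' @return `read_ratings()` returns a `ratings_table`; `write_ratings()`
#'   returns `path` invisibly.
#' @export
write_ratings <- function(ratings, path) {
  .check_schema(ratings, .RATINGS_COLS, "ratings")
  write.csv(ratings[, .RATINGS_COLS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_schema(df, .RATINGS_COLS, "ratings")
  key <- paste(df$participant_id, df$block_index, df$rating_index)
  if (anyDuplicated(key))
    stop("duplicate (participant_id, block_index, rating_index) keys in ", path)
  class(df) <- c("ratings_table", "data.frame")
  df
}

#' Read and write schedules and catalogs
#'
#' CSV round-trip helpers for the trial schedule and the stimulus catalog,
#' with header validation on read.
#'
#' @param schedule,catalog Objects produced by [build_schedule()] /
#'   [generate_catalog()].
#' @param path File path.
#' @return Readers return the corresponding classed data frame; writers
#'   return `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  .check_schema(schedule, .SCHEDULE_COLS, "schedule")
  write.csv(schedule[, .SCHEDULE_COLS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_schema(df, .SCHEDULE_COLS, "schedule")
  df$is_rating_trial <- as.logical(df$is_rating_trial)
  class(df) <- c("affect_schedule", "data.frame")
  df
}

#' @rdname write_schedule
#' @export
write_catalog <- function(catalog, path) {
  .check_schema(catalog, .CATALOG_COLS, "catalog")
  write.csv(catalog[, .CATALOG_COLS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_catalog <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_schema(df, .CATALOG_COLS, "catalog")
  class(df) <- c("stimulus_catalog", "data.frame")
  df
}
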