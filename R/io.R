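# delimited-text readers for the five record tables; header row required,
# exact column names, UTF-8

read_table_checked <- function(path, cols, what, sep = ",",
                               integer_cols = character()) {
  if (!file.exists(path)) {
    stop_sf(sprintf("%s file not found: %s", what, path), "seedfate_io_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  assert_cols(df, cols, sprintf("%s (%s)", what, path))
  for (col in intersect(integer_cols, names(df))) {
    x <- df[[col]]
    bad <- which(!is.numeric(x) | is.na(x) | x != round(x))
    if (length(bad)) {
      stop_sf(sprintf("%s (%s): column '%s' has non-integer value(s) at row(s) %s",
                      what, path, col,
                      paste(utils::head(bad, 5), collapse = ", ")),
              "seedfate_schema_error")
    }
  }
  df
}

#' Read focal fruit-handling records
#' @param path delimited-text file with columns `site`, `tree_id`,
#'   `session_hours`, `actor`, `n_swallowed`, `n_spat`, `n_dropped`.
#' @param sep field separator (default comma).
#' @return data.frame of focal records.
#' @export
read_focal_records <- function(path, sep = ",") {
  read_table_checked(path, c("site", "tree_id", "session_hours", "actor",
                             "n_swallowed", "n_spat", "n_dropped"),
                     "focal records", sep,
                     integer_cols = c("n_swallowed", "n_spat", "n_dropped"))
}

#' Read germination-trial records
#' @param path delimited-text file with columns `site`, `treatment`,
#'   `block_id`, `n_sown`, `n_germinated`.
#' @param sep field separator (default comma).
#' @return data.frame of germination trials.
#' @export
read_germination_trials <- function(path, sep = ",") {
  read_table_checked(path, c("site", "treatment", "block_id", "n_sown",
                             "n_germinated"), "germination trials", sep,
                     integer_cols = c("n_sown", "n_germinated"))
}

#' Read dispersal-distance records
#' @param path delimited-text file with columns `disperser`, `distance_m`.
#' @param sep field separator (default comma).
#' @return data.frame of distance records.
#' @export
read_distance_records <- function(path, sep = ",") {
  df <- read_table_checked(path, c("disperser", "distance_m"),
                           "dispersal distances", sep)
  if (any(df$distance_m < 0)) {
    stop_sf(sprintf("dispersal distances (%s): negative distance at row(s) %s",
                    path,
                    paste(utils::head(which(df$distance_m < 0), 5),
                          collapse = ", ")), "seedfate_schema_error")
  }
  df
}

#' Read seed-survival records
#' @param path delimited-text file with columns `site`, `year`, `tree_id`,
#'   `distance_m`, `n_placed`, `n_surviving`.
#' @param sep field separator (default comma).
#' @return data.frame of survival records.
#' @export
read_survival_records <- function(path, sep = ",") {
  read_table_checked(path, c("site", "year", "tree_id", "distance_m",
                             "n_placed", "n_surviving"), "survival records",
                     sep, integer_cols = c("n_placed", "n_surviving"))
}

#' Read camera-trap records
#' @param path delimited-text file with columns `site`, `station_id`,
#'   `trap_days`, `species`, `n_visits`.
#' @param sep field separator (default comma).
#' @return data.frame of camera records.
#' @export
read_camera_records <- function(path, sep = ",") {
  read_table_checked(path, c("site", "station_id", "trap_days", "species",
                             "n_visits"), "camera records", sep,
                     integer_cols = c("n_visits"))
}
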