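## Long-format CSV interchange for cohort data.
##
## Missing values are blank cells, never sentinel numbers. Timestamps
## are local "YYYY-MM-DDTHH:MM" with no zone suffix.

#' Write a cohort to a directory of CSV files
#'
#' Emits `participants.csv`, `surveys.csv`, and (when minute data are
#' present) `minutes.csv`; round-trips losslessly through
#' [read_cohort()].
#'
#' @param cohort A `wearlab_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "wearlab_cohort"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create directory: ", dir)
  }
  wr <- function(df, name) {
    path <- file.path(dir, name)
    ok <- tryCatch({
      utils::write.csv(df, path, row.names = FALSE, na = "")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("failed to write: ", path)
  }
  wr(cohort$profiles, "participants.csv")
  wr(cohort$surveys, "surveys.csv")
  if (!is.null(cohort$minutes)) {
    m <- cohort$minutes
    out <- data.frame(
      participant_id = m$participant_id,
      timestamp = sprintf("%sT%02d:%02d", format(m$date, "%Y-%m-%d"),
                          m$minute %/% 60L, m$minute %% 60L),
      heart_rate = m$heart_rate,
      sleep_class = c("awake", "asleep")[m$sleep_class + 1L],
      steps = m$steps,
      intensity = m$intensity)
    wr(out, "minutes.csv")
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `participants.csv`, `surveys.csv` and
#'   optionally `minutes.csv`.
#' @return A `wearlab_cohort` (without generator-internal scoring; run
#'   [score_sleep_nights()] on the minutes to derive nightly metrics).
#' @export
read_cohort <- function(dir) {
  need <- file.path(dir, c("participants.csv", "surveys.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) stop("missing input file: ", paste(missing, collapse = ", "))
  profiles <- utils::read.csv(file.path(dir, "participants.csv"),
                              stringsAsFactors = FALSE)
  profiles$reversed_cycle <- as.logical(profiles$reversed_cycle)
  surveys <- utils::read.csv(file.path(dir, "surveys.csv"),
                             stringsAsFactors = FALSE,
                             colClasses = list(phq_item_ids = "character",
                                               endorsements = "character"))
  surveys$date <- as.Date(surveys$date)
  minutes <- NULL
  mpath <- file.path(dir, "minutes.csv")
  if (file.exists(mpath)) {
    raw <- utils::read.csv(mpath, stringsAsFactors = FALSE)
    minutes <- data.frame(
      participant_id = raw$participant_id,
      date = as.Date(substr(raw$timestamp, 1, 10)),
      minute = as.integer(substr(raw$timestamp, 12, 13)) * 60L +
        as.integer(substr(raw$timestamp, 15, 16)),
      heart_rate = raw$heart_rate,
      sleep_class = ifelse(raw$sleep_class == "asleep", 1L,
                           ifelse(raw$sleep_class == "awake", 0L, NA_integer_)),
      steps = raw$steps,
      intensity = ifelse(is.na(raw$intensity) | raw$intensity == "",
                         NA_character_, raw$intensity))
  }
  structure(list(profiles = profiles, surveys = surveys,
                 sleep_nights = NULL, minutes = minutes, config = NULL),
            class = "wearlab_cohort")
}
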