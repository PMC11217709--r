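## Daily physical-activity aggregation from minute steps and
## device-assigned intensity classes.

INTENSITY_LEVELS <- c("sedentary", "light", "moderate", "intense")

#' Aggregate minute activity into daily indicators
#'
#' For each participant calendar day: total steps, minutes in each
#' intensity class, the longest inactive run (consecutive minutes with
#' zero/missing steps and sedentary or missing intensity), and worn
#' minutes (minutes with a non-missing intensity class). A day with zero
#' worn minutes is returned with missing indicators.
#'
#' @param minutes Minute-record data frame with `participant_id`, `date`,
#'   `minute`, `steps`, `intensity`.
#' @param missing_is_inactive Count missing minutes as inactive in the
#'   longest-run computation (default `TRUE`: a device that is off could
#'   itself signal an emergency).
#' @return Data frame `participant_id`, `date`, `steps`, `light_min`,
#'   `moderate_min`, `intense_min`, `longest_inactive_run`,
#'   `worn_minutes`.
#' @export
activity_daily <- function(minutes, missing_is_inactive = TRUE) {
  key <- paste(minutes$participant_id, format(minutes$date), sep = "|")
  pieces <- split(seq_len(nrow(minutes)), key)
  rows <- lapply(pieces, function(ix) {
    sub <- minutes[ix, , drop = FALSE]
    sub <- sub[order(sub$minute), , drop = FALSE]
    worn <- sum(!is.na(sub$intensity))
    if (worn == 0L) {
      return(data.frame(participant_id = sub$participant_id[1],
                        date = sub$date[1], steps = NA_real_,
                        light_min = NA_integer_, moderate_min = NA_integer_,
                        intense_min = NA_integer_,
                        longest_inactive_run = NA_integer_,
                        worn_minutes = 0L))
    }
    no_steps <- is.na(sub$steps) | sub$steps == 0
    sed_or_missing <- is.na(sub$intensity) | sub$intensity == "sedentary"
    inactive <- no_steps & sed_or_missing
    if (!missing_is_inactive) {
      inactive[is.na(sub$steps) & is.na(sub$intensity)] <- FALSE
    }
    r <- rle(inactive)
    longest <- if (any(r$values)) max(r$lengths[r$values]) else 0L
    data.frame(participant_id = sub$participant_id[1], date = sub$date[1],
               steps = sum(sub$steps, na.rm = TRUE),
               light_min = sum(sub$intensity == "light", na.rm = TRUE),
               moderate_min = sum(sub$intensity == "moderate", na.rm = TRUE),
               intense_min = sum(sub$intensity == "intense", na.rm = TRUE),
               longest_inactive_run = as.integer(longest),
               worn_minutes = as.integer(worn))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$date), ]
  rownames(out) <- NULL
  out
}
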