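## Daily chatbot symptom survey: script assembly and day coding.
##
## The daily voice survey asks one greeting item (safety/well-being
## check, 5-item pool) and two distinct depression items drawn from an
## 8-item pool. The depression pool corresponds to the standard 9-item
## depression questionnaire with the suicidality item removed; a day is
## coded symptomatic (1) when at least one asked depression item is
## endorsed.

#' Depression item pool (8 items; suicidality excluded)
#'
#' @return Data frame with `item_id` (1-8) and a short `label`.
#' @export
phq_item_pool <- function() {
  data.frame(item_id = 1:8,
             label = c("depressed mood", "little interest or pleasure",
                       "sleep problems", "fatigue or low energy",
                       "appetite change", "trouble concentrating",
                       "feeling bad about self", "psychomotor change"))
}

#' Greeting item pool (5 items)
#'
#' @return Data frame with `item_id` (1-5) and a short `label`.
#' @export
greeting_item_pool <- function() {
  data.frame(item_id = 1:5,
             label = c("slept well last night", "eaten your meal",
                       "feeling / pain check", "plans for today",
                       "need to visit hospital"))
}

#' Assemble one day's survey script
#'
#' Uniform selection of one greeting item and two distinct depression
#' items, without replacement, from the current RNG state (seed the RNG
#' for reproducibility).
#'
#' @param date The survey date (carried through).
#' @return List with `date`, `greeting_item_id`, `phq_item_ids` (length
#'   2, distinct, from 1-8).
#' @export
build_survey_script <- function(date) {
  list(date = date,
       greeting_item_id = sample.int(5L, 1L),
       phq_item_ids = sort(sample.int(8L, 2L)))
}

#' Code a day's symptom binary from endorsements
#'
#' 1 if any asked depression item was endorsed, 0 if all were denied,
#' `NA` when there are no responses (a missing day never coerces to 0).
#'
#' @param endorsements Integer/logical vector of 0/1 responses (may be
#'   empty or all `NA`).
#' @return Integer 0/1 or `NA`.
#' @export
code_symptom_day <- function(endorsements) {
  e <- endorsements[!is.na(endorsements)]
  if (!length(e)) return(NA_integer_)
  as.integer(max(e) > 0)
}

#' Person-level proportion of symptomatic days
#'
#' @param surveys Data frame with `participant_id` and `symptom_binary`.
#' @return Data frame `participant_id`, `p_symptom_days` (mean of the
#'   binary over non-missing days; `NA` with a warning-free flag when a
#'   participant has no coded day), `n_days`.
#' @export
symptom_person_means <- function(surveys) {
  ids <- unique(surveys$participant_id)
  out <- lapply(ids, function(pid) {
    s <- surveys$symptom_binary[surveys$participant_id == pid]
    s <- s[!is.na(s)]
    data.frame(participant_id = pid,
               p_symptom_days = if (length(s)) mean(s) else NA_real_,
               n_days = length(s))
  })
  do.call(rbind, out)
}
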