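#' Dichotomize a four-level self-rated health response
#'
#' Favorable = "excellent" or "good"; unfavorable = "fair" or "poor". Missing
#' responses propagate.
#'
#' @param response Character vector with levels excellent/good/fair/poor.
#' @return Logical vector.
#' @examples
#' code_four_level(c("excellent", "fair", NA))
#' @export
code_four_level <- function(response) {
  levels <- c("excellent", "good", "fair", "poor")
  bad <- !is.na(response) & !(response %in% levels)
  if (any(bad)) {
    stop(sprintf("unknown self-rated health level '%s'", response[bad][1]), call. = FALSE)
  }
  ifelse(is.na(response), NA, response %in% c("excellent", "good"))
}

#' Dichotomize a seven-point satisfaction response
#'
#' The scale runs 1 (most negative) to 7 (most positive). Favorable = the
#' three most positive responses (5-7); the neutral midpoint (4) and the
#' three most negative responses are unfavorable. Missing responses
#' propagate.
#'
#' @param response Integer vector in 1..7. If the source instrument is coded
#'   with 1 as most positive, set `reversed = TRUE` to re-orient at read
#'   time.
#' @param reversed Is the input scale reversed (1 = most positive)?
#' @return Logical vector.
#' @examples
#' code_seven_point(c(5L, 4L, 7L, 1L))
#' @export
code_seven_point <- function(response, reversed = FALSE) {
  bad <- !is.na(response) & !(response %in% 1:7)
  if (any(bad)) {
    stop(sprintf("satisfaction response '%s' outside 1..7", response[bad][1]), call. = FALSE)
  }
  if (reversed) response <- 8L - as.integer(response)
  ifelse(is.na(response), NA, response >= 5)
}

sa_outcomes <- c("recent_good", "for_age_good", "health_satisfied", "life_satisfied")

sa_outcome_labels <- c(
  recent_good = "Good recent general health",
  for_age_good = "Good health for age",
  health_satisfied = "Positive health satisfaction",
  life_satisfied = "Positive life satisfaction"
)

#' Code all four self-rated outcomes for a participant table
#'
#' @param records Participant tibble.
#' @param satisfaction_reversed Are the two 7-point satisfaction scales
#'   reverse-coded (1 = most positive)? Default `FALSE`.
#' @return Tibble with logical columns `recent_good`, `for_age_good`,
#'   `health_satisfied`, `life_satisfied`.
#' @export
code_outcomes <- function(records, satisfaction_reversed = FALSE) {
  tibble::tibble(
    recent_good = code_four_level(records$srh_recent),
    for_age_good = code_four_level(records$srh_for_age),
    health_satisfied = code_seven_point(records$sat_health, satisfaction_reversed),
    life_satisfied = code_seven_point(records$sat_life, satisfaction_reversed)
  )
}
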