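#' Imaging session schedules
#'
#' The two session layouts used throughout the package: ten consecutive
#' daily baseline sessions (`"baseline10"`), or three baseline sessions
#' followed by post-deprivation imaging at days 1, 2, 3 and 7
#' (`"deprivation"`).
#'
#' @param schedule One of `"baseline10"` or `"deprivation"`.
#' @return A tibble with one row per session: `session` (label),
#'   `session_index` (1-based order), `phase` (`"baseline"` or
#'   `"deprivation"`), and `day` (day offset from the first session; the
#'   deprivation schedule has a gap between day-3 and day-7 sessions).
#' @export
#' @examples
#' schedule_sessions("deprivation")
schedule_sessions <- function(schedule = c("baseline10", "deprivation")) {
  schedule <- match.arg(schedule)
  if (schedule == "baseline10") {
    tibble(
      session = paste0("D", 1:10),
      session_index = 1:10,
      phase = "baseline",
      day = 0:9
    )
  } else {
    tibble(
      session = c("BL1", "BL2", "BL3", "VD1", "VD2", "VD3", "VD7"),
      session_index = 1:7,
      phase = c(rep("baseline", 3), rep("deprivation", 4)),
      day = c(0, 1, 2, 3, 4, 5, 9)
    )
  }
}

baseline_sessions <- function(sessions) {
  sessions$session[sessions$phase == "baseline"]
}

deprivation_sessions <- function(sessions) {
  sessions$session[sessions$phase == "deprivation"]
}
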