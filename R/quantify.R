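#' Shaft-ratio normalization of a spine ROI
#'
#' The core intensity measure: the background-subtracted spine ROI divided
#' by the background-subtracted dsRed signal on the adjacent dendritic
#' shaft ROI. Applied to the green (SEP-GluA1) spine ROI it yields the
#' sGluA1 level; applied to the red (dsRed2) spine ROI it yields the spine
#' size proxy. The shaft denominator cancels any per-session multiplicative
#' imaging gain shared by the ROIs.
#'
#' A non-positive denominator marks the measurement invalid (`NA`); a
#' non-positive numerator is floored at `eps` so trace shapes stay aligned
#' (callers flag and exclude such values from statistics).
#'
#' @param spine_raw,spine_bg Mean pixel intensity of the spine ROI and its
#'   matched background ROI.
#' @param shaft_raw,shaft_bg Mean pixel intensity of the adjacent shaft ROI
#'   (dsRed channel) and its matched background ROI.
#' @param eps Floor for non-positive numerators (default 1e-6).
#' @return Numeric vector of dimensionless ratios; `NA` where the shaft
#'   denominator is non-positive.
#' @export
#' @examples
#' normalize_spine_value(200, 50, 350, 50)  # 0.5
normalize_spine_value <- function(spine_raw, spine_bg, shaft_raw, shaft_bg,
                                  eps = 1e-6) {
  num <- spine_raw - spine_bg
  den <- shaft_raw - shaft_bg
  out <- ifelse(den > 0, pmax(num, eps) / den, NA_real_)
  out
}

# flag vector companion to normalize_spine_value()
normalize_flag <- function(spine_raw, spine_bg, shaft_raw, shaft_bg) {
  num <- spine_raw - spine_bg
  den <- shaft_raw - shaft_bg
  case_when(
    is.na(num) | is.na(den) ~ "missing",
    den <= 0 ~ "invalid_shaft",
    num <= 0 ~ "floored",
    TRUE ~ "ok"
  )
}

#' Quantify raw ROI intensities into sGluA1 and size ratios
#'
#' Applies [normalize_spine_value()] row-wise to a long spine table,
#' producing the per-spine per-session `sglua1` (green spine / red shaft)
#' and `size` (red spine / red shaft) ratios plus quality flags. Flagged
#' values (invalid shaft, floored numerator) are set to `NA` in the value
#' columns so they propagate as missing downstream; the flag columns
#' retain the reason.
#'
#' @param tbl Long spine table with the six raw ROI columns (see
#'   [spine_table()]).
#' @param eps Numerator floor passed to [normalize_spine_value()].
#' @return `tbl` with added columns `sglua1`, `size`, `flag_sglua1`,
#'   `flag_size`.
#' @export
quantify_intensities <- function(tbl, eps = 1e-6) {
  tbl %>%
    mutate(
      flag_sglua1 = normalize_flag(.data$green_spine, .data$bg_green_spine,
                                   .data$red_shaft, .data$bg_red_shaft),
      flag_size = normalize_flag(.data$red_spine, .data$bg_red_spine,
                                 .data$red_shaft, .data$bg_red_shaft),
      sglua1 = if_else(
        .data$flag_sglua1 == "ok",
        normalize_spine_value(.data$green_spine, .data$bg_green_spine,
                              .data$red_shaft, .data$bg_red_shaft, eps = eps),
        NA_real_
      ),
      size = if_else(
        .data$flag_size == "ok",
        normalize_spine_value(.data$red_spine, .data$bg_red_spine,
                              .data$red_shaft, .data$bg_red_shaft, eps = eps),
        NA_real_
      )
    )
}

#' Normalize per-spine traces across sessions
#'
#' Re-expresses each spine's per-session ratio trace in one of the
#' normalization modes used for the different analyses:
#' \describe{
#'   \item{`raw_ratio`}{unchanged shaft ratios.}
#'   \item{`to_day1`}{each spine divided by its own first-session value.}
#'   \item{`to_baseline_mean`}{each spine divided by the mean of its
#'     baseline sessions (BL1-BL3 for the deprivation schedule).}
#'   \item{`daily_change`}{each session divided by the previous session's
#'     value; transitions spanning a missing session are dropped (see
#'     [daily_change()]).}
#' }
#' A spine whose reference value(s) are missing is excluded from that
#' normalization (its values become `NA`). Missing inputs stay missing;
#' nothing is imputed.
#'
#' @param tbl Quantified table (from [quantify_intensities()]) with
#'   `spine_id`, `session`, and the value columns.
#' @param mode One of `"raw_ratio"`, `"to_day1"`, `"to_baseline_mean"`,
#'   `"daily_change"`.
#' @param sessions Session tibble from [schedule_sessions()]; required for
#'   ordering and for identifying baseline sessions.
#' @param values Character vector of value columns to normalize
#'   (default `c("sglua1", "size")`, intersected with what is present).
#' @return The table with value columns replaced by normalized values and a
#'   `norm_mode` column recording the mode.
#' @export
normalize_trace <- function(tbl, mode = c("raw_ratio", "to_day1",
                                          "to_baseline_mean", "daily_change"),
                            sessions, values = c("sglua1", "size")) {
  mode <- match.arg(mode)
  values <- intersect(values, names(tbl))
  if (!length(values)) abort("no value columns to normalize")
  tbl <- tbl %>%
    left_join(sessions %>% select("session", "session_index", "phase"),
              by = "session") %>%
    arrange(.data$spine_id, .data$session_index)

  out <- switch(mode,
    raw_ratio = tbl,
    to_day1 = tbl %>%
      group_by(.data$spine_id) %>%
      mutate(across(dplyr::all_of(values), ~ {
        ref <- .x[.data$session_index == min(.data$session_index)][1]
        if (is.na(ref) || ref <= 0) rep(NA_real_, length(.x)) else .x / ref
      })) %>%
      ungroup(),
    to_baseline_mean = tbl %>%
      group_by(.data$spine_id) %>%
      mutate(across(dplyr::all_of(values), ~ {
        bl <- .x[.data$phase == "baseline"]
        if (any(is.na(bl)) || length(bl) == 0L || mean(bl) <= 0) {
          rep(NA_real_, length(.x))
        } else {
          .x / mean(bl)
        }
      })) %>%
      ungroup(),
    daily_change = daily_change(tbl, sessions = sessions, values = values)
  )
  out$norm_mode <- mode
  out
}

#' Session-to-session change ratios
#'
#' The daily-change measure: each session's value divided by the previous
#' session's value, per spine. Only transitions between consecutive
#' schedule sessions with valid values on both days are emitted; a gap
#' (missing or absent session) yields no transition.
#'
#' @param tbl Quantified table with `spine_id`, `session` and value columns.
#' @param sessions Session tibble from [schedule_sessions()].
#' @param values Value columns to transform (default `sglua1`, `size`).
#' @return A tibble with one row per spine x transition: `spine_id`,
#'   `session` (the later session), `session_index`, and the change ratios
#'   in the value columns.
#' @export
#' @examples
#' tbl <- tibble::tibble(spine_id = "s1", session = paste0("D", 1:3),
#'                       sglua1 = c(1, 2, 1))
#' daily_change(tbl, schedule_sessions("baseline10"), values = "sglua1")
daily_change <- function(tbl, sessions, values = c("sglua1", "size")) {
  values <- intersect(values, names(tbl))
  if (!"session_index" %in% names(tbl)) {
    tbl <- tbl %>%
      left_join(sessions %>% select("session", "session_index", "phase"),
                by = "session")
  }
  tbl %>%
    arrange(.data$spine_id, .data$session_index) %>%
    group_by(.data$spine_id) %>%
    mutate(
      .consecutive = .data$session_index - dplyr::lag(.data$session_index) == 1L,
      across(dplyr::all_of(values), ~ if_else(
        .data$.consecutive & !is.na(.x) & !is.na(dplyr::lag(.x)),
        .x / dplyr::lag(.x), NA_real_
      ))
    ) %>%
    ungroup() %>%
    filter(dplyr::if_any(dplyr::all_of(values), ~ !is.na(.x))) %>%
    select(-".consecutive")
}

#' Spine values relative to their dendrite's mean
#'
#' Re-expresses each spine's value relative to the arithmetic mean of all
#' valid spines on the same dendrite at the same session, so the included
#' spines average to 1 per dendrite-session. This is the relative level
#' used for cross-day stability, CV, and transient-spine comparisons.
#'
#' @param tbl Table with `dendrite_id`, `session`, and value columns.
#' @param values Value columns to transform (default `sglua1`, `size`).
#' @return The table with value columns replaced by relative levels.
#' @export
relative_to_dendrite_mean <- function(tbl, values = c("sglua1", "size")) {
  values <- intersect(values, names(tbl))
  if (!length(values)) abort("no value columns present")
  out <- tbl %>%
    group_by(.data$dendrite_id, .data$session) %>%
    mutate(across(dplyr::all_of(values), ~ {
      m <- mean(.x, na.rm = TRUE)
      if (!is.finite(m) || m <= 0) rep(NA_real_, length(.x)) else .x / m
    })) %>%
    ungroup()
  if (all(purrr::map_lgl(values, function(v) all(is.na(out[[v]]))))) {
    abort("relative_to_dendrite_mean(): no valid spine values on any dendrite")
  }
  out
}

#' Per-dendrite geometric-mean summaries
#'
#' The per-dendrite change summary: the geometric mean of spine values per
#' dendrite and session, restricted by default to persistent spines
#' (present at every session of the schedule), matching how timecourse
#' figures summarize dendrites.
#'
#' @param tbl Table with `spine_id`, `dendrite_id`, `session`, `present`,
#'   and value columns.
#' @param sessions Session tibble from [schedule_sessions()].
#' @param values Value columns to summarize (default `sglua1`, `size`).
#' @param persistent_only Restrict to spines present at every session.
#' @return A tibble with one row per dendrite x session: geometric means
#'   per value column and `n_spines` (spines with a valid first value
#'   column at the session).
#' @export
dendrite_summary <- function(tbl, sessions, values = c("sglua1", "size"),
                             persistent_only = TRUE) {
  values <- intersect(values, names(tbl))
  if (persistent_only && "present" %in% names(tbl)) {
    keep <- tbl %>%
      group_by(.data$spine_id) %>%
      summarise(.all = sum(.data$present) == nrow(sessions)) %>%
      filter(.data$.all) %>%
      pull("spine_id")
    tbl <- tbl %>% filter(.data$spine_id %in% keep)
  }
  tbl %>%
    group_by(.data$dendrite_id, .data$session) %>%
    summarise(
      n_spines = sum(!is.na(.data[[values[1]]])),
      across(dplyr::all_of(values), ~ geom_mean(.x[!is.na(.x) & .x > 0])),
      .groups = "drop"
    ) %>%
    filter(.data$n_spines >= 1L)
}
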