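#' Classify spine fate over an imaging schedule
#'
#' Labels each tracked spine by its presence pattern: `persistent`
#' (detected at the first and last session), `formed` (first detected
#' after session 1), `eliminated` (last detected before the final
#' session), or `formed_and_eliminated`. A spine absent at an interior
#' session but present before and after is treated as a detection gap,
#' not as elimination followed by re-formation, so a spine spanning the
#' whole schedule is persistent even with interior gaps.
#'
#' @param tbl Long table with `spine_id`, `session`, `present`.
#' @param sessions Session tibble from [schedule_sessions()].
#' @return A tibble with one row per spine: `spine_id`, `fate`,
#'   `first_detected`, `last_detected` (session labels), `n_present`.
#' @export
classify_spine_fate <- function(tbl, sessions) {
  n_sess <- nrow(sessions)
  fates <- tbl %>%
    select(-dplyr::any_of(c("session_index", "phase", "day"))) %>%
    left_join(sessions %>% select("session", "session_index"), by = "session") %>%
    group_by(.data$spine_id) %>%
    summarise(
      n_present = sum(.data$present),
      .first = ifelse(any(.data$present),
                      min(.data$session_index[.data$present]), NA_integer_),
      .last = ifelse(any(.data$present),
                     max(.data$session_index[.data$present]), NA_integer_),
      .groups = "drop"
    )
  if (any(fates$n_present == 0L)) {
    abort(paste0("never-present spine(s): ",
                 paste(head(fates$spine_id[fates$n_present == 0L], 5),
                       collapse = ", ")))
  }
  fates %>%
    mutate(
      fate = case_when(
        .data$.first == 1L & .data$.last == n_sess ~ "persistent",
        .data$.first > 1L & .data$.last < n_sess ~ "formed_and_eliminated",
        .data$.first > 1L ~ "formed",
        TRUE ~ "eliminated"
      ),
      first_detected = sessions$session[.data$.first],
      last_detected = sessions$session[.data$.last]
    ) %>%
    select("spine_id", "fate", "first_detected", "last_detected", "n_present")
}

#' Fraction of spines persisting across the whole schedule
#'
#' The percentage of tracked spines present at every imaging session.
#' The default denominator is the cohort present at the first session
#' (spines formed mid-series cannot, by construction, persist across all
#' sessions and are excluded); `cohort = "all"` divides by every tracked
#' spine instead.
#'
#' With independent per-session survival probability \eqn{p} over
#' \eqn{n} sessions the expected value is \eqn{100\,p^{\,n-1}}.
#'
#' @param fates Fate table from [classify_spine_fate()].
#' @param cohort `"first_session"` (default) or `"all"`.
#' @return Percentage in \[0, 100\].
#' @export
persistence_fraction <- function(fates, cohort = c("first_session", "all")) {
  cohort <- match.arg(cohort)
  if (nrow(fates) == 0L) abort("empty fate table")
  if (cohort == "first_session") {
    fates <- fates %>% filter(.data$fate %in% c("persistent", "eliminated"))
  }
  100 * sum(fates$fate == "persistent") / nrow(fates)
}

#' Transient-spine intensity at and around formation/elimination
#'
#' For newly formed spines, the relative-to-dendrite-mean sGluA1 at first
#' detection; for eliminated spines, at last detection. Also returns the
#' peri-event trajectory (sessions indexed relative to the event) for
#' event-aligned curves.
#'
#' @param rel_tbl Table of relative-to-dendrite-mean values (see
#'   [relative_to_dendrite_mean()]) with `spine_id`, `session`, value
#'   column `sglua1`.
#' @param fates Fate table from [classify_spine_fate()]; only `formed`,
#'   `eliminated` or `formed_and_eliminated` spines are allowed.
#' @param sessions Session tibble.
#' @return A list with `at_event` (one row per spine x event:
#'   `spine_id`, `event`, `session`, `value`) and `trajectory` (rows per
#'   spine x session with `offset` = session index minus event index).
#' @export
transient_intensity <- function(rel_tbl, fates, sessions) {
  bad <- fates$spine_id[fates$fate == "persistent"]
  if (length(bad)) {
    abort(paste0("persistent spine(s) passed to transient_intensity(): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  idx <- sessions %>% select("session", "session_index")
  rel <- rel_tbl %>%
    select(-dplyr::any_of(c("session_index", "phase", "day"))) %>%
    inner_join(fates, by = "spine_id") %>%
    left_join(idx, by = "session")

  events <- fates %>%
    tidyr::pivot_longer(
      c("first_detected", "last_detected"),
      names_to = "which", values_to = "session"
    ) %>%
    filter(
      (.data$which == "first_detected" &
         .data$fate %in% c("formed", "formed_and_eliminated")) |
        (.data$which == "last_detected" &
           .data$fate %in% c("eliminated", "formed_and_eliminated"))
    ) %>%
    mutate(event = if_else(.data$which == "first_detected",
                           "formation", "elimination")) %>%
    select("spine_id", "event", "session") %>%
    left_join(idx, by = "session") %>%
    rename(event_index = "session_index")

  at_event <- events %>%
    left_join(rel %>% select("spine_id", "session", value = "sglua1"),
              by = c("spine_id", "session"))

  trajectory <- events %>%
    select("spine_id", "event", "event_index") %>%
    left_join(rel %>% select("spine_id", "session", "session_index",
                             value = "sglua1"),
              by = "spine_id", relationship = "many-to-many") %>%
    mutate(offset = .data$session_index - .data$event_index) %>%
    filter(!is.na(.data$value)) %>%
    select("spine_id", "event", "session", "offset", "value")

  list(at_event = at_event, trajectory = trajectory)
}

#' Per-spine coefficient of variation across sessions
#'
#' The day-to-day dynamics metric: for each spine, the sample standard
#' deviation divided by the arithmetic mean of its valid values inside the
#' session window. Spines with fewer than 3 valid windowed values return
#' `NA` (and are counted in the attached exclusion message).
#'
#' @param tbl Table with `spine_id`, `session`, and the value column.
#' @param window Optional character vector of session labels restricting
#'   the window (default: all sessions present in `tbl`).
#' @param value Name of the value column (default `"sglua1"`).
#' @return Tibble with `spine_id`, `n_valid`, `cv`.
#' @export
spine_cv <- function(tbl, window = NULL, value = "sglua1") {
  if (!is.null(window)) tbl <- tbl %>% filter(.data$session %in% window)
  out <- tbl %>%
    group_by(.data$spine_id) %>%
    summarise(
      n_valid = sum(!is.na(.data[[value]])),
      cv = if (sum(!is.na(.data[[value]])) >= 3L) {
        coef_variation(.data[[value]])
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  n_excl <- sum(is.na(out$cv))
  if (n_excl > 0) {
    message("spine_cv(): ", n_excl, " spine(s) with < 3 valid sessions set to NA")
  }
  out
}

#' Correlation of spine levels between two sessions
#'
#' Pearson correlation of per-spine values between two sessions (e.g.
#' relative sGluA1 at day 1 vs day 10), over spines valid at both.
#'
#' @param tbl Table with `spine_id`, `session`, value column.
#' @param session_a,session_b Session labels to pair.
#' @param value Value column name (default `"sglua1"`).
#' @return Tibble with `r`, `p_value`, `n`.
#' @export
cross_day_correlation <- function(tbl, session_a, session_b, value = "sglua1") {
  wide <- tbl %>%
    filter(.data$session %in% c(session_a, session_b)) %>%
    select("spine_id", "session", dplyr::all_of(value)) %>%
    tidyr::pivot_wider(names_from = "session", values_from = dplyr::all_of(value))
  x <- wide[[session_a]]
  y <- wide[[session_b]]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) abort("cross_day_correlation() needs >= 3 paired spines")
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Coupling between daily changes in spine size and sGluA1
#'
#' Pools all spine-transitions for the overall Pearson correlation between
#' daily spine-size change and daily sGluA1 change, computes per-spine
#' correlations for spines with enough transitions, and reports the
#' inverse fraction: the share of such spines whose per-spine correlation
#' falls below `inverse_threshold` (default 0, i.e. a negative sign).
#'
#' @param changes Daily-change table (from [daily_change()]) with columns
#'   `spine_id`, `sglua1`, `size`.
#' @param min_transitions Minimum paired transitions per spine for the
#'   per-spine correlation (default 3).
#' @param inverse_threshold Per-spine r below this counts as inverse
#'   (default 0).
#' @return A list: `pooled` (tibble `r`, `p_value`, `n`), `per_spine`
#'   (tibble `spine_id`, `r`, `n`), `inverse_fraction`.
#' @export
size_fluorescence_coupling <- function(changes, min_transitions = 3L,
                                       inverse_threshold = 0) {
  ok <- !is.na(changes$sglua1) & !is.na(changes$size)
  pooled_tbl <- changes[ok, ]
  if (nrow(pooled_tbl) < 3L) abort("not enough paired daily changes")
  ct <- cor.test(pooled_tbl$size, pooled_tbl$sglua1, method = "pearson")
  pooled <- tibble(r = unname(ct$estimate), p_value = ct$p.value,
                   n = nrow(pooled_tbl))

  per_spine <- pooled_tbl %>%
    group_by(.data$spine_id) %>%
    summarise(n = dplyr::n(),
              r = if (dplyr::n() >= min_transitions && sd(.data$size) > 0 &&
                        sd(.data$sglua1) > 0) {
                cor(.data$size, .data$sglua1)
              } else {
                NA_real_
              },
              .groups = "drop") %>%
    filter(!is.na(.data$r))

  inverse_fraction <- if (nrow(per_spine)) {
    mean(per_spine$r < inverse_threshold)
  } else {
    NA_real_
  }
  list(pooled = pooled, per_spine = per_spine,
       inverse_fraction = inverse_fraction)
}

#' Distribution shift between two groups of spine levels
#'
#' Two-sample Kolmogorov-Smirnov comparison with group medians reported so
#' the direction of any shift is explicit.
#'
#' @param group_a,group_b Numeric vectors (NAs dropped).
#' @return Tibble with `statistic`, `p_value`, `median_a`, `median_b`,
#'   `n_a`, `n_b`.
#' @export
distribution_shift <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("distribution_shift() needs >= 2 values per group")
  }
  ks <- suppressWarnings(ks.test(group_a, group_b))
  tibble(
    statistic = unname(ks$statistic), p_value = ks$p.value,
    median_a = median(group_a), median_b = median(group_b),
    n_a = length(group_a), n_b = length(group_b)
  )
}
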