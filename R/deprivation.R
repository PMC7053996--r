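#' Group timecourse of baseline-normalized dendrite summaries
#'
#' Per-session group mean and SEM of per-dendrite geometric-mean changes
#' (values already normalized to the baseline mean), with a repeated-
#' measures comparison of sessions against the pooled baseline routed
#' through [route_test()] (ANOVA + Bonferroni post hoc, or Friedman +
#' Dunn when any session fails normality). Dendrites lacking a complete
#' baseline (or any session, for the repeated design) are excluded and
#' counted.
#'
#' @param dsum Dendrite-summary table (see [dendrite_summary()] applied to
#'   a `to_baseline_mean`-normalized table) with `dendrite_id`, `session`,
#'   and the value column.
#' @param sessions Session tibble from [schedule_sessions()].
#' @param value Value column name (default `"sglua1"`).
#' @return A `spinedyn_timecourse` list: `summary` (tibble session, mean,
#'   sem, n), `stat` (a `spinedyn_stat`), `n_excluded`.
#' @export
timecourse <- function(dsum, sessions, value = "sglua1") {
  wide <- dsum %>%
    select("dendrite_id", "session", dplyr::all_of(value)) %>%
    tidyr::pivot_wider(names_from = "session",
                       values_from = dplyr::all_of(value))
  miss <- setdiff(sessions$session, names(wide))
  for (s in miss) wide[[s]] <- NA_real_
  wide <- wide[, c("dendrite_id", sessions$session)]
  complete <- complete.cases(wide)
  n_excluded <- sum(!complete)
  if (n_excluded > 0) {
    message("timecourse(): excluded ", n_excluded,
            " dendrite(s) with incomplete sessions")
  }
  wide <- wide[complete, ]
  if (nrow(wide) < 2L) abort("timecourse() needs >= 2 complete dendrites")

  long <- wide %>%
    tidyr::pivot_longer(-"dendrite_id", names_to = "session",
                        values_to = "value") %>%
    rename(unit = "dendrite_id")
  summary <- long %>%
    group_by(.data$session) %>%
    summarise(mean = mean(.data$value), sem = sem(.data$value),
              n = dplyr::n(), .groups = "drop") %>%
    left_join(sessions %>% select("session", "session_index", "phase"),
              by = "session") %>%
    arrange(.data$session_index)

  stat <- route_test("repeated_oneway", data = long,
                     baseline = baseline_sessions(sessions))
  structure(list(summary = summary, stat = stat, n_excluded = n_excluded,
                 value = value),
            class = "spinedyn_timecourse")
}

#' @export
print.spinedyn_timecourse <- function(x, ...) {
  cat("<spinedyn_timecourse> value:", x$value, "\n")
  print(as.data.frame(x$summary[, c("session", "mean", "sem", "n")]),
        row.names = FALSE, digits = 4)
  print(x$stat)
  invisible(x)
}

#' @export
tidy.spinedyn_timecourse <- function(x, ...) {
  x$summary
}

#' @export
glance.spinedyn_timecourse <- function(x, ...) {
  glance(x$stat)
}

#' Sham-derived decrease threshold
#'
#' The decrease/no-decrease classification threshold: the sample standard
#' deviation of the percent change in the sham group at the first
#' post-deprivation session, returned as a positive fraction. Values are
#' baseline-normalized ratios, so the change is `value - 1`.
#'
#' @param sham_values Baseline-normalized sham-unit values at the
#'   VD1-equivalent session (>= 3 required).
#' @return The threshold fraction (e.g. 0.18 for an 18% rule).
#' @export
#' @examples
#' sham_threshold(c(0.9, 1.0, 1.1))  # 0.1
sham_threshold <- function(sham_values) {
  sham_values <- sham_values[!is.na(sham_values)]
  if (length(sham_values) < 3L) abort("sham_threshold() needs >= 3 sham units")
  thr <- sd(sham_values - 1)
  if (thr == 0) warn("sham_threshold(): degenerate threshold of 0")
  thr
}

#' Decrease / no-decrease response classification
#'
#' Labels each unit (dendrite, spine, or cell) `decrease` if its
#' baseline-normalized value at the evaluated session falls by at least
#' the threshold fraction (`value <= 1 - threshold`), else `no_decrease`.
#' This is a pure threshold rule calibrated from the sham arm (see
#' [sham_threshold()]); the reference constants are 0.18 for dendrites,
#' 0.435 for spines, and 0.098 for cells. Units missing the evaluated
#' session are excluded and counted.
#'
#' @param tbl Table with a unit-id column and per-session values, long
#'   format: `unit_id`, `session`, `value`.
#' @param threshold Decrease threshold as a fraction (> 0).
#' @param session Session evaluated (default `"VD1"`).
#' @param unit_level Label recorded in the output (`"dendrite"`,
#'   `"spine"`, or `"cell"`).
#' @return Tibble with `unit_id`, `unit_level`, `value`, `label`,
#'   `threshold`, `session_evaluated`.
#' @export
classify_response <- function(tbl, threshold, session = "VD1",
                              unit_level = "dendrite") {
  if (!is.numeric(threshold) || threshold <= 0) {
    abort("threshold must be a positive fraction")
  }
  at <- tbl %>%
    filter(.data$session == .env$session) %>%
    select("unit_id", "value")
  n_missing <- sum(is.na(at$value)) + length(setdiff(unique(tbl$unit_id),
                                                     at$unit_id))
  if (n_missing > 0) {
    message("classify_response(): excluded ", n_missing,
            " unit(s) without a valid value at ", session)
  }
  at %>%
    filter(!is.na(.data$value)) %>%
    mutate(
      unit_level = unit_level,
      label = if_else(.data$value <= 1 - threshold, "decrease", "no_decrease"),
      threshold = threshold,
      session_evaluated = session
    )
}

#' Summarize a response classification
#'
#' Counts and percentage of `decrease` units.
#'
#' @param labels Either the tibble returned by [classify_response()] or a
#'   character vector of `"decrease"` / `"no_decrease"` labels.
#' @return Tibble with `n_decrease`, `n_no_decrease`, `n_total`,
#'   `pct_decrease`.
#' @export
#' @examples
#' classification_summary(rep(c("decrease", "no_decrease"), c(25, 24)))
classification_summary <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  n_dec <- sum(labels == "decrease")
  n_tot <- length(labels)
  tibble(
    n_decrease = n_dec,
    n_no_decrease = n_tot - n_dec,
    n_total = n_tot,
    pct_decrease = 100 * n_dec / n_tot
  )
}

#' Correlation of unit changes between deprivation day 1 and day 7
#'
#' Pearson correlation of per-unit baseline-normalized changes at the
#' first and last post-deprivation sessions.
#'
#' @param tbl Long table `unit_id`, `session`, `value`.
#' @param session_a,session_b Sessions to pair (defaults `"VD1"`, `"VD7"`).
#' @return Tibble with `r`, `p_value`, `n`.
#' @export
day1_day7_correlation <- function(tbl, session_a = "VD1", session_b = "VD7") {
  wide <- tbl %>%
    filter(.data$session %in% c(session_a, session_b)) %>%
    select("unit_id", "session", "value") %>%
    tidyr::pivot_wider(names_from = "session", values_from = "value")
  x <- wide[[session_a]]
  y <- wide[[session_b]]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) abort("day1_day7_correlation() needs >= 3 paired units")
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Per-neuron basal-to-apical change ratio
#'
#' For each neuron with both compartments, pools its dendrites' baseline-
#' normalized changes by geometric mean per compartment, then takes
#' basal / apical at the requested session. Neurons whose apical pooled
#' change is at or below `eps` are excluded (unstable denominator) and
#' counted.
#'
#' @param dsum Dendrite-summary table (`to_baseline_mean` mode) with
#'   `dendrite_id`, `session`, value column.
#' @param dendrites Dendrite metadata with `dendrite_id`, `neuron_id`,
#'   `compartment`.
#' @param session Session at which to form the ratio (default `"VD7"`).
#' @param value Value column (default `"sglua1"`).
#' @param eps Apical-denominator guard (default 0.05).
#' @return Tibble with `neuron_id`, `basal`, `apical`, `ratio`.
#' @export
basal_apical_ratio <- function(dsum, dendrites, session = "VD7",
                               value = "sglua1", eps = 0.05) {
  pooled <- dsum %>%
    filter(.data$session == .env$session) %>%
    left_join(dendrites %>% select("dendrite_id", "neuron_id", "compartment"),
              by = "dendrite_id") %>%
    filter(!is.na(.data[[value]])) %>%
    group_by(.data$neuron_id, .data$compartment) %>%
    summarise(change = geom_mean(.data[[value]]), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "compartment", values_from = "change")
  if (!all(c("apical", "basal") %in% names(pooled))) {
    abort("basal_apical_ratio() needs neurons with both compartments")
  }
  pooled <- pooled %>% filter(!is.na(.data$apical), !is.na(.data$basal))
  n_guard <- sum(pooled$apical <= eps)
  if (n_guard > 0) {
    message("basal_apical_ratio(): excluded ", n_guard,
            " neuron(s) with apical change <= ", eps)
  }
  pooled %>%
    filter(.data$apical > eps) %>%
    mutate(ratio = .data$basal / .data$apical) %>%
    select("neuron_id", "basal", "apical", "ratio")
}

# min-max scale within groups; all-equal groups yield NA (excluded)
.rel_minmax <- function(tbl, coord, out, group = "dendrite_id") {
  tbl %>%
    group_by(.data[[group]]) %>%
    mutate(!!out := {
      v <- .data[[coord]]
      r <- range(v, na.rm = TRUE)
      if (!all(is.finite(r)) || diff(r) == 0) rep(NA_real_, length(v))
      else (v - r[1]) / diff(r)
    }) %>%
    ungroup()
}

#' Relative spine depth within a dendrite
#'
#' Min-max scales each spine's depth below the pia within its dendrite:
#' the most superficial spine maps to 0, the deepest to 1. Dendrites whose
#' spines all share one depth get `NA` (excluded from depth analyses).
#' Invariant under positive affine transforms of z.
#'
#' @param tbl Spine table with `dendrite_id` and `z_um`.
#' @return The table with an added `rel_depth` column.
#' @export
relative_depth_on_dendrite <- function(tbl) {
  .rel_minmax(tbl, "z_um", "rel_depth")
}

#' Relative spine distance from the branch point within a dendrite
#'
#' Min-max scales each spine's distance from the dendrite branch point:
#' the most proximal spine maps to 0, the most distal to 1.
#'
#' @param tbl Spine table with `dendrite_id` and `dist_branch_um`.
#' @return The table with an added `rel_distance` column.
#' @export
relative_distance_on_dendrite <- function(tbl) {
  .rel_minmax(tbl, "dist_branch_um", "rel_distance")
}

#' Ascending / descending dendrite orientation
#'
#' Classifies each dendritic segment from its endpoint geometry: with z
#' increasing downward from the pia, a dendrite is `ascending` when its
#' distal end is shallower than its proximal end (running toward the pia)
#' and |deltaDepth| / deltaDistance exceeds `ratio_threshold` (default
#' 0.1); `descending` when the distal end is deeper with the same ratio
#' condition; otherwise `excluded`.
#'
#' @param dendrites Dendrite metadata with `z_proximal_um`, `z_distal_um`,
#'   `arc_length_um`.
#' @param ratio_threshold Minimum |deltaDepth| / deltaDistance (default 0.1).
#' @return The table with added `delta_depth`, `depth_distance_ratio`,
#'   `orientation`.
#' @export
dendrite_orientation <- function(dendrites, ratio_threshold = 0.1) {
  if (any(dendrites$arc_length_um <= 0)) {
    abort("dendrite_orientation(): zero or negative arc length")
  }
  dendrites %>%
    mutate(
      delta_depth = .data$z_distal_um - .data$z_proximal_um,
      depth_distance_ratio = abs(.data$delta_depth) / .data$arc_length_um,
      orientation = case_when(
        .data$depth_distance_ratio <= ratio_threshold ~ "excluded",
        .data$delta_depth < 0 ~ "ascending",
        TRUE ~ "descending"
      )
    )
}

#' Dendrite depth and relative depth within an imaging ROI
#'
#' A dendrite's depth is the mean depth of its spines; within each imaging
#' ROI (grouping column, default the neuron) relative depth is min-max
#' scaled across dendrites: most superficial dendrite = 0, deepest = 1.
#' ROIs with a single dendrite get `NA` relative depth.
#'
#' @param spine_tbl Spine table with `dendrite_id`, `z_um`.
#' @param dendrites Dendrite metadata mapping `dendrite_id` to the ROI
#'   grouping column.
#' @param roi Name of the ROI grouping column (default `"neuron_id"`).
#' @return Tibble with `dendrite_id`, the ROI column, `depth_um`,
#'   `rel_depth`.
#' @export
dendrite_depth <- function(spine_tbl, dendrites, roi = "neuron_id") {
  depths <- spine_tbl %>%
    distinct(.data$spine_id, .data$dendrite_id, .data$z_um) %>%
    group_by(.data$dendrite_id) %>%
    summarise(depth_um = mean(.data$z_um), .groups = "drop") %>%
    left_join(dendrites %>% select("dendrite_id", dplyr::all_of(roi)),
              by = "dendrite_id")
  .rel_minmax(depths, "depth_um", "rel_depth", group = roi)
}

#' Correlation between a per-unit value and a coordinate
#'
#' Pearson correlation between a value (e.g. VD7 relative change, or
#' baseline relative level) and a spatial coordinate (relative depth or
#' relative distance) across units.
#'
#' @param tbl Table holding both columns.
#' @param value,coord Column names.
#' @return Tibble with `r`, `p_value`, `n`.
#' @export
coordinate_correlation <- function(tbl, value, coord) {
  x <- tbl[[coord]]
  y <- tbl[[value]]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) abort("coordinate_correlation() needs >= 3 units")
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Change in the deepest vs most superficial spines of each dendrite
#'
#' Along each dendrite, compares the mean baseline-normalized change of
#' the deepest `fraction` of spines with the most superficial `fraction`
#' at the requested session. Group size is `max(1,
#' round(fraction * n))` with half rounded away from zero; ties in depth
#' are broken by spine id for determinism. Dendrites with too few spines
#' for non-overlapping groups are excluded and counted.
#'
#' @param tbl Baseline-normalized spine table with `spine_id`,
#'   `dendrite_id`, `session`, `z_um`, and the value column.
#' @param fraction Extreme fraction per group (default 0.15).
#' @param session Session evaluated (default `"VD7"`).
#' @param value Value column (default `"sglua1"`).
#' @return Tibble with `dendrite_id`, `n_spines`, `k`, `deep`,
#'   `superficial`.
#' @export
depth_extremes_change <- function(tbl, fraction = 0.15, session = "VD7",
                                  value = "sglua1") {
  min_n <- ceiling(1 / fraction)
  at <- tbl %>%
    filter(.data$session == .env$session, !is.na(.data[[value]])) %>%
    arrange(.data$dendrite_id, .data$z_um, .data$spine_id)
  out <- at %>%
    group_by(.data$dendrite_id) %>%
    summarise(
      n_spines = dplyr::n(),
      k = max(1, round_half_up(fraction * dplyr::n())),
      superficial = mean(head(.data[[value]], max(1, round_half_up(fraction * dplyr::n())))),
      deep = mean(tail(.data[[value]], max(1, round_half_up(fraction * dplyr::n())))),
      .groups = "drop"
    )
  n_excl <- sum(out$n_spines < min_n)
  if (n_excl > 0) {
    message("depth_extremes_change(): excluded ", n_excl,
            " dendrite(s) with < ", min_n, " spines")
  }
  out %>%
    filter(.data$n_spines >= min_n) %>%
    select("dendrite_id", "n_spines", "k", "deep", "superficial")
}
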