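# Small deterministic fixtures shared across test files.

# long table for one spine with given per-session sGluA1 ratios (already
# quantified); sessions taken from the schedule in order
trace_tbl <- function(values, schedule = "baseline10", spine_id = "s1",
                      dendrite_id = "d1") {
  sess <- schedule_sessions(schedule)$session[seq_along(values)]
  tibble::tibble(
    spine_id = spine_id, dendrite_id = dendrite_id,
    session = sess, sglua1 = values
  )
}

# raw ROI table for hand-computed normalization checks
raw_row <- function(green, bg_green, shaft, bg_shaft,
                    red = shaft, bg_red = bg_shaft, session = "D1") {
  tibble::tibble(
    spine_id = "s1", dendrite_id = "d1", session = session, present = TRUE,
    green_spine = green, red_spine = red, red_shaft = shaft,
    bg_green_spine = bg_green, bg_red_spine = bg_red, bg_red_shaft = bg_shaft
  )
}

# tiny deprivation-schedule dataset helper used by several files
small_vd_dataset <- function(seed = 11, preset = "L23_VD", ...) {
  simulate_spine_dataset(spine_preset(preset, ...), seed = seed)
}

# quantified + baseline-normalized dendrite summaries for a dataset
vd_dendrite_summaries <- function(ds) {
  q <- quantify_intensities(spine_table(ds))
  nb <- normalize_trace(q, "to_baseline_mean", ds$sessions)
  dendrite_summary(nb, ds$sessions)
}
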