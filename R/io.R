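.SPINE_SCHEMA_VERSION <- "1.0"

.spine_cols <- c(
  "spine_id", "dendrite_id", "neuron_id", "session", "present",
  "green_spine", "red_spine", "red_shaft",
  "bg_green_spine", "bg_red_spine", "bg_red_shaft",
  "x_um", "y_um", "z_um", "dist_branch_um"
)

.dendrite_cols <- c(
  "dendrite_id", "neuron_id", "compartment", "layer", "region",
  "genotype", "condition",
  "x_proximal_um", "y_proximal_um", "z_proximal_um",
  "x_distal_um", "y_distal_um", "z_distal_um", "arc_length_um"
)

.session_cols <- c("session", "session_index", "phase", "day")

.write_tsv_with_header <- function(tbl, path, what) {
  header <- c(
    paste0("# spinedyn ", what, " table; schema_version=", .SPINE_SCHEMA_VERSION),
    "# units: coordinates and distances in um (z increases downward from pia);",
    "#        intensities in arbitrary units; missing values empty"
  )
  writeLines(header, path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE, na = "")
  invisible(path)
}

#' Write a spine dataset to TSV tables
#'
#' Writes the long-format spine table plus its dendrite-metadata and
#' session companions as tab-separated files (`spines.tsv`,
#' `dendrites.tsv`, `sessions.tsv`) with a `#`-prefixed header recording
#' schema version and units. Output is byte-deterministic for a given
#' dataset.
#'
#' @param dataset A `spine_dataset`, or a list with elements
#'   `spine_table`, `dendrites`, `sessions`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_spine_table <- function(dataset, dir) {
  if (inherits(dataset, "spine_dataset")) {
    tabs <- list(
      spine_table = spine_table(dataset),
      dendrites = dendrite_table(dataset),
      sessions = dataset$sessions %>% select(-dplyr::any_of("true_gain"))
    )
  } else {
    tabs <- dataset
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv_with_header(tabs$spine_table[, .spine_cols],
                         file.path(dir, "spines.tsv"), "spine")
  .write_tsv_with_header(tabs$dendrites[, .dendrite_cols],
                         file.path(dir, "dendrites.tsv"), "dendrite")
  .write_tsv_with_header(tabs$sessions[, .session_cols],
                         file.path(dir, "sessions.tsv"), "session")
  invisible(dir)
}

.read_checked <- function(path, cols, what) {
  if (!file.exists(path)) abort(paste0(what, " table not found: ", path))
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         na = c("", "NA"))
  missing <- setdiff(cols, names(tbl))
  if (length(missing)) {
    abort(paste0(what, " table ", path, " missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tbl[, cols]
}

#' Read and validate a spine table directory
#'
#' Reads `spines.tsv`, `dendrites.tsv`, `sessions.tsv` written by
#' [write_spine_table()], validating the schema (named missing columns),
#' uniqueness of (spine_id, session) with the offending row reported,
#' foreign-key integrity, and non-emptiness.
#'
#' @param dir Directory containing the three tables.
#' @return A list with tibbles `spine_table`, `dendrites`, `sessions`.
#' @export
read_spine_table <- function(dir) {
  spines <- .read_checked(file.path(dir, "spines.tsv"), .spine_cols, "spine")
  dendrites <- .read_checked(file.path(dir, "dendrites.tsv"), .dendrite_cols,
                             "dendrite")
  sessions <- .read_checked(file.path(dir, "sessions.tsv"), .session_cols,
                            "session")
  if (nrow(spines) == 0L) abort("no spines")

  dup <- duplicated(spines[, c("spine_id", "session")])
  if (any(dup)) {
    abort(paste0("duplicate (spine_id, session) at row ", which(dup)[1], ": ",
                 spines$spine_id[which(dup)[1]], " / ",
                 spines$session[which(dup)[1]]))
  }
  bad_fk <- which(!spines$dendrite_id %in% dendrites$dendrite_id)
  if (length(bad_fk)) {
    abort(paste0("spine row ", bad_fk[1], " references unknown dendrite '",
                 spines$dendrite_id[bad_fk[1]], "'"))
  }
  bad_sess <- which(!spines$session %in% sessions$session)
  if (length(bad_sess)) {
    abort(paste0("spine row ", bad_sess[1], " references unknown session '",
                 spines$session[bad_sess[1]], "'"))
  }
  message("read_spine_table(): ", nrow(spines), " rows, ",
          length(unique(spines$spine_id)), " spines, ",
          nrow(dendrites), " dendrites")
  list(spine_table = spines, dendrites = dendrites, sessions = sessions)
}

#' Run the full analysis pipeline on a synthetic preset
#'
#' Simulates a dataset, quantifies it, runs the schedule-appropriate
#' analyses (baseline dynamics for 10-day schedules; deprivation
#' timecourse, response classification and day1/day7 correlation for
#' deprivation schedules; basal/apical ratios when both compartments are
#' present), and optionally writes all output tables, a JSON run manifest
#' and a plain-text summary to `out_dir`. Identical `(preset, seed)` runs
#' produce byte-identical outputs.
#'
#' @param preset Preset name (see [spine_preset()]) or a `spine_config`.
#' @param seed Integer seed (default: the config's).
#' @param out_dir Optional output directory.
#' @param threshold Decrease threshold for response classification
#'   (default 0.18, the dendrite-level reference constant; pass a value
#'   from [sham_threshold()] to calibrate from a sham arm).
#' @return A list of results (`dataset`, `quantified`, plus per-analysis
#'   tables and statistics), invisibly if `out_dir` is given.
#' @export
run_pipeline <- function(preset, seed = NULL, out_dir = NULL, threshold = 0.18) {
  cfg <- if (inherits(preset, "spine_config")) preset else spine_preset(preset)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  ds <- simulate_spine_dataset(cfg)
  sessions <- ds$sessions
  tbl <- spine_table(ds)
  q <- quantify_intensities(tbl)
  fates <- classify_spine_fate(q, sessions)

  res <- list(config = cfg, dataset = ds, quantified = q, fates = fates)
  res$persistence <- persistence_fraction(fates)

  rel <- relative_to_dendrite_mean(q)
  res$cv <- spine_cv(rel)

  if (cfg$schedule == "deprivation") {
    nb <- normalize_trace(q, "to_baseline_mean", sessions)
    dsum <- dendrite_summary(nb, sessions)
    res$dendrite_summary <- dsum
    res$timecourse <- timecourse(dsum, sessions)
    units <- dsum %>% rename(unit_id = "dendrite_id", value = "sglua1")
    res$classification <- classify_response(units, threshold = threshold)
    res$classification_summary <- classification_summary(res$classification)
    res$day1_day7 <- tryCatch(day1_day7_correlation(units),
                              error = function(e) NULL)
    dmeta <- dendrite_table(ds)
    if (all(c("apical", "basal") %in% dmeta$compartment)) {
      res$basal_apical <- basal_apical_ratio(dsum, dmeta)
    }
  } else {
    first <- sessions$session[1]
    last <- tail(sessions$session, 1)
    res$cross_day <- cross_day_correlation(rel, first, last)
    chg <- daily_change(q, sessions)
    res$coupling <- size_fluorescence_coupling(chg)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_spine_table(ds, file.path(out_dir, "tables"))
    readr::write_tsv(res$fates, file.path(out_dir, "spine_fates.tsv"))
    readr::write_tsv(res$cv, file.path(out_dir, "spine_cv.tsv"))
    if (!is.null(res$timecourse)) {
      readr::write_tsv(res$timecourse$summary,
                       file.path(out_dir, "timecourse.tsv"))
      readr::write_tsv(res$classification,
                       file.path(out_dir, "classification.tsv"))
    }
    manifest <- list(
      package = "spinedyn",
      version = as.character(utils::packageVersion("spinedyn")),
      preset = cfg$name, seed = cfg$seed,
      config_hash = rlang::hash(unclass(cfg)),
      schema_version = .SPINE_SCHEMA_VERSION
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    summary_lines <- c(
      paste0("preset: ", cfg$name, " (seed ", cfg$seed, ")"),
      sprintf("persistence: %.1f%%", res$persistence),
      sprintf("mean spine CV: %.3f", mean(res$cv$cv, na.rm = TRUE)),
      if (!is.null(res$classification_summary)) {
        sprintf("decrease fraction: %.2f%% (%d/%d)",
                res$classification_summary$pct_decrease,
                res$classification_summary$n_decrease,
                res$classification_summary$n_total)
      },
      if (!is.null(res$timecourse)) {
        paste0("timecourse means: ",
               paste(sprintf("%s=%.3f", res$timecourse$summary$session,
                             res$timecourse$summary$mean), collapse = " "))
      },
      if (!is.null(res$basal_apical)) {
        sprintf("mean basal/apical ratio: %.3f", mean(res$basal_apical$ratio))
      }
    )
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))
    return(invisible(res))
  }
  res
}
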