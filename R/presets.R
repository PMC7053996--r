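#' Synthetic experiment presets
#'
#' Fully parameterized configurations of the synthetic-data generator, one
#' per experimental arm: baseline imaging of layer 2/3 or layer 5 neurons,
#' sham surgery, binocular visual deprivation (VD) of V1 or non-V1 layer 2/3
#' apical or basal dendrites, VD of layer 5 apical dendrites, and VD in
#' GRIP1 knockout animals.
#'
#' Calibration notes (all downstream analyses are tested against these):
#' * Per-session spine survival is 0.958 for L2/3 (0.958^9 = 68% of the
#'   day-1 cohort persists over 10 daily sessions) and 0.955 for L5
#'   (0.955^9 = 66%).
#' * Day-to-day fluctuation CV is larger for L2/3 (0.30) than L5 (0.20);
#'   after deprivation it falls to 0.22 for L2/3 and rises to 0.26 for L5.
#' * Under VD, 51% of L2/3 apical dendrites belong to a "decrease"
#'   subpopulation that dips at VD1 and recovers, while the rest rise above
#'   baseline by VD7; basal dendrites increase from VD1 onward; non-V1
#'   dendrites decline; L5 and GRIP1-KO arms dip and recover with no net
#'   late increase.
#' * The deprivation effect on L2/3 neurons grows with relative spine depth
#'   (deeper spines potentiate more).
#'
#' @param name Preset identifier, one of `"L23_baseline"`, `"L23_sham"`,
#'   `"L23_VD"`, `"L23_VD_basal"`, `"nonV1_VD"`, `"L5_baseline"`,
#'   `"L5_VD"`, `"GRIP1KO_VD"`.
#' @param ... Named overrides for any configuration field (e.g.
#'   `n_neurons = 14`, `seed = 7`).
#' @return A validated `spine_config` object (a named list).
#' @export
#' @examples
#' cfg <- spine_preset("L23_VD", seed = 1)
#' cfg$survival_per_session
spine_preset <- function(name, ...) {
  presets <- .spine_presets()
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets)) {
    abort(paste0(
      "Unknown preset ", if (is.character(name)) paste0("'", name, "'") else "",
      ". Valid presets: ", paste(names(presets), collapse = ", ")
    ))
  }
  cfg <- presets[[name]]
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      abort(paste0("Unknown config field(s): ", paste(bad, collapse = ", ")))
    }
    cfg[names(overrides)] <- overrides
  }
  validate_spine_config(cfg)
}

#' @rdname spine_preset
#' @export
spine_preset_names <- function() names(.spine_presets())

.flat_timecourse <- function() {
  rep(1, 7)
}

.spine_presets <- function() {
  # fields shared by every arm
  base <- list(
    name = NA_character_,
    schedule = "deprivation",
    layer = "L23",
    region = "V1",
    genotype = "WT",
    condition = "VD",
    n_neurons = 8L,
    dendrites_per_neuron = 3L,
    compartments = c(apical = 1),
    spines_per_dendrite = c(mean = 12, min = 5),
    survival_per_session = 0.958,
    formation_rate = 0.2,
    baseline_log_mean = 0,
    baseline_log_sd = 0.5,
    size_coupling_rho = 0.7,
    fluctuation_cv = 0.30,
    fluctuation_cv_vd = 0.30,
    session_gain_sd = 0.1,
    background_level = 50,
    noise_sd = 3,
    intensity_scale = 1000,
    transient_level = 0.5,
    decrease_fraction = 0,
    subpop_level = "dendrite",
    effect_timecourse = list(
      apical = list(decrease = .flat_timecourse(), no_decrease = .flat_timecourse()),
      basal = list(decrease = .flat_timecourse(), no_decrease = .flat_timecourse())
    ),
    depth_gradient = 0,
    distance_gradient_baseline = 0.4,
    geometry = list(
      apical_z = c(30, 120),
      basal_z = c(150, 300),
      arc_length = c(35, 60),
      slope = c(0.05, 0.6)
    ),
    seed = 1L
  )

  with_fields <- function(...) {
    cfg <- base
    fields <- list(...)
    cfg[names(fields)] <- fields
    cfg
  }

  bl10 <- rep(1, 10)

  l23_vd_effect <- list(
    apical = list(
      decrease = c(1, 1, 1, 0.70, 0.90, 1.00, 1.00),
      no_decrease = c(1, 1, 1, 1.00, 1.05, 1.10, 1.30)
    ),
    basal = list(
      decrease = c(1, 1, 1, 1.15, 1.20, 1.25, 1.35),
      no_decrease = c(1, 1, 1, 1.15, 1.20, 1.25, 1.35)
    )
  )

  list(
    L23_baseline = with_fields(
      name = "L23_baseline", schedule = "baseline10", condition = "sham",
      effect_timecourse = list(
        apical = list(decrease = bl10, no_decrease = bl10),
        basal = list(decrease = bl10, no_decrease = bl10)
      )
    ),
    L23_sham = with_fields(
      name = "L23_sham", condition = "sham"
    ),
    L23_VD = with_fields(
      name = "L23_VD",
      n_neurons = 16L, dendrites_per_neuron = 4L,
      compartments = c(apical = 2, basal = 2),
      fluctuation_cv_vd = 0.22,
      decrease_fraction = 0.51,
      effect_timecourse = l23_vd_effect,
      depth_gradient = 0.25
    ),
    L23_VD_basal = with_fields(
      name = "L23_VD_basal",
      n_neurons = 10L, dendrites_per_neuron = 4L,
      compartments = c(basal = 1),
      fluctuation_cv_vd = 0.22,
      effect_timecourse = l23_vd_effect,
      depth_gradient = 0.25
    ),
    nonV1_VD = with_fields(
      name = "nonV1_VD", region = "nonV1",
      n_neurons = 11L,
      effect_timecourse = list(
        apical = list(
          decrease = c(1, 1, 1, 0.95, 0.92, 0.90, 0.85),
          no_decrease = c(1, 1, 1, 0.95, 0.92, 0.90, 0.85)
        ),
        basal = list(decrease = .flat_timecourse(), no_decrease = .flat_timecourse())
      )
    ),
    L5_baseline = with_fields(
      name = "L5_baseline", schedule = "baseline10", condition = "sham",
      layer = "L5",
      survival_per_session = 0.955,
      fluctuation_cv = 0.20, fluctuation_cv_vd = 0.20,
      effect_timecourse = list(
        apical = list(decrease = bl10, no_decrease = bl10),
        basal = list(decrease = bl10, no_decrease = bl10)
      )
    ),
    L5_VD = with_fields(
      name = "L5_VD", layer = "L5",
      n_neurons = 12L,
      survival_per_session = 0.955,
      fluctuation_cv = 0.20, fluctuation_cv_vd = 0.26,
      decrease_fraction = 0.5,
      subpop_level = "cell",
      effect_timecourse = list(
        apical = list(
          decrease = c(1, 1, 1, 0.80, 0.85, 0.95, 1.00),
          no_decrease = c(1, 1, 1, 1.00, 1.02, 1.05, 1.08)
        ),
        basal = list(decrease = .flat_timecourse(), no_decrease = .flat_timecourse())
      )
    ),
    GRIP1KO_VD = with_fields(
      name = "GRIP1KO_VD", genotype = "Grip1KO",
      n_neurons = 11L,
      decrease_fraction = 1,
      effect_timecourse = list(
        apical = list(
          decrease = c(1, 1, 1, 0.85, 0.85, 0.90, 1.00),
          no_decrease = c(1, 1, 1, 0.85, 0.85, 0.90, 1.00)
        ),
        basal = list(decrease = .flat_timecourse(), no_decrease = .flat_timecourse())
      )
    )
  )
}

#' Validate a synthetic-data configuration
#'
#' Checks the structural invariants of a generator configuration: all
#' probabilities in \[0, 1\], per-session survival in (0, 1\], positive
#' intensity parameters, effect timecourses matching the schedule length,
#' and sham arms having an identically flat (= 1) effect at every session.
#'
#' @param cfg A `spine_config` list, e.g. from [spine_preset()].
#' @return The validated config, invisibly classed `spine_config`.
#' @export
validate_spine_config <- function(cfg) {
  stopifnot(is.list(cfg))
  sessions <- schedule_sessions(cfg$schedule)
  n_sess <- nrow(sessions)

  chk <- function(ok, msg) if (!isTRUE(ok)) abort(paste0("Invalid config: ", msg))

  chk(cfg$survival_per_session > 0 && cfg$survival_per_session <= 1,
      "survival_per_session must be in (0, 1]")
  chk(cfg$decrease_fraction >= 0 && cfg$decrease_fraction <= 1,
      "decrease_fraction must be in [0, 1]")
  chk(cfg$formation_rate >= 0, "formation_rate must be >= 0")
  chk(cfg$n_neurons >= 1 && cfg$dendrites_per_neuron >= 1,
      "counts must be positive")
  chk(cfg$spines_per_dendrite[["mean"]] > 0, "spines_per_dendrite mean must be positive")
  chk(all(c(cfg$baseline_log_sd, cfg$fluctuation_cv, cfg$fluctuation_cv_vd,
            cfg$intensity_scale) > 0),
      "intensity/fluctuation parameters must be positive")
  chk(cfg$session_gain_sd >= 0 && cfg$noise_sd >= 0 && cfg$background_level >= 0,
      "noise parameters must be non-negative")
  chk(abs(cfg$size_coupling_rho) <= 1, "size_coupling_rho must be in [-1, 1]")
  chk(cfg$subpop_level %in% c("dendrite", "cell"), "subpop_level must be dendrite or cell")
  chk(all(names(cfg$compartments) %in% c("apical", "basal")) &&
        sum(cfg$compartments) >= 1,
      "compartments must be named apical/basal counts")

  for (comp in names(cfg$effect_timecourse)) {
    for (sub in names(cfg$effect_timecourse[[comp]])) {
      tc <- cfg$effect_timecourse[[comp]][[sub]]
      chk(length(tc) == n_sess,
          paste0("effect_timecourse$", comp, "$", sub,
                 " must have one value per session (", n_sess, ")"))
      chk(all(tc > 0), "effect_timecourse values must be positive")
      chk(all(tc[sessions$phase == "baseline"] == 1),
          "effect_timecourse must be 1 at baseline sessions")
      if (cfg$condition == "sham") {
        chk(all(tc == 1), "sham presets must have a flat effect_timecourse of 1")
      }
    }
  }
  if (cfg$condition == "sham") {
    chk(cfg$depth_gradient == 0, "sham presets must have depth_gradient = 0")
  }

  structure(cfg, class = "spine_config")
}

#' @export
print.spine_config <- function(x, ...) {
  cat("<spine_config>", x$name, "\n")
  cat("  schedule:", x$schedule, " layer:", x$layer, " region:", x$region,
      " genotype:", x$genotype, " condition:", x$condition, "\n")
  cat("  neurons:", x$n_neurons, "x", x$dendrites_per_neuron, "dendrites (",
      paste(names(x$compartments), x$compartments, collapse = ", "), ")\n")
  cat("  survival/session:", x$survival_per_session,
      " fluctuation CV:", x$fluctuation_cv, "->", x$fluctuation_cv_vd, "\n")
  cat("  decrease fraction:", x$decrease_fraction,
      " depth gradient:", x$depth_gradient, " seed:", x$seed, "\n")
  invisible(x)
}
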