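#' Simulate a longitudinal spine-imaging dataset
#'
#' Generates a synthetic two-channel ROI intensity dataset with the
#' statistical structure the downstream analyses assume: daily imaging
#' sessions, per-session spine survival and new-spine formation, lognormal
#' spine-to-spine variability in surface GluA1 (sGluA1) and spine size with
#' coupled day-to-day fluctuations, per-session multiplicative imaging gain
#' shared by all ROIs of a session (cancelled by shaft normalization),
#' transient-spine intensity ramps, and - for deprivation arms - dendrite-
#' or cell-level response subpopulations with a depth-dependent effect.
#'
#' The per-spine latent sGluA1 at session \eqn{s} is
#' \deqn{V_{is} = S_i \, e^{\epsilon_{is}} \, m_{is} \, r_{is}}
#' where \eqn{S_i} is a lognormal set-point (optionally scaled by relative
#' distance from the branch point), \eqn{\epsilon_{is}} is i.i.d. Gaussian
#' log-noise with variance chosen so the day-to-day coefficient of variation
#' matches `fluctuation_cv` (or `fluctuation_cv_vd` at post-deprivation
#' sessions), \eqn{m_{is}} is the deprivation effect
#' `effect_timecourse[session] * (1 + depth_gradient * relative_depth)`
#' (the depth term applies at post-deprivation sessions only), and
#' \eqn{r_{is}} is a 2-session linear ramp for newly formed / soon-to-be
#' eliminated spines. Spine size follows the same model with log-noise
#' correlated at `size_coupling_rho` and a square-root-attenuated
#' deprivation effect (size changes track sGluA1 but are smaller).
#'
#' Raw ROI intensities are `gain_s * intensity_scale * latent +
#' background_level + noise`, with matched background ROIs carrying
#' `background_level + noise`, so that background subtraction followed by
#' division by the background-subtracted shaft dsRed recovers the latent
#' value up to additive noise.
#'
#' Columns prefixed `true_` (and the dendrites' `true_subpop`) are latent
#' ground truth for generator tests only; analysis functions never read
#' them, and [spine_table()] drops them.
#'
#' @param config A `spine_config`, e.g. from [spine_preset()].
#' @param seed Integer seed; defaults to `config$seed`. The dataset is a
#'   deterministic function of `(config, seed)`.
#' @return A `spine_dataset`: a list with tibbles `sessions`, `neurons`,
#'   `dendrites`, `spines`, `intensities`, plus the `config` and `seed`.
#' @export
#' @examples
#' ds <- simulate_spine_dataset(spine_preset("L23_baseline", n_neurons = 2), seed = 1)
#' head(ds$intensities)
simulate_spine_dataset <- function(config, seed = NULL) {
  cfg <- if (inherits(config, "spine_config")) config else validate_spine_config(config)
  if (is.null(seed)) seed <- cfg$seed
  set.seed(as.integer(seed))

  sessions <- schedule_sessions(cfg$schedule)
  n_sess <- nrow(sessions)
  vd_phase <- sessions$phase == "deprivation"

  ## --- neurons and dendrites -------------------------------------------
  neurons <- tibble(
    neuron_id = sprintf("n%02d", seq_len(cfg$n_neurons)),
    layer = cfg$layer, region = cfg$region,
    genotype = cfg$genotype, condition = cfg$condition
  )

  comp_cycle <- rep(names(cfg$compartments), times = cfg$compartments)
  comp_assign <- rep(comp_cycle, length.out = cfg$dendrites_per_neuron)

  dendrites <- purrr::map_dfr(neurons$neuron_id, function(nid) {
    tibble(
      dendrite_id = sprintf("%s_d%02d", nid, seq_len(cfg$dendrites_per_neuron)),
      neuron_id = nid,
      compartment = comp_assign
    )
  })
  n_dend <- nrow(dendrites)

  geo <- cfg$geometry
  z_range <- function(comp) if (comp == "apical") geo$apical_z else geo$basal_z
  dendrites <- dendrites %>%
    mutate(
      arc_length_um = runif(n_dend, geo$arc_length[1], geo$arc_length[2]),
      slope = runif(n_dend, geo$slope[1], geo$slope[2]) *
        sample(c(-1, 1), n_dend, replace = TRUE),
      z_proximal_um = purrr::map_dbl(.data$compartment,
                                     ~ runif(1, z_range(.x)[1], z_range(.x)[2])),
      x_proximal_um = runif(n_dend, 0, 80),
      y_proximal_um = runif(n_dend, 0, 80),
      z_distal_um = .data$z_proximal_um + .data$slope * .data$arc_length_um,
      x_distal_um = .data$x_proximal_um +
        .data$arc_length_um * sqrt(pmax(0, 1 - .data$slope^2)),
      y_distal_um = .data$y_proximal_um
    )

  ## response subpopulation (latent): per dendrite, or per cell for L5
  if (cfg$subpop_level == "cell") {
    cell_sub <- tibble(
      neuron_id = neurons$neuron_id,
      true_subpop = if_else(
        rbinom(cfg$n_neurons, 1, cfg$decrease_fraction) == 1L,
        "decrease", "no_decrease"
      )
    )
    dendrites <- left_join(dendrites, cell_sub, by = "neuron_id")
  } else {
    dendrites$true_subpop <- if_else(
      rbinom(n_dend, 1, cfg$decrease_fraction) == 1L, "decrease", "no_decrease"
    )
  }

  ## --- spines -----------------------------------------------------------
  sp_mean <- cfg$spines_per_dendrite[["mean"]]
  sp_min <- cfg$spines_per_dendrite[["min"]]
  n_per_dend <- pmax(sp_min, rpois(n_dend, sp_mean))

  spines <- purrr::map_dfr(seq_len(n_dend), function(i) {
    d <- dendrites[i, ]
    n <- n_per_dend[i]
    dist <- sort(runif(n, 1, d$arc_length_um - 1))
    tibble(
      spine_id = sprintf("%s_s%03d", d$dendrite_id, seq_len(n)),
      dendrite_id = d$dendrite_id,
      dist_branch_um = dist,
      x_um = d$x_proximal_um + dist * sqrt(pmax(0, 1 - d$slope^2)),
      y_um = d$y_proximal_um,
      z_um = d$z_proximal_um + d$slope * dist,
      formed_at = 1L
    )
  })

  ## new spines appearing at later sessions
  if (cfg$formation_rate > 0 && n_sess > 1) {
    n_new <- rpois(n_dend * (n_sess - 1), cfg$formation_rate)
    idx <- which(n_new > 0)
    if (length(idx)) {
      formed <- purrr::map_dfr(idx, function(k) {
        i <- ((k - 1) %/% (n_sess - 1)) + 1
        s <- ((k - 1) %% (n_sess - 1)) + 2
        d <- dendrites[i, ]
        n <- n_new[k]
        dist <- runif(n, 1, d$arc_length_um - 1)
        tibble(
          spine_id = sprintf("%s_f%02d_%02d", d$dendrite_id, s, seq_len(n)),
          dendrite_id = d$dendrite_id,
          dist_branch_um = dist,
          x_um = d$x_proximal_um + dist * sqrt(pmax(0, 1 - d$slope^2)),
          y_um = d$y_proximal_um,
          z_um = d$z_proximal_um + d$slope * dist,
          formed_at = s
        )
      })
      spines <- bind_rows(spines, formed)
    }
  }
  n_spine <- nrow(spines)

  ## presence: survive each transition independently after first detection
  present <- matrix(FALSE, n_spine, n_sess)
  surv_draw <- matrix(runif(n_spine * n_sess) < cfg$survival_per_session,
                      n_spine, n_sess)
  for (i in seq_len(n_spine)) {
    f <- spines$formed_at[i]
    present[i, f] <- TRUE
    if (f < n_sess) {
      for (s in (f + 1):n_sess) {
        present[i, s] <- present[i, s - 1] && surv_draw[i, s]
      }
    }
  }
  first_det <- apply(present, 1, function(p) which(p)[1])
  last_det <- apply(present, 1, function(p) max(which(p)))
  persistent <- first_det == 1L & last_det == n_sess

  ## relative coordinates within each dendrite (used by the generator only;
  ## analyses recompute them from the observed table)
  rel_by_dend <- function(x, id) {
    stats::ave(x, id, FUN = function(v) {
      r <- range(v)
      if (diff(r) == 0) rep(0.5, length(v)) else (v - r[1]) / diff(r)
    })
  }
  rel_depth <- rel_by_dend(spines$z_um, spines$dendrite_id)
  rel_dist <- rel_by_dend(spines$dist_branch_um, spines$dendrite_id)

  ## --- latent set-points -----------------------------------------------
  rho <- cfg$size_coupling_rho
  z1 <- rnorm(n_spine)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_spine)
  set_glua <- exp(cfg$baseline_log_mean + cfg$baseline_log_sd * z1) *
    (1 + cfg$distance_gradient_baseline * rel_dist)
  set_size <- exp(cfg$baseline_log_mean + cfg$baseline_log_sd * z2) *
    (1 + cfg$distance_gradient_baseline * rel_dist)
  set_glua[!persistent] <- set_glua[!persistent] * cfg$transient_level
  set_size[!persistent] <- set_size[!persistent] * cfg$transient_level

  ## --- daily fluctuations (coupled in log space) ------------------------
  cv_s <- ifelse(vd_phase, cfg$fluctuation_cv_vd, cfg$fluctuation_cv)
  sigma_s <- sqrt(log(1 + cv_s^2))
  zg <- matrix(rnorm(n_spine * n_sess), n_spine, n_sess)
  ze <- matrix(rnorm(n_spine * n_sess), n_spine, n_sess)
  sig <- matrix(sigma_s, n_spine, n_sess, byrow = TRUE)
  eps_glua <- sig * zg - sig^2 / 2
  eps_size <- sig * (rho * zg + sqrt(1 - rho^2) * ze) - sig^2 / 2

  ## --- deprivation effect ----------------------------------------------
  dmeta <- dendrites[match(spines$dendrite_id, dendrites$dendrite_id), ]
  eff <- matrix(1, n_spine, n_sess)
  for (comp in unique(dmeta$compartment)) {
    for (sub in c("decrease", "no_decrease")) {
      rows <- which(dmeta$compartment == comp & dmeta$true_subpop == sub)
      if (length(rows)) {
        tc <- cfg$effect_timecourse[[comp]][[sub]]
        eff[rows, ] <- matrix(tc, length(rows), n_sess, byrow = TRUE)
      }
    }
  }
  # centred on the dendrite midpoint so the gradient redistributes the
  # deprivation effect across depth without shifting the session mean
  grad <- 1 + cfg$depth_gradient * (rel_depth - 0.5)
  eff[, vd_phase] <- eff[, vd_phase] * grad

  ## --- transient ramps: linear over 2 sessions --------------------------
  ramp <- matrix(1, n_spine, n_sess)
  for (i in which(first_det > 1L)) {
    f <- first_det[i]
    ramp[i, f] <- ramp[i, f] * 0.5
    if (f + 1 <= n_sess) ramp[i, f + 1] <- ramp[i, f + 1] * 0.75
  }
  for (i in which(last_det < n_sess)) {
    l <- last_det[i]
    ramp[i, l] <- ramp[i, l] * 0.5
    if (l - 1 >= 1) ramp[i, l - 1] <- ramp[i, l - 1] * 0.75
  }

  true_glua <- set_glua * exp(eps_glua) * eff * ramp
  true_size <- set_size * exp(eps_size) * sqrt(eff) * ramp

  ## --- raw ROI intensities ---------------------------------------------
  gain <- exp(rnorm(n_sess, 0, cfg$session_gain_sd))
  gmat <- matrix(gain, n_spine, n_sess, byrow = TRUE)
  scale <- cfg$intensity_scale
  bg <- cfg$background_level
  nz <- function() matrix(rnorm(n_spine * n_sess, 0, cfg$noise_sd), n_spine, n_sess)

  raw <- list(
    green_spine = gmat * scale * true_glua + bg + nz(),
    red_spine = gmat * scale * true_size + bg + nz(),
    red_shaft = gmat * scale + bg + nz(),
    bg_green_spine = bg + nz(),
    bg_red_spine = bg + nz(),
    bg_red_shaft = bg + nz()
  )

  intensities <- tidyr::expand_grid(
    spine_id = spines$spine_id,
    session = sessions$session
  ) %>%
    mutate(
      present = as.vector(t(present)),
      green_spine = as.vector(t(raw$green_spine)),
      red_spine = as.vector(t(raw$red_spine)),
      red_shaft = as.vector(t(raw$red_shaft)),
      bg_green_spine = as.vector(t(raw$bg_green_spine)),
      bg_red_spine = as.vector(t(raw$bg_red_spine)),
      bg_red_shaft = as.vector(t(raw$bg_red_shaft)),
      true_sglua1 = as.vector(t(true_glua)),
      true_size = as.vector(t(true_size))
    ) %>%
    mutate(across(
      c("green_spine", "red_spine", "red_shaft",
        "bg_green_spine", "bg_red_spine", "bg_red_shaft",
        "true_sglua1", "true_size"),
      ~ if_else(.data$present, .x, NA_real_)
    ))

  spines <- spines %>%
    mutate(
      true_set_point_sglua1 = set_glua,
      true_set_point_size = set_size,
      true_persistent = persistent
    ) %>%
    select(-"formed_at")

  sessions$true_gain <- gain

  structure(
    list(
      config = cfg, seed = as.integer(seed),
      sessions = sessions, neurons = neurons,
      dendrites = dendrites, spines = spines,
      intensities = intensities
    ),
    class = "spine_dataset"
  )
}

#' @export
print.spine_dataset <- function(x, ...) {
  cat("<spine_dataset>", x$config$name, " seed:", x$seed, "\n")
  cat(" ", nrow(x$neurons), "neurons,", nrow(x$dendrites), "dendrites,",
      nrow(x$spines), "spines,", nrow(x$sessions), "sessions\n")
  invisible(x)
}

#' Observed long-format spine table
#'
#' Joins the per-session ROI intensities with spine geometry into the
#' long observed table consumed by the quantification functions, dropping
#' every latent (`true_*`) ground-truth column.
#'
#' @param dataset A `spine_dataset`.
#' @return A tibble with one row per spine x session: identifiers,
#'   coordinates, `present`, and the six raw ROI intensity columns.
#' @export
spine_table <- function(dataset) {
  stopifnot(inherits(dataset, "spine_dataset"))
  dataset$intensities %>%
    select(-dplyr::starts_with("true_")) %>%
    left_join(
      dataset$spines %>%
        select(-dplyr::starts_with("true_")),
      by = "spine_id"
    ) %>%
    left_join(
      dataset$dendrites %>% select("dendrite_id", "neuron_id"),
      by = "dendrite_id"
    ) %>%
    select(
      "spine_id", "dendrite_id", "neuron_id", "session", "present",
      "green_spine", "red_spine", "red_shaft",
      "bg_green_spine", "bg_red_spine", "bg_red_shaft",
      "x_um", "y_um", "z_um", "dist_branch_um"
    )
}

#' Observed dendrite metadata
#'
#' Dendrite-level metadata (compartment, layer, region, genotype,
#' condition, endpoint coordinates) without the latent subpopulation label.
#'
#' @param dataset A `spine_dataset`.
#' @return A tibble with one row per dendrite.
#' @export
dendrite_table <- function(dataset) {
  stopifnot(inherits(dataset, "spine_dataset"))
  dataset$dendrites %>%
    select(-dplyr::any_of("true_subpop")) %>%
    left_join(dataset$neurons, by = "neuron_id")
}
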