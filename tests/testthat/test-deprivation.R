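test_that("sham threshold is the SD of percent change", {
  expect_equal(sham_threshold(c(0.9, 1.0, 1.1)), 0.1)
  expect_warning(sham_threshold(c(1, 1, 1)), "degenerate")
  expect_error(sham_threshold(c(1, 1.1)), ">= 3")
})

test_that("response classification applies the pure threshold rule", {
  tbl <- tibble::tibble(unit_id = c("a", "b"), session = "VD1",
                        value = c(0.80, 0.90))
  cl <- classify_response(tbl, threshold = 0.18)
  expect_equal(cl$label, c("decrease", "no_decrease"))
  # boundary: exactly 1 - threshold counts as decrease
  cl <- classify_response(tibble::tibble(unit_id = "c", session = "VD1",
                                         value = 0.82),
                          threshold = 0.18)
  expect_equal(cl$label, "decrease")
  expect_error(classify_response(tbl, threshold = 0), "positive")
  # missing VD1 excluded with a message
  tbl2 <- tibble::tibble(unit_id = c("a", "b"), session = "VD1",
                         value = c(0.5, NA))
  expect_message(cl <- classify_response(tbl2, 0.18), "excluded 1")
  expect_equal(nrow(cl), 1)
})

test_that("classification summary reproduces the published decrease percentage", {
  cs <- classification_summary(rep(c("decrease", "no_decrease"), c(25, 24)))
  expect_equal(cs$pct_decrease, 51.02, tolerance = 1e-4)
  expect_equal(cs$n_total, 49)
})

test_that("day1/day7 correlation is Pearson over paired units", {
  tbl <- tibble::tibble(
    unit_id = rep(paste0("d", 1:5), 2),
    session = rep(c("VD1", "VD7"), each = 5),
    value = c(1:5, 1:5 * 2)
  )
  expect_equal(day1_day7_correlation(tbl)$r, 1)
  expect_error(day1_day7_correlation(tbl[c(1, 6), ]), ">= 3")
})

test_that("basal/apical ratios pool compartments by geometric mean", {
  dends <- tibble::tibble(
    dendrite_id = c("a1", "a2", "b1", "b2"),
    neuron_id = "n1",
    compartment = c("apical", "apical", "basal", "basal")
  )
  dsum <- tibble::tibble(
    dendrite_id = c("a1", "a2", "b1", "b2"), session = "VD7",
    sglua1 = c(1.0, 1.0, 1.2, 1.2)
  )
  ba <- basal_apical_ratio(dsum, dends)
  expect_equal(ba$ratio, 1.2)
  dsum$sglua1 <- c(0.5, 2, 1, 4)  # geometric means: apical 1, basal 2
  expect_equal(basal_apical_ratio(dsum, dends)$ratio, 2)
  # identical compartments give exactly 1
  dsum$sglua1 <- c(1.3, 1.3, 1.3, 1.3)
  expect_equal(basal_apical_ratio(dsum, dends)$ratio, 1)
  # apical change below the guard excludes the neuron
  dsum$sglua1 <- c(0.01, 0.01, 1.2, 1.2)
  expect_message(ba <- basal_apical_ratio(dsum, dends), "excluded 1 neuron")
  expect_equal(nrow(ba), 0)
})

test_that("relative coordinates min-max scale within the dendrite", {
  tbl <- tibble::tibble(
    spine_id = paste0("s", 1:3), dendrite_id = "d1",
    z_um = c(100, 110, 120), dist_branch_um = c(10, 30, 50)
  )
  out <- relative_distance_on_dendrite(relative_depth_on_dendrite(tbl))
  expect_equal(out$rel_depth, c(0, 0.5, 1))
  expect_equal(out$rel_distance, c(0, 0.5, 1))
  # two spines span 0 and 1
  two <- relative_depth_on_dendrite(tbl[c(1, 3), ])
  expect_equal(two$rel_depth, c(0, 1))
  # positive affine transforms of z leave relative depth unchanged
  tbl2 <- tbl; tbl2$z_um <- 3 * tbl2$z_um + 17
  expect_equal(relative_depth_on_dendrite(tbl2)$rel_depth, out$rel_depth)
  # degenerate: all spines at one depth -> NA (dendrite excluded)
  flat <- tbl; flat$z_um <- 100
  expect_true(all(is.na(relative_depth_on_dendrite(flat)$rel_depth)))
})

test_that("dendrite orientation follows the endpoint depth/distance rule", {
  dends <- tibble::tibble(
    dendrite_id = c("asc", "desc", "flat"),
    z_proximal_um = c(100, 100, 100),
    z_distal_um = c(90, 110, 102),     # -10, +10, +2 um over 50 um
    arc_length_um = 50
  )
  out <- dendrite_orientation(dends)
  expect_equal(out$orientation, c("ascending", "descending", "excluded"))
  expect_equal(out$depth_distance_ratio, c(0.2, 0.2, 0.04))
  expect_error(
    dendrite_orientation(dplyr::mutate(dends, arc_length_um = 0)),
    "arc length"
  )
  # inverting the z axis flips ascending and descending
  flipped <- dends
  flipped$z_proximal_um <- -dends$z_proximal_um
  flipped$z_distal_um <- -dends$z_distal_um
  out2 <- dendrite_orientation(flipped)
  expect_equal(out2$orientation, c("descending", "ascending", "excluded"))
})

test_that("ascending and descending dendrites partition non-excluded segments", {
  ds <- small_vd_dataset(seed = 15)
  o <- dendrite_orientation(dendrite_table(ds))
  expect_true(all(o$orientation %in% c("ascending", "descending", "excluded")))
  tab <- table(o$orientation)
  expect_equal(sum(tab), nrow(o))
})

test_that("dendrite depth averages spines and scales within the imaging ROI", {
  spines <- tibble::tibble(
    spine_id = paste0("s", 1:6),
    dendrite_id = rep(c("d1", "d2", "d3"), each = 2),
    z_um = c(95, 105, 145, 155, 195, 205)
  )
  dends <- tibble::tibble(dendrite_id = c("d1", "d2", "d3"), neuron_id = "n1")
  out <- dendrite_depth(spines, dends)
  expect_equal(out$depth_um, c(100, 150, 200))
  expect_equal(out$rel_depth, c(0, 0.5, 1))
  # a single dendrite in the ROI has undefined relative depth
  solo <- dendrite_depth(spines[1:2, ], dends[1, ])
  expect_true(is.na(solo$rel_depth))
})

test_that("coordinate correlations recover identity and the sham null", {
  tbl <- tibble::tibble(v = 1:10 / 10, d = 1:10 / 10)
  expect_equal(coordinate_correlation(tbl, "v", "d")$r, 1)
  expect_error(coordinate_correlation(tbl[1:2, ], "v", "d"), ">= 3")
  # sham arm: no depth dependence of the VD7 change
  ds <- simulate_spine_dataset(spine_preset("L23_sham"), seed = 16)
  dsum <- suppressMessages(vd_dendrite_summaries(ds))
  dd <- dendrite_depth(spine_table(ds), dendrite_table(ds))
  vd7 <- dplyr::inner_join(
    dplyr::filter(dsum, session == "VD7"), dd, by = "dendrite_id"
  )
  cc <- coordinate_correlation(vd7, "sglua1", "depth_um")
  expect_gt(cc$p_value, 0.05)
})

test_that("depth extremes use the rounded group size and detect no false gradient", {
  tbl <- tibble::tibble(
    spine_id = paste0("s", 1:20), dendrite_id = "d1", session = "VD7",
    z_um = 1:20, sglua1 = rep(1.1, 20)
  )
  out <- depth_extremes_change(tbl)
  expect_equal(out$k, 3)  # round(0.15 * 20)
  expect_equal(out$deep, out$superficial)  # uniform change
  # group size floors at 1 and requires non-overlapping groups
  out7 <- depth_extremes_change(dplyr::slice(tbl, 1:7))
  expect_equal(out7$k, 1)
  expect_message(depth_extremes_change(dplyr::slice(tbl, 1:5)), "excluded")
})

test_that("sham-calibrated classification recovers the generator subpopulations", {
  sham <- simulate_spine_dataset(spine_preset("L23_sham"), seed = 17)
  sham_sum <- suppressMessages(vd_dendrite_summaries(sham))
  thr <- sham_threshold(sham_sum$sglua1[sham_sum$session == "VD1"])
  expect_gt(thr, 0.03); expect_lt(thr, 0.25)

  ds <- simulate_spine_dataset(spine_preset("L23_VD"), seed = 18)
  dsum <- suppressMessages(vd_dendrite_summaries(ds))
  apical <- dplyr::semi_join(
    dsum, dplyr::filter(dendrite_table(ds), compartment == "apical"),
    by = "dendrite_id"
  )
  units <- dplyr::rename(apical, unit_id = dendrite_id, value = sglua1)
  cl <- classify_response(units, threshold = thr)
  truth <- dplyr::select(ds$dendrites, unit_id = dendrite_id, true_subpop)
  joined <- dplyr::inner_join(cl, truth, by = "unit_id")
  acc <- mean((joined$label == "decrease") ==
                (joined$true_subpop == "decrease"))
  expect_gte(acc, 0.9)
})

test_that("timecourse flags deprivation effects and spares the sham arm", {
  sham <- simulate_spine_dataset(spine_preset("L23_sham"), seed = 19)
  tc_sham <- suppressMessages(
    timecourse(vd_dendrite_summaries(sham), sham$sessions)
  )
  expect_gt(tc_sham$stat$p_value, 0.05)

  ds <- simulate_spine_dataset(spine_preset("L23_VD"), seed = 19)
  dsum <- suppressMessages(vd_dendrite_summaries(ds))
  apical <- dplyr::semi_join(
    dsum, dplyr::filter(dendrite_table(ds), compartment == "apical"),
    by = "dendrite_id"
  )
  tc <- suppressMessages(timecourse(apical, ds$sessions))
  expect_gt(tc$summary$mean[tc$summary$session == "VD7"], 1)
  expect_lt(tc$stat$p_value, 0.05)
  # day1-day7 correlation induced by the shared subpopulation effect
  units <- dplyr::rename(apical, unit_id = dendrite_id, value = sglua1)
  expect_gt(day1_day7_correlation(units)$r, 0)
})
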