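sess10 <- schedule_sessions("baseline10")

presence_tbl <- function(pattern, spine_id = "s1") {
  tibble::tibble(spine_id = spine_id, session = sess10$session,
                 present = pattern)
}

test_that("spine fates follow the presence pattern with gap tolerance", {
  f <- classify_spine_fate(presence_tbl(rep(TRUE, 10)), sess10)
  expect_equal(f$fate, "persistent")
  f <- classify_spine_fate(presence_tbl(c(rep(FALSE, 3), rep(TRUE, 7))), sess10)
  expect_equal(f$fate, "formed")
  expect_equal(f$first_detected, "D4")
  f <- classify_spine_fate(presence_tbl(c(rep(TRUE, 6), rep(FALSE, 4))), sess10)
  expect_equal(f$fate, "eliminated")
  expect_equal(f$last_detected, "D6")
  # interior gap = detection failure, spine spans the schedule -> persistent
  gap <- rep(TRUE, 10); gap[5] <- FALSE
  expect_equal(classify_spine_fate(presence_tbl(gap), sess10)$fate, "persistent")
  # formed then eliminated
  f <- classify_spine_fate(presence_tbl(c(FALSE, TRUE, TRUE, rep(FALSE, 7))),
                           sess10)
  expect_equal(f$fate, "formed_and_eliminated")
  expect_error(classify_spine_fate(presence_tbl(rep(FALSE, 10)), sess10),
               "never-present")
})

test_that("persistence fraction counts persistent spines in the day-1 cohort", {
  tbl <- dplyr::bind_rows(
    presence_tbl(rep(TRUE, 10), "a"),
    presence_tbl(rep(TRUE, 10), "b"),
    presence_tbl(c(rep(TRUE, 5), rep(FALSE, 5)), "c"),
    presence_tbl(c(rep(FALSE, 5), rep(TRUE, 5)), "d")
  )
  f <- classify_spine_fate(tbl, sess10)
  # 2 persistent of 3 spines present at D1 (the formed spine is excluded)
  expect_equal(persistence_fraction(f), 100 * 2 / 3)
  # all tracked spines as denominator: 2 of 4
  expect_equal(persistence_fraction(f, cohort = "all"), 50)
  f_all <- classify_spine_fate(presence_tbl(rep(TRUE, 10)), sess10)
  expect_equal(persistence_fraction(f_all), 100)
})

test_that("spine CV matches hand arithmetic and is scale invariant", {
  cv_tbl <- function(vals) {
    spine_cv(trace_tbl(vals), value = "sglua1")
  }
  expect_equal(suppressMessages(cv_tbl(c(3, 3, 3)))$cv, 0)
  expect_equal(suppressMessages(cv_tbl(c(2, 4, 3)))$cv, 1 / 3)  # sd 1, mean 3
  # fewer than 3 valid sessions -> NA
  expect_true(is.na(suppressMessages(cv_tbl(c(2, 4)))$cv))
  set.seed(5)
  v <- rlnorm(6)
  expect_equal(suppressMessages(cv_tbl(v * 7))$cv,
               suppressMessages(cv_tbl(v))$cv)
})

test_that("cross-day correlation behaves as Pearson on paired spines", {
  tbl <- tibble::tibble(
    spine_id = rep(paste0("s", 1:3), 2),
    session = rep(c("D1", "D10"), each = 3),
    sglua1 = c(1, 2, 3, 1, 2, 3)
  )
  expect_equal(cross_day_correlation(tbl, "D1", "D10")$r, 1)
  tbl$sglua1[4:6] <- c(3, 2, 1)
  expect_equal(cross_day_correlation(tbl, "D1", "D10")$r, -1)
  # joint permutation invariance
  set.seed(9)
  big <- tibble::tibble(
    spine_id = rep(paste0("s", 1:20), 2),
    session = rep(c("D1", "D10"), each = 20),
    sglua1 = rlnorm(40)
  )
  r1 <- cross_day_correlation(big, "D1", "D10")$r
  r2 <- cross_day_correlation(big[sample(nrow(big)), ], "D1", "D10")$r
  expect_equal(r1, r2)
  expect_error(cross_day_correlation(tbl[c(1, 4), ], "D1", "D10"), ">= 3")
})

test_that("size-fluorescence coupling recovers perfect and inverse coupling", {
  set.seed(2)
  ch <- tibble::tibble(
    spine_id = rep(paste0("s", 1:10), each = 5),
    sglua1 = rlnorm(50, sdlog = 0.3)
  )
  ch$size <- ch$sglua1
  cp <- size_fluorescence_coupling(ch)
  expect_equal(cp$pooled$r, 1)
  expect_equal(cp$inverse_fraction, 0)
  # reciprocal changes: per-spine correlation negative for every spine
  ch$size <- 1 / ch$sglua1
  cp <- size_fluorescence_coupling(ch)
  expect_true(all(cp$per_spine$r < 0))
  expect_equal(cp$inverse_fraction, 1)
})

test_that("distribution shift reports KS extremes and shift direction", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(distribution_shift(a, a)$statistic, 0)
  expect_equal(distribution_shift(a, a + 10)$statistic, 1)
  set.seed(4)
  x <- rnorm(200); y <- rnorm(200) + 0.5
  d <- distribution_shift(x, y)
  expect_true(d$median_a < d$median_b)
  expect_error(distribution_shift(1, a), ">= 2")
})

test_that("transient spines sit below persistent spines and are more variable", {
  ds <- simulate_spine_dataset(spine_preset("L23_baseline"), seed = 21)
  q <- quantify_intensities(spine_table(ds))
  fates <- classify_spine_fate(q, ds$sessions)
  rel <- relative_to_dendrite_mean(q)

  expect_error(
    transient_intensity(rel, fates[fates$fate == "persistent", ][1, ], ds$sessions),
    "persistent"
  )
  trans <- fates[fates$fate != "persistent", ]
  ti <- transient_intensity(rel, trans, ds$sessions)
  # relative level at the event is below the dendrite mean of 1
  expect_true(mean(ti$at_event$value, na.rm = TRUE) < 1)
  # transient spines are more variable than persistent ones
  cv_p <- suppressMessages(spine_cv(
    dplyr::semi_join(rel, fates[fates$fate == "persistent", ], by = "spine_id")
  ))
  cv_t <- suppressMessages(spine_cv(
    dplyr::semi_join(rel, trans, by = "spine_id")
  ))
  expect_gt(mean(cv_t$cv, na.rm = TRUE), mean(cv_p$cv, na.rm = TRUE))
})

test_that("eliminated spines ramp down over their final sessions in latent values", {
  cfg <- spine_preset("L23_baseline", noise_sd = 0, session_gain_sd = 0,
                      fluctuation_cv = 1e-4, fluctuation_cv_vd = 1e-4)
  ds <- simulate_spine_dataset(cfg, seed = 8)
  q <- quantify_intensities(spine_table(ds))
  fates <- classify_spine_fate(q, ds$sessions)
  elim <- fates[fates$fate == "eliminated" & fates$n_present >= 3, ]
  expect_gt(nrow(elim), 0)
  traj <- q |>
    dplyr::semi_join(elim, by = "spine_id") |>
    dplyr::filter(!is.na(sglua1)) |>
    dplyr::left_join(ds$sessions, by = "session") |>
    dplyr::arrange(spine_id, session_index)
  last_two <- traj |>
    dplyr::group_by(spine_id) |>
    dplyr::slice_tail(n = 2) |>
    dplyr::summarise(drop = dplyr::first(sglua1) >= dplyr::last(sglua1))
  expect_true(all(last_two$drop))
})
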