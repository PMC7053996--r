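test_that("shaft-ratio normalization matches hand arithmetic and flags bad ROIs", {
  expect_equal(normalize_spine_value(200, 50, 350, 50), 0.5)  # 150/300
  # spine ROI identical to shaft ROI with equal backgrounds
  expect_equal(normalize_spine_value(300, 50, 300, 50), 1.0)
  # zero numerator floored at eps, flagged
  expect_equal(normalize_spine_value(100, 100, 300, 50), 1e-6 / 250)
  expect_equal(normalize_flag(100, 100, 300, 50), "floored")
  # non-positive denominator invalid
  expect_true(is.na(normalize_spine_value(200, 50, 40, 50)))
  expect_equal(normalize_flag(200, 50, 40, 50), "invalid_shaft")
})

test_that("normalization is invariant to a common multiplicative gain", {
  set.seed(101)
  for (i in 1:50) {
    r <- runif(4, 10, 500)
    r[3] <- r[3] + 600  # keep the shaft denominator positive
    c_gain <- runif(1, 0.1, 10)
    expect_equal(
      normalize_spine_value(r[1] * c_gain, r[2] * c_gain,
                            r[3] * c_gain, r[4] * c_gain),
      normalize_spine_value(r[1], r[2], r[3], r[4])
    )
  }
})

test_that("quantify_intensities flags propagate as missing values", {
  tbl <- dplyr::bind_rows(
    raw_row(200, 50, 350, 50, session = "D1"),
    raw_row(100, 100, 300, 50, session = "D2"),   # floored numerator
    raw_row(200, 50, 40, 50, session = "D3")      # invalid shaft
  )
  q <- quantify_intensities(tbl)
  expect_equal(q$sglua1[1], 0.5)
  expect_true(all(is.na(q$sglua1[2:3])))
  expect_equal(q$flag_sglua1, c("ok", "floored", "invalid_shaft"))
})

test_that("trace normalization modes satisfy their reference invariants", {
  sess <- schedule_sessions("baseline10")
  # constant trace -> all ones under any mode
  const <- trace_tbl(rep(2.5, 5))
  for (mode in c("to_day1", "to_baseline_mean")) {
    out <- normalize_trace(const, mode, sess, values = "sglua1")
    expect_equal(out$sglua1, rep(1, 5))
  }
  # (2, 3, 4) to_day1 -> (1, 1.5, 2)
  out <- normalize_trace(trace_tbl(c(2, 3, 4)), "to_day1", sess,
                         values = "sglua1")
  expect_equal(out$sglua1, c(1, 1.5, 2))
  # deprivation baseline-mean: BL (1,1,1), VD1 0.8 -> VD1 = 0.8
  dsess <- schedule_sessions("deprivation")
  out <- normalize_trace(trace_tbl(c(1, 1, 1, 0.8), "deprivation"),
                         "to_baseline_mean", dsess, values = "sglua1")
  expect_equal(out$sglua1[out$session == "VD1"], 0.8)
  # baseline mean is 1 per spine by construction
  expect_equal(mean(out$sglua1[out$phase == "baseline"]), 1)
})

test_that("ratio normalizations commute: baseline-mean of a day1-normalized trace", {
  sess <- schedule_sessions("deprivation")
  set.seed(7)
  tbl <- trace_tbl(runif(7, 0.5, 2), "deprivation")
  direct <- normalize_trace(tbl, "to_baseline_mean", sess, values = "sglua1")
  via_day1 <- normalize_trace(
    normalize_trace(tbl, "to_day1", sess, values = "sglua1") |>
      dplyr::select("spine_id", "dendrite_id", "session", "sglua1"),
    "to_baseline_mean", sess, values = "sglua1"
  )
  expect_equal(via_day1$sglua1, direct$sglua1)
})

test_that("missing reference sessions exclude the spine rather than imputing", {
  sess <- schedule_sessions("deprivation")
  tbl <- trace_tbl(c(NA, 1, 1, 0.8), "deprivation")
  out <- normalize_trace(tbl, "to_baseline_mean", sess, values = "sglua1")
  expect_true(all(is.na(out$sglua1)))
})

test_that("relative-to-dendrite-mean levels average to one", {
  tbl <- tibble::tibble(
    spine_id = c("a", "b"), dendrite_id = "d1", session = "D1",
    sglua1 = c(2, 4)
  )
  out <- relative_to_dendrite_mean(tbl, values = "sglua1")
  expect_equal(out$sglua1, c(2 / 3, 4 / 3))
  # singleton and identical values
  one <- relative_to_dendrite_mean(
    tibble::tibble(spine_id = "a", dendrite_id = "d", session = "D1", sglua1 = 5),
    values = "sglua1"
  )
  expect_equal(one$sglua1, 1)
  expect_error(
    relative_to_dendrite_mean(
      tibble::tibble(spine_id = "a", dendrite_id = "d", session = "D1",
                     sglua1 = NA_real_),
      values = "sglua1"
    ),
    "no valid spine"
  )
})

test_that("daily change divides by the previous day and skips gaps", {
  sess <- schedule_sessions("baseline10")
  out <- daily_change(trace_tbl(c(1, 2, 1)), sess, values = "sglua1")
  expect_equal(out$sglua1, c(2, 0.5))
  expect_equal(out$session, c("D2", "D3"))
  # constant trace -> all ones
  expect_equal(daily_change(trace_tbl(rep(3, 4)), sess, values = "sglua1")$sglua1,
               rep(1, 3))
  # gap: (1, missing, 3) -> no transitions
  gap <- trace_tbl(c(1, NA, 3))
  expect_equal(nrow(daily_change(gap, sess, values = "sglua1")), 0L)
})

test_that("dendrite summaries are geometric means over valid spines", {
  sess <- schedule_sessions("baseline10")[1, ]
  tbl <- tibble::tibble(
    spine_id = c("a", "b"), dendrite_id = "d1", session = "D1",
    present = TRUE, sglua1 = c(2, 0.5)
  )
  expect_equal(dendrite_summary(tbl, sess, values = "sglua1")$sglua1, 1)
  tbl$sglua1 <- c(1, 4)
  expect_equal(dendrite_summary(tbl, sess, values = "sglua1")$sglua1, 2)
  one <- tbl[1, ]; one$sglua1 <- 3
  expect_equal(dendrite_summary(one, sess, values = "sglua1")$sglua1, 3)
})

test_that("dendrite summary of relative values equals geometric mean of them", {
  set.seed(3)
  tbl <- tibble::tibble(
    spine_id = paste0("s", 1:8), dendrite_id = "d1", session = "D1",
    present = TRUE, sglua1 = rlnorm(8)
  )
  rel <- relative_to_dendrite_mean(tbl, values = "sglua1")
  sess <- schedule_sessions("baseline10")[1, ]
  expect_equal(dendrite_summary(rel, sess, values = "sglua1")$sglua1,
               geom_mean(rel$sglua1))
})
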