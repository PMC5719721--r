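test_that("registration interpolates piecewise-linearly between landmarks", {
  st <- make_test_study(length_mm = 50)
  st$landmark_pairs <- data.frame(baseline_frame_index = c(0L, 100L),
                                  follow_up_frame_index = c(0L, 100L))
  map <- build_registration(st)
  expect_equal(map$map(25), 25)  # identity

  # 10% uniform stretch: baseline 50 -> follow-up 55 given pairs (0,0),(100,110)
  st2 <- make_test_study(length_mm = 50, stretch = 1.1)
  st2$landmark_pairs <- data.frame(baseline_frame_index = c(0L, 100L),
                                   follow_up_frame_index = c(0L, 110L))
  map2 <- build_registration(st2)
  expect_equal(map2$map(50), 55)

  # three pairs at positions (0,0),(40,50),(100,110): baseline 70 maps to
  # 50 + 30 * (60/60) = 80
  st3 <- make_test_study(length_mm = 100, stretch = 1.1)
  st3$landmark_pairs <- data.frame(baseline_frame_index = c(0L, 80L, 200L),
                                   follow_up_frame_index = c(0L, 100L, 220L))
  map3 <- build_registration(st3)
  expect_equal(map3$map(70), 80)
  expect_equal(map3$map(20), 25)
})

test_that("non-monotone landmark pairs are rejected with the offending pair", {
  st <- make_test_study(length_mm = 30)
  st$landmark_pairs <- data.frame(baseline_frame_index = c(0L, 30L, 60L),
                                  follow_up_frame_index = c(0L, 40L, 35L))
  expect_error(build_registration(st), "non-monotone")
})

test_that("registration is exact at every landmark on random monotone sets", {
  set.seed(21)
  st <- make_test_study(length_mm = 60)
  n_fr <- nrow(st$baseline$frames)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    bl <- sort(sample(0:(n_fr - 1), k))
    fu <- sort(sample(0:(n_fr - 1), k))
    while (any(duplicated(bl)) || any(duplicated(fu))) {
      bl <- sort(sample(0:(n_fr - 1), k)); fu <- sort(sample(0:(n_fr - 1), k))
    }
    st$landmark_pairs <- data.frame(baseline_frame_index = bl,
                                    follow_up_frame_index = fu)
    map <- build_registration(st)
    expect_equal(map$map(bl * 0.5), fu * 0.5, tolerance = 1e-12)
  }
})

test_that("partitioning tiles the analyzed length into disjoint 5-mm windows", {
  st <- make_test_study(length_mm = 32)  # 6 full segments, 2 mm tail dropped
  seg <- partition_segments(st)
  expect_equal(nrow(seg), 6)
  expect_equal(seg$bl_end_mm - seg$bl_start_mm, rep(5, 6))
  expect_equal(seg$bl_start_mm[-1], seg$bl_end_mm[-6])
  expect_equal(sum(seg$n_frames_bl), 6 * 10)  # no frame in two windows
  # identity registration and uniform spacing: equal frame counts
  expect_equal(seg$n_frames_bl, seg$n_frames_fu)
})

test_that("70.5 mm of registered vessel yields 14 segment pairs", {
  st <- make_test_study(length_mm = 70.5)
  expect_equal(nrow(partition_segments(st)), 14)
})

test_that("patients below the registered-overlap minimum are excluded with a reason", {
  st <- make_test_study(length_mm = 4.5)
  err <- tryCatch(partition_segments(st), vh_exclusion = function(e) e)
  expect_s3_class(err, "vh_exclusion")
  expect_match(err$reason, "insufficient overlap")
  # one segment would fit, but the 25 mm inclusion minimum still applies
  st2 <- make_test_study(length_mm = 20)
  err2 <- tryCatch(partition_segments(st2), vh_exclusion = function(e) e)
  expect_match(err2$reason, "25 mm")
  expect_equal(nrow(partition_segments(
    st2, cfg = analysis_config(min_overlap_mm = 10))), 4)
})

test_that("deltas equal recomputed follow-up minus baseline differences", {
  st <- make_test_study(length_mm = 30, fu_lumen = 7.5, fu_eem = 16.5)
  seg <- partition_segments(st)
  expect_equal(seg$delta_mean_plaque_csa_mm2,
               seg$mean_plaque_csa_mm2_fu - seg$mean_plaque_csa_mm2_bl)
  expect_equal(seg$delta_pav_pct, seg$pav_pct_fu - seg$pav_pct_bl)
  expect_equal(unique(seg$delta_mean_lumen_csa_mm2), -0.5)
  expect_equal(unique(seg$delta_mean_eem_csa_mm2), 0.5)
})

test_that("the pipeline is deterministic: identical inputs, identical tables", {
  st <- make_test_study(length_mm = 40, stretch = 1.08)
  a <- partition_segments(st)
  b <- partition_segments(st)
  attr(a, "frames") <- attr(b, "frames") <- NULL
  expect_identical(a, b)
})
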