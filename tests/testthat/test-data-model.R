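test_that("a well-formed frame table reads into a validated pullback", {
  f <- make_frames(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(f, path, row.names = FALSE)
  pb <- read_frame_table(path, "baseline")
  expect_s3_class(pb, "vh_pullback")
  expect_equal(nrow(pb$frames), 3)
  expect_true(all(diff(pb$frames$axial_position_mm) > 0))
  expect_equal(analyzed_length(pb), 1.0)
})

test_that("axial positions are synthesized from frame spacing when absent", {
  f <- make_frames(4)
  f$axial_position_mm <- NULL
  out <- validate_frames(f, analysis_config(frame_spacing_mm = 0.5))
  expect_equal(out$axial_position_mm, c(0, 0.5, 1, 1.5))
})

test_that("every frame invariant has a rejecting case naming the rule", {
  ok <- make_frames(3)
  bad <- ok; bad$lumen_csa_mm2[2] <- 9; bad$eem_csa_mm2[2] <- 8
  expect_error(validate_frames(bad), "lumen")
  bad <- ok; bad$nc_area_mm2[1] <- 0; bad$nc_lumen_arc_deg[1] <- 45
  expect_error(validate_frames(bad), "arc")
  bad <- ok; bad$f_area_mm2[3] <- -1
  expect_error(validate_frames(bad), "negative component")
  bad <- ok; bad$f_area_mm2[1] <- 100
  expect_error(validate_frames(bad), "tolerance")
  bad <- ok; bad$axial_position_mm[2] <- 0
  expect_error(validate_frames(bad), "increasing")
  bad <- ok; bad$nc_lumen_arc_deg[1] <- 400
  expect_error(validate_frames(bad), "360")
})

test_that("schema errors name the missing column", {
  f <- make_frames(3)
  f$eem_csa_mm2 <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(f, path, row.names = FALSE)
  expect_error(read_frame_table(path, "baseline"), "eem_csa_mm2")
})

test_that("pullback construction enforces landmark sanity", {
  f <- make_frames(5)
  expect_error(pullback(f, 4L, 0L, "baseline"), "distal")
  expect_error(pullback(f, 0L, 99L, "baseline"), "valid frame")
  expect_error(pullback(f[1, ], 0L, 0L, "baseline"), "2 frames")
})

test_that("landmark pairs must be monotone and at least two", {
  f10 <- make_frames(10)
  pb <- function(tp) pullback(f10, 0L, 9L, tp)
  mk <- function(lp) patient_study("P", "DM", pb("baseline"), pb("follow_up"), lp)
  expect_error(mk(data.frame(baseline_frame_index = 0,
                             follow_up_frame_index = 0)), "at least 2")
  expect_error(mk(data.frame(baseline_frame_index = c(0, 5),
                             follow_up_frame_index = c(5, 5))), "monotone")
  expect_s3_class(mk(data.frame(baseline_frame_index = c(0, 9),
                                follow_up_frame_index = c(0, 9))),
                  "vh_patient_study")
})

test_that("frame tables round-trip through CSV on randomized instances", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(3:30, 1)
    lumen <- runif(n, 4, 9); eem <- runif(n, 10, 20)
    plaque <- eem - lumen
    f <- make_frames(n, lumen = lumen, eem = eem,
                     f = plaque * runif(n, 0.2, 0.5),
                     ff = plaque * runif(n, 0, 0.15),
                     nc = plaque * runif(n, 0.05, 0.2),
                     dc = plaque * runif(n, 0, 0.1),
                     arc = runif(n, 0, 300))
    path <- withr::local_tempfile(fileext = ".csv")
    write.csv(f, path, row.names = FALSE)
    back <- read_frame_table(path, "baseline")$frames
    expect_equal(back, validate_frames(f), tolerance = 1e-9)
  }
})

test_that("write_results emits one CSV per family plus a reconciling manifest", {
  out <- withr::local_tempdir()
  seg <- data.frame(segment_index = seq_len(698), pav_pct = runif(698))
  man <- write_results(list(per_segment = seg,
                            per_patient = data.frame(patient_id = character(0))),
                       out, seed = 7)
  expect_equal(man$counts$per_segment, 698)
  expect_equal(man$counts$per_patient, 0)
  expect_true(file.exists(file.path(out, "manifest.json")))
  back <- read.csv(file.path(out, "per_segment.csv"))
  expect_equal(back$segment_index, seg$segment_index)
  expect_equal(back$pav_pct, seg$pav_pct, tolerance = 1e-9)
  empty <- read.csv(file.path(out, "per_patient.csv"))
  expect_equal(nrow(empty), 0)
})

test_that("analysis config round-trips losslessly through YAML", {
  cfg <- analysis_config(segment_length_mm = 4,
                         laps_coeffs = list(intercept = -1.5, nc_dc = 0.7,
                                            mla = -3.39, remodeling = 5,
                                            tcfa = 3),
                         laps_frame_mla = "segment")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  expect_identical(read_config(path), cfg)
  expect_error(analysis_config(segment_length_mm = -1), "positive")
  expect_error(analysis_config(segment_length_mm = 0.4), "exceed")
})
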