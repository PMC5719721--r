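test_that("the classification cascade assigns each phenotype region", {
  lab <- function(...) as.character(classify_frames(make_morph(...)))
  expect_equal(lab(burden_pct = 35, nc_pct = 20, arc = 90), "NL")
  expect_equal(lab(burden_pct = 50, nc_pct = 12, arc = 40), "TCFA")
  expect_equal(lab(burden_pct = 50, nc_pct = 12, arc = 10), "ThCFA")
  expect_equal(lab(burden_pct = 45, nc_pct = 5, dc_pct = 15), "FcP")
  expect_equal(lab(burden_pct = 45, nc_pct = 5, dc_pct = 5, ff_pct = 20), "PIT")
  expect_equal(lab(burden_pct = 45, nc_pct = 5, dc_pct = 5, ff_pct = 10), "FP")
  # the NL cutoff is exclusive: a burden of exactly 40% is a lesion
  expect_equal(lab(burden_pct = 40, nc_pct = 5, ff_pct = 20), "PIT")
  # the arc contact threshold is inclusive
  expect_equal(lab(burden_pct = 50, nc_pct = 12, arc = 30), "TCFA")
})

test_that("cascade thresholds come from the configuration", {
  cfg <- analysis_config(nc_arc_contact_deg = 1)
  m <- make_morph(burden_pct = 50, nc_pct = 12, arc = 5)
  expect_equal(as.character(classify_frames(m, cfg)), "TCFA")
  expect_equal(as.character(classify_frames(m)), "ThCFA")
})

test_that("severity is monotone in NC share at fixed burden and contact", {
  set.seed(3)
  for (rep in 1:20) {
    arc <- sample(c(0, 45), 1)
    dc <- runif(1, 0, 20); ff <- runif(1, 0, 25)
    ncs <- sort(runif(2, 0, 40))
    r1 <- severity_rank(classify_frames(
      make_morph(50, nc_pct = ncs[1], dc_pct = dc, ff_pct = ff, arc = arc)))
    r2 <- severity_rank(classify_frames(
      make_morph(50, nc_pct = ncs[2], dc_pct = dc, ff_pct = ff, arc = arc)))
    expect_gte(r2, r1)
  }
})

test_that("TCFA candidates need a confirmed run of three consecutive frames", {
  run <- function(x) as.character(confirm_tcfa_runs(
    factor(x, levels = phenotype_levels, ordered = TRUE)))
  expect_equal(run(c("TCFA", "TCFA", "TCFA")), rep("TCFA", 3))
  expect_equal(run(c("TCFA", "TCFA")), rep("ThCFA", 2))
  expect_equal(run(c("TCFA", "TCFA", "FP", "TCFA", "TCFA", "TCFA")),
               c("ThCFA", "ThCFA", "FP", "TCFA", "TCFA", "TCFA"))
  expect_equal(run(character(0)), character(0))
  # run length requirement is configurable
  cfg2 <- analysis_config(tcfa_min_run_frames = 2)
  expect_equal(as.character(confirm_tcfa_runs(
    factor(c("TCFA", "TCFA"), levels = phenotype_levels, ordered = TRUE),
    cfg2)), c("TCFA", "TCFA"))
})

test_that("run confirmation is idempotent and never adds TCFA frames", {
  set.seed(11)
  for (rep in 1:20) {
    raw <- factor(sample(phenotype_levels, 30, replace = TRUE,
                         prob = c(1, 1, 1, 1, 1, 3)),
                  levels = phenotype_levels, ordered = TRUE)
    conf <- confirm_tcfa_runs(raw)
    expect_identical(confirm_tcfa_runs(conf), conf)
    expect_lte(sum(conf == "TCFA"), sum(raw == "TCFA"))
    # non-candidate labels pass through unchanged
    expect_identical(raw[raw != "TCFA"], conf[raw != "TCFA"])
  }
})

test_that("segments are labeled by their most advanced frame, straddle forces TCFA", {
  as_ph <- function(x) factor(x, levels = phenotype_levels, ordered = TRUE)
  expect_equal(as.character(label_segment(as_ph(c("PIT", "FP", "ThCFA")))),
               "ThCFA")
  expect_equal(as.character(label_segment(as_ph(c("NL", "NL")))), "NL")
  expect_equal(as.character(label_segment(as_ph(c("PIT", "PIT")),
                                          straddle_tcfa = TRUE)), "TCFA")
  expect_error(label_segment(as_ph(character(0))), "empty")
})

test_that("a confirmed run straddling two segments labels both TCFA", {
  # 60 frames; a 4-frame confirmed run spans positions 4.0-5.5 mm, i.e. the
  # boundary between the first and second 5-mm windows
  f <- make_frames(61, lumen = 8, eem = 16, nc = 0.9, dc = 0.3, arc = 0)
  f$nc_lumen_arc_deg[9:12] <- 60
  st <- make_test_study(length_mm = 30)
  st$baseline$frames <- validate_frames(f)
  st$follow_up$frames <- validate_frames(f)
  seg <- partition_segments(st)
  expect_equal(seg$phenotype_bl[1:2], c("TCFA", "TCFA"))
  expect_true(seg$straddle_tcfa_bl[1] || seg$straddle_tcfa_bl[2])
  # remaining windows have no contact: thick-cap fibroatheroma
  expect_true(all(seg$phenotype_bl[-(1:2)] == "ThCFA"))
})
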