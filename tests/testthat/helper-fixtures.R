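# frame-table builders used across the suite; all values in schema units
# (areas mm^2, arcs degrees, positions mm)

make_frames <- function(n = 10, spacing = 0.5, eem = 16, lumen = 8,
                        f = 2, ff = 0.5, nc = 0.8, dc = 0.4, arc = 0,
                        start_index = 0) {
  rep_n <- function(x) rep_len(x, n)
  data.frame(
    frame_index = start_index + seq_len(n) - 1L,
    axial_position_mm = (start_index + seq_len(n) - 1L) * spacing,
    lumen_csa_mm2 = rep_n(lumen), eem_csa_mm2 = rep_n(eem),
    f_area_mm2 = rep_n(f), ff_area_mm2 = rep_n(ff),
    nc_area_mm2 = rep_n(nc), dc_area_mm2 = rep_n(dc),
    nc_lumen_arc_deg = rep_n(arc)
  )
}

# one-row morphometry input with a chosen composition, burden in percent
make_morph <- function(burden_pct = 50, nc_pct = 5, dc_pct = 5, ff_pct = 10,
                       arc = 0, eem = 16) {
  plaque <- eem * burden_pct / 100
  total <- 0.9 * plaque
  f_pct <- 100 - nc_pct - dc_pct - ff_pct
  fr <- data.frame(
    frame_index = 0L, axial_position_mm = 0,
    lumen_csa_mm2 = eem - plaque, eem_csa_mm2 = eem,
    f_area_mm2 = f_pct / 100 * total, ff_area_mm2 = ff_pct / 100 * total,
    nc_area_mm2 = nc_pct / 100 * total, dc_area_mm2 = dc_pct / 100 * total,
    nc_lumen_arc_deg = arc
  )
  frame_morphometry(fr)
}

# a simple two-timepoint study: uniform frames, identity or linear stretch
make_test_study <- function(length_mm = 30, stretch = 1, group = "DM",
                            patient_id = "P1", lumen = 8, eem = 16,
                            fu_lumen = lumen, fu_eem = eem) {
  n_bl <- length_mm / 0.5 + 1
  bl <- make_frames(n_bl, lumen = lumen, eem = eem)
  fu_len <- length_mm * stretch
  n_fu <- floor(fu_len / 0.5) + 1
  fu <- make_frames(n_fu, lumen = fu_lumen, eem = fu_eem)
  patient_study(
    patient_id = patient_id, group = group,
    baseline = pullback(bl, 0L, n_bl - 1L, "baseline", patient_id),
    follow_up = pullback(fu, 0L, n_fu - 1L, "follow_up", patient_id),
    landmark_pairs = data.frame(
      baseline_frame_index = c(0L, n_bl - 1L),
      follow_up_frame_index = c(0L, n_fu - 1L))
  )
}

# canonical full-size synthetic cohort (default generator seed), built once
# per test run and shared by the generator, pipeline and acceptance tests
.canonical <- new.env(parent = emptyenv())

canonical_cohort <- function() {
  if (is.null(.canonical$cohort)) {
    .canonical$cohort <- generate_cohort(generator_config())
  }
  .canonical$cohort
}

canonical_analysis <- function() {
  if (is.null(.canonical$analysis)) {
    .canonical$analysis <- suppressMessages(
      analyze_cohort(canonical_cohort()))
  }
  .canonical$analysis
}
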