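#' Build a baseline-to-follow-up registration map
#'
#' Converts the study's landmark frame pairs to axial positions and returns a
#' piecewise-linear map from baseline axial position to follow-up axial
#' position. The map is exact at every landmark pair, monotone increasing,
#' and clamped outside the outermost pair (those regions are excluded from
#' analysis downstream).
#'
#' @param study A [patient_study()].
#' @return An object of class `vh_registration` with fields `bl_pos`,
#'   `fu_pos` (landmark positions) and `$map(pos)` / `$inverse(pos)`
#'   interpolators.
#' @export
build_registration <- function(study) {
  lp <- study$landmark_pairs
  bl_pos <- frame_position(study$baseline, lp$baseline_frame_index)
  fu_pos <- frame_position(study$follow_up, lp$follow_up_frame_index)
  if (any(is.na(bl_pos)) || any(is.na(fu_pos))) {
    stop("registration error: landmark frame not present in pullback",
         call. = FALSE)
  }
  if (any(diff(bl_pos) <= 0) || any(diff(fu_pos) <= 0)) {
    k <- which(diff(bl_pos) <= 0 | diff(fu_pos) <= 0)[1]
    stop(sprintf(
      "registration error: non-monotone landmark pair (%d, %d) -> (%d, %d)",
      lp$baseline_frame_index[k], lp$follow_up_frame_index[k],
      lp$baseline_frame_index[k + 1], lp$follow_up_frame_index[k + 1]),
      call. = FALSE)
  }
  x <- list(
    landmark_pairs = lp, bl_pos = bl_pos, fu_pos = fu_pos,
    map = function(p) approx(bl_pos, fu_pos, xout = p, rule = 2)$y,
    inverse = function(p) approx(fu_pos, bl_pos, xout = p, rule = 2)$y
  )
  class(x) <- "vh_registration"
  x
}

#' @export
print.vh_registration <- function(x, ...) {
  cat(sprintf("Registration map: %d landmark pairs, baseline span %.1f mm -> follow-up span %.1f mm\n",
              length(x$bl_pos), diff(range(x$bl_pos)), diff(range(x$fu_pos))))
  invisible(x)
}

vh_exclusion <- function(patient_id, reason) {
  structure(class = c("vh_exclusion", "error", "condition"),
            list(message = sprintf("patient '%s' excluded: %s",
                                   patient_id, reason),
                 call = NULL, patient_id = patient_id, reason = reason))
}

analysis_region <- function(study, map) {
  d0 <- max(frame_position(study$baseline, study$baseline$distal_landmark_frame),
            min(map$bl_pos))
  p0 <- min(frame_position(study$baseline, study$baseline$proximal_landmark_frame),
            max(map$bl_pos))
  # follow-up landmarks can further crop the registered region
  fu_lo <- frame_position(study$follow_up, study$follow_up$distal_landmark_frame)
  fu_hi <- frame_position(study$follow_up, study$follow_up$proximal_landmark_frame)
  d0 <- max(d0, map$inverse(fu_lo))
  p0 <- min(p0, map$inverse(fu_hi))
  c(d0, p0)
}

timepoint_segment <- function(frames, confirmed_all, runs, in_window,
                              cfg) {
  sf <- frames[in_window, , drop = FALSE]
  morph <- frame_morphometry(sf, cfg)
  seg <- segment_morphometry(sf, cfg)
  conf <- confirmed_all[in_window]
  idx <- which(in_window)
  straddle <- FALSE
  if (nrow(runs) > 0 && length(idx) > 0) {
    lo <- min(idx); hi <- max(idx)
    overlaps <- runs$start <= hi & runs$end >= lo
    extends <- runs$start < lo | runs$end > hi
    straddle <- any(overlaps & extends)
  }
  label <- label_segment(conf, straddle_tcfa = straddle)
  li <- laps_inputs_for_frame(morph, seg, conf, cfg)
  scores <- laps_frame(li$nc_dc_ratio, li$mla_mm2, li$remodeling_positive,
                       li$tcfa_indicator, cfg)
  list(seg = seg, label = as.character(label), straddle = straddle,
       laps = laps_segment(scores),
       frame_labels = as.character(conf), frame_laps = scores,
       frame_index = sf$frame_index)
}

#' Partition a registered study into paired 5-mm segments
#'
#' Lays consecutive `segment_length_mm` windows on baseline axial coordinates
#' starting at the distal end of the registered overlap; the residual
#' proximal tail shorter than one segment is dropped. Each baseline window is
#' mapped to its follow-up span through the registration map; morphometry,
#' confirmed phenotype (with the TCFA straddle rule) and LAPS are computed
#' per timepoint over each span's own frames, and follow-up − baseline deltas
#' are attached for every numeric index.
#'
#' Patients whose registered overlap is shorter than `min_overlap_mm`
#' (default 25 mm) raise a `vh_exclusion` condition carrying the reason.
#'
#' @param study A [patient_study()].
#' @param map A `vh_registration` from [build_registration()]; built from
#'   `study` when `NULL`.
#' @param cfg An [analysis_config()].
#' @return A data frame of class `vh_segment_pairs`, one row per segment
#'   pair, with per-timepoint columns suffixed `_bl` / `_fu` and `delta_*`
#'   columns. Per-frame detail is attached as attribute `"frames"`.
#' @export
partition_segments <- function(study, map = NULL, cfg = analysis_config()) {
  if (is.null(map)) map <- build_registration(study)
  region <- analysis_region(study, map)
  overlap <- region[2] - region[1]
  if (overlap < cfg$segment_length_mm) {
    stop(vh_exclusion(study$patient_id, sprintf(
      "insufficient overlap (%.1f mm < one %.0f mm segment)",
      overlap, cfg$segment_length_mm)))
  }
  if (overlap < cfg$min_overlap_mm) {
    stop(vh_exclusion(study$patient_id, sprintf(
      "registered overlap %.1f mm below the %.0f mm inclusion minimum",
      overlap, cfg$min_overlap_mm)))
  }
  n_seg <- floor(overlap / cfg$segment_length_mm + 1e-9)

  bl <- study$baseline$frames
  fu <- study$follow_up$frames
  raw_bl <- classify_frames(frame_morphometry(bl, cfg), cfg)
  raw_fu <- classify_frames(frame_morphometry(fu, cfg), cfg)
  conf_bl <- confirm_tcfa_runs(raw_bl, cfg)
  conf_fu <- confirm_tcfa_runs(raw_fu, cfg)
  runs_bl <- tcfa_runs(raw_bl, cfg)
  runs_fu <- tcfa_runs(raw_fu, cfg)

  rows <- vector("list", n_seg)
  frame_detail <- vector("list", n_seg)
  for (i in seq_len(n_seg)) {
    lo <- region[1] + (i - 1) * cfg$segment_length_mm
    hi <- lo + cfg$segment_length_mm
    in_bl <- bl$axial_position_mm >= lo - 1e-9 &
      bl$axial_position_mm < hi - 1e-9
    flo <- map$map(lo); fhi <- map$map(hi)
    in_fu <- fu$axial_position_mm >= flo - 1e-9 &
      fu$axial_position_mm < fhi - 1e-9
    if (sum(in_bl) < 3 || sum(in_fu) < 3) {
      stop(sprintf(
        "segment %d of patient '%s' has fewer than 3 frames at one timepoint",
        i, study$patient_id), call. = FALSE)
    }
    b <- timepoint_segment(bl, conf_bl, runs_bl, in_bl, cfg)
    f <- timepoint_segment(fu, conf_fu, runs_fu, in_fu, cfg)
    sb <- b$seg; sf <- f$seg
    num <- setdiff(names(sb), c("mla_frame_index", "n_frames"))
    row <- data.frame(segment_index = i - 1L,
                      bl_start_mm = lo, bl_end_mm = hi,
                      fu_start_mm = flo, fu_end_mm = fhi,
                      n_frames_bl = sb$n_frames, n_frames_fu = sf$n_frames)
    for (v in num) {
      row[[paste0(v, "_bl")]] <- sb[[v]]
      row[[paste0(v, "_fu")]] <- sf[[v]]
    }
    row$phenotype_bl <- b$label
    row$phenotype_fu <- f$label
    row$straddle_tcfa_bl <- b$straddle
    row$straddle_tcfa_fu <- f$straddle
    row$laps_bl <- b$laps
    row$laps_fu <- f$laps
    for (v in num) {
      row[[paste0("delta_", v)]] <- sf[[v]] - sb[[v]]
    }
    row$delta_laps <- f$laps - b$laps
    rows[[i]] <- row
    frame_detail[[i]] <- list(baseline = b, follow_up = f)
  }
  out <- do.call(rbind, rows)
  attr(out, "frames") <- frame_detail
  attr(out, "patient_id") <- study$patient_id
  attr(out, "group") <- study$group
  class(out) <- c("vh_segment_pairs", "data.frame")
  out
}
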