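#' Per-frame morphometry
#'
#' Computes, for each frame, the plaque cross-sectional area
#' (EEM CSA − lumen CSA), the plaque burden (plaque / EEM, in \[0, 1\]) and
#' the tissue composition both as absolute areas and as fractions of
#' characterized tissue (component / (F + FF + NC + DC)). When no tissue is
#' characterized the four fractions are all 0 by convention.
#'
#' Composition fractions are taken relative to characterized tissue rather
#' than to plaque CSA because VH leaves media and unclassified pixels
#' uncounted.
#'
#' @param frames A validated frame table (or anything [validate_frames()]
#'   accepts), possibly a single row.
#' @param cfg An [analysis_config()].
#' @return A data frame with one row per frame: `frame_index`,
#'   `axial_position_mm`, `lumen_csa_mm2`, `eem_csa_mm2`, `plaque_csa_mm2`,
#'   `plaque_burden_frac`, `f_frac`, `ff_frac`, `nc_frac`, `dc_frac`, the four
#'   absolute areas and `nc_lumen_arc_deg`.
#' @export
#' @examples
#' f <- data.frame(frame_index = 0, axial_position_mm = 0,
#'                 lumen_csa_mm2 = 8.53, eem_csa_mm2 = 15.79,
#'                 f_area_mm2 = 1.8, ff_area_mm2 = 0.4, nc_area_mm2 = 0.8,
#'                 dc_area_mm2 = 0.4, nc_lumen_arc_deg = 60)
#' frame_morphometry(f)$plaque_csa_mm2  # 7.26
frame_morphometry <- function(frames, cfg = analysis_config()) {
  frames <- validate_frames(frames, cfg)
  if (any(frames$eem_csa_mm2 <= 0)) {
    stop("degenerate frame: EEM CSA must be > 0 for morphometry",
         call. = FALSE)
  }
  plaque <- frames$eem_csa_mm2 - frames$lumen_csa_mm2
  total <- frames$f_area_mm2 + frames$ff_area_mm2 + frames$nc_area_mm2 +
    frames$dc_area_mm2
  safe_frac <- function(x) ifelse(total > 0, x / total, 0)
  data.frame(
    frame_index = frames$frame_index,
    axial_position_mm = frames$axial_position_mm,
    lumen_csa_mm2 = frames$lumen_csa_mm2,
    eem_csa_mm2 = frames$eem_csa_mm2,
    plaque_csa_mm2 = plaque,
    plaque_burden_frac = plaque / frames$eem_csa_mm2,
    f_frac = safe_frac(frames$f_area_mm2),
    ff_frac = safe_frac(frames$ff_area_mm2),
    nc_frac = safe_frac(frames$nc_area_mm2),
    dc_frac = safe_frac(frames$dc_area_mm2),
    f_area_mm2 = frames$f_area_mm2,
    ff_area_mm2 = frames$ff_area_mm2,
    nc_area_mm2 = frames$nc_area_mm2,
    dc_area_mm2 = frames$dc_area_mm2,
    nc_lumen_arc_deg = frames$nc_lumen_arc_deg
  )
}

#' Percent atheroma volume
#'
#' `PAV = 100 * sum(EEM_area - Lumen_area) / sum(EEM_area)` over the supplied
#' frames.
#'
#' @param frames A frame table with at least `lumen_csa_mm2` and
#'   `eem_csa_mm2`; all EEM CSAs must be positive.
#' @return Percent in \[0, 100\].
#' @export
#' @examples
#' f <- data.frame(frame_index = 0:1, axial_position_mm = c(0, 0.5),
#'                 lumen_csa_mm2 = c(6, 12), eem_csa_mm2 = c(10, 20),
#'                 f_area_mm2 = 0, ff_area_mm2 = 0, nc_area_mm2 = 0,
#'                 dc_area_mm2 = 0, nc_lumen_arc_deg = 0)
#' pav(f)  # 40
pav <- function(frames) {
  frames <- as.data.frame(frames)
  if (nrow(frames) == 0) stop("pav() needs at least one frame", call. = FALSE)
  if (any(frames$eem_csa_mm2 <= 0)) {
    stop("pav() requires all EEM CSAs > 0", call. = FALSE)
  }
  100 * sum(frames$eem_csa_mm2 - frames$lumen_csa_mm2) /
    sum(frames$eem_csa_mm2)
}

#' Remodeling index of a segment
#'
#' Ratio of the EEM CSA at the segment's minimal-lumen-area (MLA) frame to
#' the mean EEM CSA of the segment's two boundary frames (first and last
#' frame of the segment). When the segment abuts a pullback end the single
#' available boundary frame is used. This follows the standard lesion
#' remodeling index, with the segment boundaries serving as the nearest
#' available reference sites; the definition is isolated here so alternative
#' references are drop-in.
#'
#' @param segment_frames Frame table of the segment (>= 3 frames, in pullback
#'   order).
#' @param mla_frame_index `frame_index` of the MLA frame.
#' @param boundary Which boundary frames are available: `"both"`, or
#'   `"distal"` / `"proximal"` when the segment abuts a pullback end.
#' @return Positive ratio.
#' @export
remodeling_index <- function(segment_frames, mla_frame_index,
                             boundary = c("both", "distal", "proximal")) {
  boundary <- match.arg(boundary)
  sf <- as.data.frame(segment_frames)
  if (nrow(sf) < 3) {
    stop("remodeling_index() needs >= 3 frames; merge the segment with its neighbor",
         call. = FALSE)
  }
  sf <- sf[order(sf$frame_index), ]
  i <- match(mla_frame_index, sf$frame_index)
  if (is.na(i)) stop("mla_frame_index not in segment", call. = FALSE)
  ref <- switch(boundary,
                both = mean(c(sf$eem_csa_mm2[1], sf$eem_csa_mm2[nrow(sf)])),
                distal = sf$eem_csa_mm2[1],
                proximal = sf$eem_csa_mm2[nrow(sf)])
  sf$eem_csa_mm2[i] / ref
}

#' Segment morphometry
#'
#' Aggregates a segment's frames into the indices reported per 5-mm vessel
#' segment: unweighted frame means of lumen, EEM and plaque CSA and of the
#' tissue composition (mm^2 and fractions of characterized tissue), the
#' minimal lumen area (MLA; ties broken toward the most distal frame), PAV
#' over the segment's frames, and the remodeling index.
#'
#' @param segment_frames Frame table of the segment (>= 3 frames).
#' @param cfg An [analysis_config()].
#' @param boundary Passed to [remodeling_index()].
#' @return One-row data frame: `n_frames`, `mean_lumen_csa_mm2`,
#'   `mean_eem_csa_mm2`, `mean_plaque_csa_mm2`, `pav_pct`, `mla_mm2`,
#'   `mla_frame_index`, `remodeling_index`, mean composition areas/fractions
#'   and `mean_nc_lumen_arc_deg`.
#' @export
segment_morphometry <- function(segment_frames, cfg = analysis_config(),
                                boundary = "both") {
  m <- frame_morphometry(segment_frames, cfg)
  if (nrow(m) < 3) {
    stop("segment_morphometry() needs >= 3 frames", call. = FALSE)
  }
  m <- m[order(m$frame_index), ]
  mla_i <- which.min(m$lumen_csa_mm2)  # which.min takes the first = most distal
  data.frame(
    n_frames = nrow(m),
    mean_lumen_csa_mm2 = mean(m$lumen_csa_mm2),
    mean_eem_csa_mm2 = mean(m$eem_csa_mm2),
    mean_plaque_csa_mm2 = mean(m$plaque_csa_mm2),
    pav_pct = pav(m),
    mla_mm2 = m$lumen_csa_mm2[mla_i],
    mla_frame_index = m$frame_index[mla_i],
    remodeling_index = remodeling_index(m, m$frame_index[mla_i],
                                        boundary = boundary),
    mean_f_frac = mean(m$f_frac),
    mean_ff_frac = mean(m$ff_frac),
    mean_nc_frac = mean(m$nc_frac),
    mean_dc_frac = mean(m$dc_frac),
    mean_f_area_mm2 = mean(m$f_area_mm2),
    mean_ff_area_mm2 = mean(m$ff_area_mm2),
    mean_nc_area_mm2 = mean(m$nc_area_mm2),
    mean_dc_area_mm2 = mean(m$dc_area_mm2),
    mean_nc_lumen_arc_deg = mean(m$nc_lumen_arc_deg)
  )
}
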