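#' Liverpool Active Plaque Score of a frame
#'
#' `LAPS = intercept + nc_dc * (NC/DC) + mla * MLA + remodeling * [RI > cutoff]
#' + tcfa * [VH-TCFA]`, with default coefficients
#' `-2.149 + 0.68 * NC/DC + 3.39 * MLA + 5.1 + 3.7` for the respective terms.
#' All inputs are vectorized; arithmetic is exact (no rounding).
#'
#' The MLA coefficient is applied exactly as configured (positive by
#' default); users needing the opposite sign convention can override
#' `laps_coeffs$mla`.
#'
#' @param nc_dc_ratio NC/DC ratio (dimensionless, >= 0, already capped — see
#'   [laps_inputs_for_frame()]).
#' @param mla_mm2 Lumen CSA entering the MLA term (mm^2).
#' @param remodeling_positive Logical: remodeling index above the configured
#'   cutoff.
#' @param tcfa_indicator 0/1: confirmed VH-TCFA.
#' @param cfg An [analysis_config()] supplying `laps_coeffs`.
#' @return Numeric score(s).
#' @export
#' @examples
#' laps_frame(0, 0, FALSE, 0)               # -2.149 (intercept only)
#' laps_frame(1, 1, TRUE, 1)                # 10.721
laps_frame <- function(nc_dc_ratio, mla_mm2, remodeling_positive,
                       tcfa_indicator, cfg = analysis_config()) {
  stopifnot(all(nc_dc_ratio >= 0), all(mla_mm2 >= 0),
            all(tcfa_indicator %in% c(0, 1)))
  co <- cfg$laps_coeffs
  co$intercept + co$nc_dc * nc_dc_ratio + co$mla * mla_mm2 +
    co$remodeling * as.numeric(remodeling_positive) +
    co$tcfa * as.numeric(tcfa_indicator)
}

#' Assemble LAPS inputs for the frames of a segment
#'
#' For each frame: the NC/DC ratio is NC area divided by `max(DC area,
#' dc_epsilon_mm2)` and capped at `nc_dc_ratio_cap` (a ratio is undefined at
#' DC = 0; the floor-and-cap keeps scores finite and monotone); a frame with
#' no NC has ratio 0 regardless of DC. The MLA term uses the frame's own
#' lumen CSA by default (`laps_frame_mla = "frame"`; LAPS is a frame-level
#' score, and the frame's lumen is its only frame-local lumen) or the
#' segment MLA when configured. The remodeling indicator comes from the
#' enclosing segment's remodeling index; the TCFA indicator is 1 iff the
#' frame's confirmed label is TCFA.
#'
#' @param morph Frame morphometry of the segment ([frame_morphometry()]).
#' @param seg Segment morphometry ([segment_morphometry()]) supplying the
#'   remodeling index and segment MLA.
#' @param confirmed Confirmed phenotype labels of the same frames.
#' @param cfg An [analysis_config()].
#' @return Data frame: `frame_index`, `nc_dc_ratio`, `mla_mm2`,
#'   `remodeling_positive`, `tcfa_indicator`.
#' @export
laps_inputs_for_frame <- function(morph, seg, confirmed,
                                  cfg = analysis_config()) {
  stopifnot(nrow(morph) == length(confirmed))
  ratio <- ifelse(morph$nc_area_mm2 == 0, 0,
                  pmin(morph$nc_area_mm2 /
                         pmax(morph$dc_area_mm2, cfg$dc_epsilon_mm2),
                       cfg$nc_dc_ratio_cap))
  mla <- if (cfg$laps_frame_mla == "frame") morph$lumen_csa_mm2 else
    rep(seg$mla_mm2, nrow(morph))
  data.frame(
    frame_index = morph$frame_index,
    nc_dc_ratio = ratio,
    mla_mm2 = mla,
    remodeling_positive = rep(seg$remodeling_index > cfg$ri_threshold,
                              nrow(morph)),
    tcfa_indicator = as.integer(as.character(confirmed) == "TCFA")
  )
}

#' Segment- and pullback-level LAPS
#'
#' The LAPS of a 5-mm vessel segment is the highest frame LAPS found in the
#' segment; the LAPS of a pullback (one examination) is the arithmetic mean
#' of its segment scores.
#'
#' @param frame_scores Numeric vector of frame LAPS values (>= 1).
#' @return `laps_segment()`: the maximum; `laps_pullback()`: the mean.
#' @export
laps_segment <- function(frame_scores) {
  if (length(frame_scores) == 0) stop("laps_segment() needs >= 1 score",
                                      call. = FALSE)
  max(frame_scores)
}

#' @rdname laps_segment
#' @param segment_scores Numeric vector of segment LAPS values (>= 1).
#' @export
laps_pullback <- function(segment_scores) {
  if (length(segment_scores) == 0) stop("laps_pullback() needs >= 1 score",
                                        call. = FALSE)
  mean(segment_scores)
}
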