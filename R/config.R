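#' Analysis configuration
#'
#' Collects every threshold and constant used by the pipeline: the segment
#' length, the plaque-burden lesion cutoff, the composition thresholds of the
#' phenotype cascade, the TCFA run-confirmation length, the remodeling-index
#' cutoff and the LAPS coefficients. All values can be overridden, serialized
#' to YAML with [write_config()] and read back with [read_config()].
#'
#' @param segment_length_mm Length of one analysis segment (mm). Default 5.
#' @param frame_spacing_mm Fallback inter-frame spacing (mm) used to
#'   synthesize axial positions when a frame table has none. Default 0.5
#'   (motorized pullback at 0.5 mm/s with ~1 Hz gated frames).
#' @param tcfa_min_run_frames Minimum number of consecutive TCFA-candidate
#'   frames required to confirm a TCFA. Default 3.
#' @param pb_lesion_threshold_pct Plaque-burden cutoff (percent) below which a
#'   frame is "no lesion" (NL). Default 40.
#' @param nc_confluent_threshold_pct Necrotic-core share of characterized
#'   tissue (percent) treated as confluent NC. Default 10.
#' @param dc_threshold_pct Dense-calcium share (percent) defining a
#'   fibro-calcified plaque. Default 10.
#' @param ff_threshold_pct Fibro-fatty share (percent) defining pathologic
#'   intimal thickening. Default 15.
#' @param nc_arc_contact_deg Minimum NC-lumen arc (degrees) counted as NC
#'   abutting the lumen. Default 30.
#' @param ri_threshold Remodeling-index cutoff for positive remodeling
#'   (the LAPS remodeling term applies when RI exceeds it). Default 1.05.
#' @param laps_coeffs Named list of LAPS coefficients: `intercept`, `nc_dc`,
#'   `mla`, `remodeling`, `tcfa`.
#' @param laps_frame_mla Either `"frame"` (the MLA term of a frame's LAPS uses
#'   that frame's own lumen CSA) or `"segment"` (all frames of a segment use
#'   the segment MLA).
#' @param dc_epsilon_mm2 Floor applied to the DC area in the NC/DC ratio so
#'   the ratio stays finite. Default 0.01.
#' @param nc_dc_ratio_cap Upper cap on the NC/DC ratio. Default 10.
#' @param composition_tolerance_frac Allowed excess of F+FF+NC+DC over plaque
#'   CSA, as a fraction of plaque CSA (VH leaves media/unclassified pixels
#'   uncounted, so the sum is usually below plaque CSA). Default 0.05.
#' @param min_overlap_mm Minimum registered baseline/follow-up overlap (mm)
#'   for a patient to be analyzed. Default 25.
#' @param length_weighted_means If `TRUE`, segment means weight frames by
#'   inter-frame distance instead of uniformly. Default `FALSE`.
#'
#' @return An object of class `vh_config` (a validated named list).
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$laps_coeffs$intercept
analysis_config <- function(segment_length_mm = 5,
                            frame_spacing_mm = 0.5,
                            tcfa_min_run_frames = 3,
                            pb_lesion_threshold_pct = 40,
                            nc_confluent_threshold_pct = 10,
                            dc_threshold_pct = 10,
                            ff_threshold_pct = 15,
                            nc_arc_contact_deg = 30,
                            ri_threshold = 1.05,
                            laps_coeffs = list(intercept = -2.149,
                                               nc_dc = 0.68,
                                               mla = 3.39,
                                               remodeling = 5.1,
                                               tcfa = 3.7),
                            laps_frame_mla = c("frame", "segment"),
                            dc_epsilon_mm2 = 0.01,
                            nc_dc_ratio_cap = 10,
                            composition_tolerance_frac = 0.05,
                            min_overlap_mm = 25,
                            length_weighted_means = FALSE) {
  laps_frame_mla <- match.arg(laps_frame_mla)
  cfg <- list(
    segment_length_mm = as.numeric(segment_length_mm),
    frame_spacing_mm = as.numeric(frame_spacing_mm),
    tcfa_min_run_frames = as.integer(tcfa_min_run_frames),
    pb_lesion_threshold_pct = as.numeric(pb_lesion_threshold_pct),
    nc_confluent_threshold_pct = as.numeric(nc_confluent_threshold_pct),
    dc_threshold_pct = as.numeric(dc_threshold_pct),
    ff_threshold_pct = as.numeric(ff_threshold_pct),
    nc_arc_contact_deg = as.numeric(nc_arc_contact_deg),
    ri_threshold = as.numeric(ri_threshold),
    laps_coeffs = lapply(laps_coeffs, as.numeric),
    laps_frame_mla = laps_frame_mla,
    dc_epsilon_mm2 = as.numeric(dc_epsilon_mm2),
    nc_dc_ratio_cap = as.numeric(nc_dc_ratio_cap),
    composition_tolerance_frac = as.numeric(composition_tolerance_frac),
    min_overlap_mm = as.numeric(min_overlap_mm),
    length_weighted_means = isTRUE(length_weighted_means)
  )
  class(cfg) <- "vh_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "vh_config"))
  pos <- c("segment_length_mm", "frame_spacing_mm", "pb_lesion_threshold_pct",
           "nc_confluent_threshold_pct", "dc_threshold_pct",
           "ff_threshold_pct", "nc_arc_contact_deg", "ri_threshold",
           "dc_epsilon_mm2", "nc_dc_ratio_cap", "min_overlap_mm")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      stop("config field '", f, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (cfg$tcfa_min_run_frames < 1L) {
    stop("tcfa_min_run_frames must be >= 1", call. = FALSE)
  }
  if (cfg$segment_length_mm <= cfg$frame_spacing_mm) {
    stop("segment_length_mm must exceed frame_spacing_mm", call. = FALSE)
  }
  need <- c("intercept", "nc_dc", "mla", "remodeling", "tcfa")
  if (!all(need %in% names(cfg$laps_coeffs))) {
    stop("laps_coeffs must name: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (cfg$composition_tolerance_frac < 0) {
    stop("composition_tolerance_frac must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

#' Write / read an analysis configuration as YAML
#'
#' Serialization round-trips losslessly: `read_config(write_config(cfg, f))`
#' reproduces `cfg` exactly.
#'
#' @param cfg A `vh_config` object.
#' @param path File path for the YAML document.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `vh_config`.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  x <- unclass(cfg)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(analysis_config, x)
}

#' @export
print.vh_config <- function(x, ...) {
  cat("IVUS-VH analysis configuration\n")
  cat(sprintf("  segment length: %g mm, frame spacing fallback: %g mm\n",
              x$segment_length_mm, x$frame_spacing_mm))
  cat(sprintf("  phenotype thresholds: burden %g%%, NC %g%%, DC %g%%, FF %g%%, arc %g deg\n",
              x$pb_lesion_threshold_pct, x$nc_confluent_threshold_pct,
              x$dc_threshold_pct, x$ff_threshold_pct, x$nc_arc_contact_deg))
  cat(sprintf("  TCFA confirmation: %d consecutive frames\n",
              x$tcfa_min_run_frames))
  cat(sprintf("  LAPS: %g + %g x NC/DC + %g x MLA + %g [RI > %g] + %g x TCFA\n",
              x$laps_coeffs$intercept, x$laps_coeffs$nc_dc, x$laps_coeffs$mla,
              x$laps_coeffs$remodeling, x$ri_threshold, x$laps_coeffs$tcfa))
  invisible(x)
}
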