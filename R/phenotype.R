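#' Plaque phenotype levels
#'
#' The six phenotype categories in ascending order from least to most
#' advanced: no lesion (NL), pathologic intimal thickening (PIT), fibrous
#' plaque (FP), fibro-calcified plaque (FcP), thick-cap fibroatheroma
#' (ThCFA), thin-cap fibroatheroma (TCFA). The package represents labels as
#' ordered factors over these levels; `severity_rank()` maps them to 0..5.
#'
#' @format A character vector of length 6.
#' @export
phenotype_levels <- c("NL", "PIT", "FP", "FcP", "ThCFA", "TCFA")

#' @rdname phenotype_levels
#' @param label Character vector or factor of phenotype labels.
#' @return `severity_rank()`: integer vector, 0 (NL) .. 5 (TCFA).
#' @export
severity_rank <- function(label) {
  match(as.character(label), phenotype_levels) - 1L
}

as_phenotype <- function(label) {
  x <- as.character(label)
  bad <- setdiff(unique(x), phenotype_levels)
  if (length(bad)) stop("unknown phenotype label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  factor(x, levels = phenotype_levels, ordered = TRUE)
}

#' Classify frames into raw plaque phenotypes
#'
#' Frame-level decision cascade over the per-frame morphometry (composition
#' percentages are fractions of characterized tissue):
#'
#' 1. plaque burden < `pb_lesion_threshold_pct` → `NL`;
#' 2. NC% >= `nc_confluent_threshold_pct` and NC abutting the lumen
#'    (`nc_lumen_arc_deg >= nc_arc_contact_deg`) → `TCFA` (candidate);
#' 3. NC% >= `nc_confluent_threshold_pct` without lumen contact → `ThCFA`;
#' 4. DC% >= `dc_threshold_pct` → `FcP`;
#' 5. FF% >= `ff_threshold_pct` → `PIT`;
#' 6. otherwise → `FP`.
#'
#' The total NC fraction serves as the surrogate for NC confluence, which a
#' scalar area cannot resolve. A returned `TCFA` is a candidate only: it
#' still requires run confirmation by [confirm_tcfa_runs()].
#'
#' @param morph Output of [frame_morphometry()] (any number of rows).
#' @param cfg An [analysis_config()].
#' @return Ordered factor of raw labels, one per frame.
#' @export
classify_frames <- function(morph, cfg = analysis_config()) {
  burden_pct <- 100 * morph$plaque_burden_frac
  nc_pct <- 100 * morph$nc_frac
  dc_pct <- 100 * morph$dc_frac
  ff_pct <- 100 * morph$ff_frac
  contact <- morph$nc_lumen_arc_deg >= cfg$nc_arc_contact_deg
  lab <- ifelse(burden_pct < cfg$pb_lesion_threshold_pct, "NL",
         ifelse(nc_pct >= cfg$nc_confluent_threshold_pct & contact, "TCFA",
         ifelse(nc_pct >= cfg$nc_confluent_threshold_pct, "ThCFA",
         ifelse(dc_pct >= cfg$dc_threshold_pct, "FcP",
         ifelse(ff_pct >= cfg$ff_threshold_pct, "PIT", "FP")))))
  as_phenotype(lab)
}

#' Confirm TCFA candidates by run length
#'
#' A TCFA requires `tcfa_min_run_frames` (default 3) consecutive frames with
#' TCFA features. Maximal runs of TCFA-candidate frames at least that long
#' are confirmed; shorter runs are demoted frame-by-frame to `ThCFA`
#' (NC-rich, but the cap criterion is unconfirmed — a severity-conservative
#' demotion). All other labels pass through unchanged. The operation is
#' idempotent.
#'
#' @param raw Ordered factor of raw labels in pullback order
#'   (from [classify_frames()]).
#' @param cfg An [analysis_config()].
#' @return Ordered factor of confirmed labels, same length.
#' @export
confirm_tcfa_runs <- function(raw, cfg = analysis_config()) {
  lab <- as.character(raw)
  if (length(lab) == 0) return(as_phenotype(lab))
  r <- rle(lab == "TCFA")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] < cfg$tcfa_min_run_frames) {
      lab[starts[k]:ends[k]] <- "ThCFA"
    }
  }
  as_phenotype(lab)
}

#' Identify confirmed TCFA runs
#'
#' @param raw Ordered factor of raw labels in pullback order.
#' @param cfg An [analysis_config()].
#' @return Data frame with one row per confirmed run: `start`, `end`
#'   (1-based positions in the label vector).
#' @export
tcfa_runs <- function(raw, cfg = analysis_config()) {
  lab <- as.character(raw)
  r <- rle(lab == "TCFA")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= cfg$tcfa_min_run_frames
  data.frame(start = starts[keep], end = ends[keep])
}

#' Label a segment by its most advanced frame phenotype
#'
#' A segment is labeled with the most advanced (highest-severity) confirmed
#' frame phenotype it contains. If a confirmed TCFA run straddles the segment
#' boundary — contributing at least one frame to this segment while the rest
#' of the run lies in a neighbor — the segment is labeled `TCFA` regardless
#' (set `straddle_tcfa = TRUE`), so both segments sharing a confirmed run
#' carry the TCFA label.
#'
#' @param confirmed Ordered factor of confirmed labels of the segment's
#'   frames (>= 1 frame).
#' @param straddle_tcfa Logical: a confirmed TCFA run touches this segment.
#' @return Single ordered-factor phenotype label.
#' @export
label_segment <- function(confirmed, straddle_tcfa = FALSE) {
  if (length(confirmed) == 0) stop("empty segment", call. = FALSE)
  if (isTRUE(straddle_tcfa)) return(as_phenotype("TCFA"))
  as_phenotype(phenotype_levels[max(severity_rank(confirmed)) + 1L])
}
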