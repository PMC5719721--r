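#' @importFrom stats approx coef median pnorm rbinom rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv
NULL

frame_cols <- c("frame_index", "axial_position_mm", "lumen_csa_mm2",
                "eem_csa_mm2", "f_area_mm2", "ff_area_mm2", "nc_area_mm2",
                "dc_area_mm2", "nc_lumen_arc_deg")

#' Validate a frame table
#'
#' A frame table has one row per IVUS-VH cross-section with geometry (lumen
#' and EEM cross-sectional areas, mm^2), the four VH tissue-component areas
#' (fibrous, fibro-fatty, necrotic core, dense calcium; mm^2), the arc of
#' necrotic core in contact with the lumen (degrees) and an axial position
#' along the centerline (mm, measured from the distal landmark, increasing
#' toward the ostium). Units are fixed by the schema; there is no unit
#' auto-detection.
#'
#' Enforced invariants, each reported with the offending `frame_index`:
#' * `0 <= lumen_csa_mm2 <= eem_csa_mm2`
#' * all component areas `>= 0`
#' * `f + ff + nc + dc <= (eem - lumen) * (1 + composition_tolerance_frac)`
#' * `nc_lumen_arc_deg` in \[0, 360\] and 0 whenever `nc_area_mm2` is 0
#' * `axial_position_mm` strictly increasing with `frame_index`
#'
#' @param frames A data frame with the frame-table columns.
#' @param cfg An [analysis_config()]; supplies the composition tolerance and
#'   the fallback frame spacing.
#' @return The validated frame table, sorted by `frame_index`, with
#'   `axial_position_mm` filled in if absent.
#' @export
validate_frames <- function(frames, cfg = analysis_config()) {
  frames <- as.data.frame(frames)
  if (is.null(frames$axial_position_mm) ||
      all(is.na(frames$axial_position_mm))) {
    frames$axial_position_mm <- frames$frame_index * cfg$frame_spacing_mm
  }
  missing <- setdiff(frame_cols, names(frames))
  if (length(missing) > 0) {
    stop("frame table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  frames <- frames[order(frames$frame_index), frame_cols, drop = FALSE]
  rownames(frames) <- NULL

  fail <- function(idx, rule) {
    stop(sprintf("frame validation error at frame_index %s: %s",
                 paste(frames$frame_index[idx], collapse = ", "), rule),
         call. = FALSE)
  }
  if (anyDuplicated(frames$frame_index)) {
    fail(which(duplicated(frames$frame_index)), "duplicated frame_index")
  }
  bad <- which(frames$lumen_csa_mm2 < 0 |
                 frames$lumen_csa_mm2 > frames$eem_csa_mm2)
  if (length(bad)) fail(bad, "lumen ≤ EEM violated (0 ≤ lumen_csa ≤ eem_csa)")
  comp <- c("f_area_mm2", "ff_area_mm2", "nc_area_mm2", "dc_area_mm2")
  bad <- which(apply(frames[comp] < 0, 1, any))
  if (length(bad)) fail(bad, "negative component area")
  plaque <- frames$eem_csa_mm2 - frames$lumen_csa_mm2
  total <- rowSums(frames[comp])
  bad <- which(total > plaque * (1 + cfg$composition_tolerance_frac) + 1e-12)
  if (length(bad)) {
    fail(bad, sprintf(
      "component areas exceed plaque area by more than %g%% tolerance",
      100 * cfg$composition_tolerance_frac))
  }
  bad <- which(frames$nc_lumen_arc_deg < 0 | frames$nc_lumen_arc_deg > 360)
  if (length(bad)) fail(bad, "nc_lumen_arc_deg outside [0, 360]")
  bad <- which(frames$nc_area_mm2 == 0 & frames$nc_lumen_arc_deg > 0)
  if (length(bad)) fail(bad, "nc_lumen_arc_deg > 0 with nc_area_mm2 = 0")
  if (nrow(frames) > 1 && any(diff(frames$axial_position_mm) <= 0)) {
    bad <- which(diff(frames$axial_position_mm) <= 0) + 1L
    fail(bad, "axial_position_mm not strictly increasing")
  }
  frames
}

#' Construct a pullback
#'
#' A pullback is the ordered frame sequence of one vessel at one timepoint,
#' together with the distal and proximal landmark frames that bound the
#' analyzed length.
#'
#' @param frames A frame table (see [validate_frames()]).
#' @param distal_landmark_frame,proximal_landmark_frame Frame indices of the
#'   two fiduciary points; distal < proximal.
#' @param timepoint `"baseline"` or `"follow_up"`.
#' @param vessel_id Identifier string.
#' @param cfg An [analysis_config()].
#' @return An object of class `vh_pullback`.
#' @export
pullback <- function(frames, distal_landmark_frame, proximal_landmark_frame,
                     timepoint = c("baseline", "follow_up"),
                     vessel_id = "vessel", cfg = analysis_config()) {
  timepoint <- match.arg(timepoint)
  frames <- validate_frames(frames, cfg)
  if (nrow(frames) < 2L) stop("a pullback needs at least 2 frames", call. = FALSE)
  if (!all(c(distal_landmark_frame, proximal_landmark_frame) %in%
             frames$frame_index)) {
    stop("landmark frames must be valid frame indices", call. = FALSE)
  }
  if (distal_landmark_frame >= proximal_landmark_frame) {
    stop("distal landmark must precede proximal landmark", call. = FALSE)
  }
  x <- list(frames = frames,
            distal_landmark_frame = as.integer(distal_landmark_frame),
            proximal_landmark_frame = as.integer(proximal_landmark_frame),
            timepoint = timepoint, vessel_id = vessel_id)
  class(x) <- "vh_pullback"
  x
}

frame_position <- function(pb, frame_index) {
  pb$frames$axial_position_mm[match(frame_index, pb$frames$frame_index)]
}

#' Analyzed length of a pullback
#'
#' Axial span (mm) between the distal and proximal landmark frames.
#' @param pb A `vh_pullback`.
#' @return Length in mm.
#' @export
analyzed_length <- function(pb) {
  frame_position(pb, pb$proximal_landmark_frame) -
    frame_position(pb, pb$distal_landmark_frame)
}

#' @export
print.vh_pullback <- function(x, ...) {
  cat(sprintf("IVUS-VH pullback '%s' (%s): %d frames, analyzed length %.1f mm\n",
              x$vessel_id, x$timepoint, nrow(x$frames), analyzed_length(x)))
  invisible(x)
}

#' Construct a patient study
#'
#' Pairs the baseline and 1-year follow-up pullbacks of one patient with the
#' landmark frame pairs used for co-registration, the patient group and any
#' clinical covariates.
#'
#' @param patient_id Identifier string.
#' @param group `"DM"` or `"non_DM"`.
#' @param baseline,follow_up `vh_pullback` objects.
#' @param landmark_pairs Data frame with columns `baseline_frame_index`,
#'   `follow_up_frame_index`; at least the two fiduciary points, strictly
#'   monotone in both coordinates.
#' @param covariates Optional named list of clinical values (LDLc, hs-CRP,
#'   glycemia, ...).
#' @return An object of class `vh_patient_study`.
#' @export
patient_study <- function(patient_id, group = c("DM", "non_DM"),
                          baseline, follow_up, landmark_pairs,
                          covariates = list()) {
  group <- match.arg(group)
  stopifnot(inherits(baseline, "vh_pullback"),
            inherits(follow_up, "vh_pullback"))
  lp <- as.data.frame(landmark_pairs)
  need <- c("baseline_frame_index", "follow_up_frame_index")
  if (!all(need %in% names(lp))) {
    stop("landmark_pairs must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lp <- lp[order(lp$baseline_frame_index), need, drop = FALSE]
  if (nrow(lp) < 2L) stop("need at least 2 landmark pairs", call. = FALSE)
  if (any(diff(lp$baseline_frame_index) <= 0) ||
      any(diff(lp$follow_up_frame_index) <= 0)) {
    stop("landmark pairs must be strictly monotone in both coordinates",
         call. = FALSE)
  }
  x <- list(patient_id = patient_id, group = group, baseline = baseline,
            follow_up = follow_up, landmark_pairs = lp,
            covariates = covariates)
  class(x) <- "vh_patient_study"
  x
}

#' @export
print.vh_patient_study <- function(x, ...) {
  cat(sprintf("Patient study '%s' (%s): baseline %.1f mm / follow-up %.1f mm, %d landmark pairs\n",
              x$patient_id, x$group, analyzed_length(x$baseline),
              analyzed_length(x$follow_up), nrow(x$landmark_pairs)))
  invisible(x)
}

#' Read a frame table from CSV
#'
#' Expects the schema
#' `frame_index,axial_position_mm,lumen_csa_mm2,eem_csa_mm2,f_area_mm2,ff_area_mm2,nc_area_mm2,dc_area_mm2,nc_lumen_arc_deg`.
#' Landmarks default to the first and last frame unless given.
#'
#' @param path CSV file path.
#' @param timepoint `"baseline"` or `"follow_up"`.
#' @param distal_landmark_frame,proximal_landmark_frame Optional landmark
#'   frame indices; default to the first / last frame of the table.
#' @param vessel_id Identifier; defaults to the file name.
#' @param cfg An [analysis_config()].
#' @return A `vh_pullback`.
#' @export
read_frame_table <- function(path, timepoint = c("baseline", "follow_up"),
                             distal_landmark_frame = NULL,
                             proximal_landmark_frame = NULL,
                             vessel_id = NULL, cfg = analysis_config()) {
  timepoint <- match.arg(timepoint)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(frame_cols, "axial_position_mm"), names(df))
  if (length(missing) > 0) {
    stop("frame table schema error in '", basename(path),
         "': missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- validate_frames(df, cfg)
  if (is.null(distal_landmark_frame)) distal_landmark_frame <- df$frame_index[1]
  if (is.null(proximal_landmark_frame)) {
    proximal_landmark_frame <- df$frame_index[nrow(df)]
  }
  if (is.null(vessel_id)) vessel_id <- sub("\\.csv$", "", basename(path))
  pullback(df, distal_landmark_frame, proximal_landmark_frame,
           timepoint = timepoint, vessel_id = vessel_id, cfg = cfg)
}

#' Read a landmark-pair file
#'
#' CSV with columns `baseline_frame_index,follow_up_frame_index`.
#' @param path CSV file path.
#' @return A data frame of landmark pairs.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("baseline_frame_index", "follow_up_frame_index")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("landmark file schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df[need]
}

#' Write result tables and a run manifest
#'
#' Writes one CSV per supplied result family plus a JSON manifest recording
#' the configuration hash, the seed, the row count of every table and the
#' list of files written. Re-reading a written table reproduces integer
#' columns exactly and real columns to at least 1e-9.
#'
#' @param tables Named list of data frames (e.g. `per_frame`, `per_segment`,
#'   `per_patient`, `group_stats`).
#' @param out_dir Output directory (created if absent).
#' @param cfg The [analysis_config()] used, stored as a hash in the manifest.
#' @param seed Optional RNG seed to record.
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(tables, out_dir, cfg = analysis_config(),
                          seed = NULL) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output dir: ", out_dir,
                                 call. = FALSE)
  files <- character(0)
  counts <- list()
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
    counts[[nm]] <- nrow(tables[[nm]])
  }
  manifest <- list(
    package = "serialvh",
    version = as.character(utils::packageVersion("serialvh")),
    config_hash = config_hash(cfg),
    seed = seed,
    counts = counts,
    files = basename(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

config_hash <- function(cfg) {
  # order-stable digest of the config without external digest packages
  s <- paste(deparse(unclass(cfg)[order(names(unclass(cfg)))]), collapse = "")
  raw <- utils::head(charToRaw(s), 100000L)
  sprintf("%08x-%08x", sum(as.integer(raw) * seq_along(raw)) %% 0xFFFFFFFF,
          length(raw))
}
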