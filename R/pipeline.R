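#' Analyze a cohort of patient studies
#'
#' Runs the full serial analysis over every patient: registration,
#' partition into paired 5-mm segments, morphometry, confirmed phenotype
#' labels, LAPS, then cohort-level phenotype-transition matrices, TCFA fates
#' and the DM vs non-DM group-statistics table. Patients that cannot be
#' analyzed (e.g. registered overlap below the inclusion minimum) are
#' skipped and recorded with their reason rather than aborting the run
#' (set `strict = TRUE` to abort instead).
#'
#' @param cohort A list of [patient_study()] objects (e.g. a `vh_cohort`).
#' @param cfg An [analysis_config()].
#' @param strict Abort on the first failed patient instead of recording an
#'   exclusion.
#' @return List of class `vh_analysis`:
#'   * `segments`: pooled segment-pair table with `patient_id` and `group`;
#'   * `patients`: per-patient table (segment count, pullback LAPS at both
#'     timepoints and its change, mean deltas);
#'   * `transitions`, `fates`: per-group transition matrices and TCFA fates;
#'   * `group_stats`: the DM vs non-DM comparison table;
#'   * `exclusions`: data frame of skipped patients with reasons.
#' @export
analyze_cohort <- function(cohort, cfg = analysis_config(), strict = FALSE) {
  seg_list <- list()
  pat_list <- list()
  excl <- data.frame(patient_id = character(0), reason = character(0))
  for (study in cohort) {
    res <- tryCatch(partition_segments(study, cfg = cfg),
                    vh_exclusion = function(e) e)
    if (inherits(res, "vh_exclusion")) {
      if (strict) stop(res)
      excl <- rbind(excl, data.frame(patient_id = res$patient_id,
                                     reason = res$reason))
      next
    }
    seg <- as.data.frame(res)
    seg$patient_id <- study$patient_id
    seg$group <- study$group
    seg_list[[study$patient_id]] <- seg
    pat_list[[study$patient_id]] <- data.frame(
      patient_id = study$patient_id,
      group = study$group,
      n_segments = nrow(seg),
      analyzed_length_mm = nrow(seg) * cfg$segment_length_mm,
      laps_pullback_bl = laps_pullback(seg$laps_bl),
      laps_pullback_fu = laps_pullback(seg$laps_fu),
      delta_laps_pullback = laps_pullback(seg$laps_fu) -
        laps_pullback(seg$laps_bl),
      mean_delta_plaque_mm2 = mean(seg$delta_mean_plaque_csa_mm2),
      mean_delta_pav_pct = mean(seg$delta_pav_pct)
    )
  }
  if (length(seg_list) == 0) stop("no patients could be analyzed",
                                  call. = FALSE)
  segments <- do.call(rbind, seg_list)
  rownames(segments) <- NULL
  patients <- do.call(rbind, pat_list)
  rownames(patients) <- NULL

  by_group <- split(segments, segments$group)
  transitions <- lapply(by_group, transition_matrix)
  fates <- lapply(by_group, classify_tcfa_fates)
  out <- list(segments = segments, patients = patients,
              transitions = transitions, fates = fates,
              group_stats = group_stats_table(segments),
              exclusions = excl)
  class(out) <- "vh_analysis"
  out
}

#' @export
print.vh_analysis <- function(x, ...) {
  cat(sprintf("Serial IVUS-VH analysis: %d patients, %d segment pairs (%d excluded)\n",
              nrow(x$patients), nrow(x$segments), nrow(x$exclusions)))
  for (g in names(x$fates)) {
    f <- x$fates[[g]]
    cat(sprintf("  %s: %d segments, TCFA share BL %.1f%%, new-TCFA rate %.1f%%\n",
                g, sum(x$segments$group == g),
                group_phenotype_share(x$segments[x$segments$group == g, ],
                                      "TCFA")$percent,
                100 * f$rates$new_rate))
  }
  invisible(x)
}

#' Write a cohort to disk in the package's file formats
#'
#' One frame-table CSV per pullback, one landmark CSV per patient, and a
#' JSON cohort manifest listing patients, group labels, file paths and
#' covariates — the on-disk form consumed by [read_cohort()] and
#' [run_study()].
#'
#' @param cohort A list of [patient_study()] objects.
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  patients <- lapply(cohort, function(s) {
    base <- s$patient_id
    bl_f <- paste0(base, "_baseline.csv")
    fu_f <- paste0(base, "_follow_up.csv")
    lm_f <- paste0(base, "_landmarks.csv")
    write.csv(s$baseline$frames, file.path(dir, bl_f), row.names = FALSE)
    write.csv(s$follow_up$frames, file.path(dir, fu_f), row.names = FALSE)
    write.csv(s$landmark_pairs, file.path(dir, lm_f), row.names = FALSE)
    list(patient_id = s$patient_id, group = s$group,
         baseline = bl_f, follow_up = fu_f, landmarks = lm_f,
         baseline_landmark_frames = c(s$baseline$distal_landmark_frame,
                                      s$baseline$proximal_landmark_frame),
         follow_up_landmark_frames = c(s$follow_up$distal_landmark_frame,
                                       s$follow_up$proximal_landmark_frame),
         covariates = s$covariates)
  })
  manifest <- file.path(dir, "cohort.json")
  jsonlite::write_json(list(patients = unname(patients)), manifest,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort from a manifest written by [write_cohort()]
#'
#' @param manifest_path Path to `cohort.json` (JSON or YAML).
#' @param cfg An [analysis_config()].
#' @return A list of `vh_patient_study` objects, class `vh_cohort`.
#' @export
read_cohort <- function(manifest_path, cfg = analysis_config()) {
  if (!file.exists(manifest_path)) stop("no such file: ", manifest_path,
                                        call. = FALSE)
  man <- if (grepl("\\.ya?ml$", manifest_path)) {
    yaml::read_yaml(manifest_path)
  } else {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  }
  if (is.null(man$patients) || length(man$patients) == 0) {
    stop("no patients in cohort manifest", call. = FALSE)
  }
  dir <- dirname(manifest_path)
  cohort <- lapply(man$patients, function(p) {
    blm <- unlist(p$baseline_landmark_frames)
    fum <- unlist(p$follow_up_landmark_frames)
    patient_study(
      patient_id = p$patient_id, group = p$group,
      baseline = read_frame_table(file.path(dir, p$baseline), "baseline",
                                  distal_landmark_frame = blm[1],
                                  proximal_landmark_frame = blm[2],
                                  vessel_id = p$patient_id, cfg = cfg),
      follow_up = read_frame_table(file.path(dir, p$follow_up), "follow_up",
                                   distal_landmark_frame = fum[1],
                                   proximal_landmark_frame = fum[2],
                                   vessel_id = p$patient_id, cfg = cfg),
      landmark_pairs = read_landmarks(file.path(dir, p$landmarks)),
      covariates = if (is.null(p$covariates)) list() else p$covariates)
  })
  names(cohort) <- vapply(cohort, function(s) s$patient_id, character(1))
  class(cohort) <- "vh_cohort"
  cohort
}

#' Run a complete study from files
#'
#' Reads a cohort manifest, runs [analyze_cohort()] and writes the per-frame
#' summary tables, the segment-pair table, the per-patient table, the
#' per-group transition and fate tables, the group-statistics table and a
#' JSON run manifest to `out_dir`.
#'
#' @param manifest_path Path to a cohort manifest (see [write_cohort()]).
#' @param out_dir Output directory.
#' @param cfg An [analysis_config()] or path to a YAML config.
#' @param strict Passed to [analyze_cohort()].
#' @param seed Recorded in the run manifest (the analysis itself is
#'   deterministic).
#' @return Invisibly, the run manifest list.
#' @export
run_study <- function(manifest_path, out_dir, cfg = analysis_config(),
                      strict = FALSE, seed = NULL) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  cohort <- read_cohort(manifest_path, cfg)
  res <- analyze_cohort(cohort, cfg, strict = strict)
  tables <- list(
    per_segment = res$segments,
    per_patient = res$patients,
    group_stats = res$group_stats,
    exclusions = res$exclusions
  )
  for (g in names(res$transitions)) {
    tm <- res$transitions[[g]]$counts
    tables[[paste0("transitions_", g)]] <-
      data.frame(baseline = rownames(tm), as.data.frame.matrix(tm))
    f <- res$fates[[g]]
    tables[[paste0("fates_", g)]] <- data.frame(
      fate = names(f$counts), count = as.integer(f$counts))
  }
  manifest <- write_results(tables, out_dir, cfg = cfg, seed = seed)
  manifest$n_patients <- nrow(res$patients)
  manifest$n_segments <- nrow(res$segments)
  manifest$exclusions <- res$exclusions
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
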