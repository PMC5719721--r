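#' Synthetic cohort generator configuration
#'
#' Loads the packaged default calibration (two patient groups with
#' group-specific vessel-length, per-segment delta and TCFA-fate
#' distributions) and applies any overrides. Defaults live in
#' `inst/extdata/generator-defaults.yaml`; every field can be overridden by
#' name.
#'
#' @param ... Named overrides of top-level fields (nested lists are replaced
#'   wholesale).
#' @param path Optional YAML file to read instead of the packaged defaults.
#' @return An object of class `vh_generator_config`.
#' @export
#' @examples
#' gcfg <- generator_config(n_dm = 3, n_nondm = 4)
generator_config <- function(..., path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "generator-defaults.yaml",
                        package = "serialvh")
  }
  gcfg <- yaml::read_yaml(path)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(gcfg))
    if (length(bad)) stop("unknown generator field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    gcfg[names(dots)] <- dots
  }
  class(gcfg) <- "vh_generator_config"
  validate_generator_config(gcfg)
  gcfg
}

validate_generator_config <- function(gcfg) {
  stopifnot(gcfg$n_dm >= 0, gcfg$n_nondm >= 0)
  probs <- c(unlist(gcfg$fates), unlist(gcfg$baseline_mix),
             gcfg$patient_intercept_frac, gcfg$characterized_frac)
  if (any(probs < 0 | probs > 1)) {
    stop("generator config error: probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  for (g in c("DM", "non_DM")) {
    mix <- unlist(gcfg$baseline_mix[[g]])
    if (abs(sum(mix) - 1) > 1e-6) {
      stop("generator config error: baseline_mix for ", g,
           " must sum to 1", call. = FALSE)
    }
    if (gcfg$vessel_length_mm[[g]]$sd <= 0) {
      stop("generator config error: vessel length SD must be > 0",
           call. = FALSE)
    }
  }
  if (gcfg$min_length_mm < 30) {
    stop("generator config error: min_length_mm below the 30 mm inclusion criterion",
         call. = FALSE)
  }
  invisible(gcfg)
}

#' Draw per-segment morphometric deltas
#'
#' I.i.d. draws from the configured group distributions of the 1-year
#' per-segment change of mean plaque CSA and of PAV. When `patient_ids` is
#' supplied, a shared patient random intercept accounts for
#' `patient_intercept_frac` of each delta's variance and the remainder is
#' segment-level noise (marginal distributions unchanged).
#'
#' @param group `"DM"` or `"non_DM"`.
#' @param n Number of segments (>= 1).
#' @param gcfg A [generator_config()].
#' @param patient_ids Optional vector of length `n` assigning segments to
#'   patients.
#' @param seed Optional RNG seed.
#' @return Data frame: `group`, `patient_id` (NA when not supplied),
#'   `delta_plaque_area_mm2`, `delta_pav_pct`.
#' @export
generate_segment_deltas <- function(group, n, gcfg = generator_config(),
                                    patient_ids = NULL, seed = NULL) {
  if (!group %in% c("DM", "non_DM")) stop("unknown group: ", group,
                                          call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rho <- if (is.null(patient_ids)) 0 else gcfg$patient_intercept_frac
  draw <- function(par) {
    z <- rnorm(n)
    if (rho > 0) {
      pid <- factor(patient_ids)
      u <- rnorm(nlevels(pid))[pid]
      par$mean + par$sd * (sqrt(rho) * u + sqrt(1 - rho) * z)
    } else {
      par$mean + par$sd * z
    }
  }
  data.frame(
    group = group,
    patient_id = if (is.null(patient_ids)) NA_character_ else
      as.character(patient_ids),
    delta_plaque_area_mm2 = draw(gcfg$delta_plaque_area_mm2[[group]]),
    delta_pav_pct = draw(gcfg$delta_pav_pct[[group]])
  )
}

#' Draw per-patient pullback LAPS changes
#'
#' I.i.d. draws from the configured group distribution of the 1-year change
#' of pullback-level LAPS (a patient-level quantity).
#'
#' @inheritParams generate_segment_deltas
#' @param n Number of patients.
#' @return Numeric vector of length `n`.
#' @export
generate_laps_deltas <- function(group, n, gcfg = generator_config(),
                                 seed = NULL) {
  if (!group %in% c("DM", "non_DM")) stop("unknown group: ", group,
                                          call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  par <- gcfg$delta_pullback_laps[[group]]
  rnorm(n, par$mean, par$sd)
}

#' Draw baseline/follow-up phenotype pairs from the fate model
#'
#' Draws baseline labels (`"TCFA"` or a non-TCFA phenotype) and applies the
#' configured fate probabilities: a baseline TCFA persists with
#' `persistent_tcfa` probability (otherwise it heals into ThCFA); a baseline
#' non-TCFA becomes a new TCFA with `new_tcfa` probability (otherwise it
#' keeps its label).
#'
#' @inheritParams generate_segment_deltas
#' @param n_tcfa Number of baseline-TCFA segment pairs.
#' @param n_non_tcfa Number of baseline-non-TCFA segment pairs (baseline
#'   labels drawn from the non-TCFA part of the configured mixture).
#' @return Data frame: `phenotype_bl`, `phenotype_fu`.
#' @export
generate_fate_pairs <- function(group, n_tcfa, n_non_tcfa,
                                gcfg = generator_config(), seed = NULL) {
  if (!group %in% c("DM", "non_DM")) stop("unknown group: ", group,
                                          call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mix <- unlist(gcfg$baseline_mix[[group]])
  non <- mix[setdiff(names(mix), "TCFA")]
  bl <- c(rep("TCFA", n_tcfa),
          sample(names(non), n_non_tcfa, replace = TRUE,
                 prob = non / sum(non)))
  p_pers <- gcfg$fates$persistent_tcfa[[group]]
  p_new <- gcfg$fates$new_tcfa[[group]]
  fu <- ifelse(bl == "TCFA",
               ifelse(runif(length(bl)) < p_pers, "TCFA", "ThCFA"),
               ifelse(runif(length(bl)) < p_new, "TCFA", bl))
  data.frame(phenotype_bl = bl, phenotype_fu = fu)
}

# ---------------------------------------------------------------------------
# frame-level synthesis
#
# Composition targets per frame role, as fractions of characterized tissue.
# Clamp windows keep every frame safely inside the classification region of
# its intended phenotype while leaving the NC/DC ratio adjustable for the
# pullback-LAPS calibration (DC is deliberately the free knob).
role_targets <- list(
  TCFA_run = list(nc = 0.20, nc_lim = c(0.13, 0.30), dc = 0.040,
                  dc_lim = c(0.010, 0.090), ff = 0.12, ff_lim = c(0.02, 0.30),
                  arc = "contact"),
  ThCFA    = list(nc = 0.16, nc_lim = c(0.11, 0.30), dc = 0.032,
                  dc_lim = c(0.008, 0.090), ff = 0.12, ff_lim = c(0.02, 0.30),
                  arc = "clear"),
  FcP      = list(nc = 0.05, nc_lim = c(0.01, 0.085), dc = 0.130,
                  dc_lim = c(0.108, 0.250), ff = 0.10, ff_lim = c(0.02, 0.30),
                  arc = "clear"),
  PIT      = list(nc = 0.05, nc_lim = c(0.01, 0.085), dc = 0.010,
                  dc_lim = c(0.003, 0.080), ff = 0.22, ff_lim = c(0.17, 0.35),
                  arc = "clear"),
  FP       = list(nc = 0.05, nc_lim = c(0.01, 0.085), dc = 0.010,
                  dc_lim = c(0.003, 0.080), ff = 0.08, ff_lim = c(0.01, 0.13),
                  arc = "clear"),
  NL       = list(nc = 0.05, nc_lim = c(0.01, 0.085), dc = 0.010,
                  dc_lim = c(0.003, 0.080), ff = 0.12, ff_lim = c(0.02, 0.13),
                  arc = "clear")
)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# burden regions: NL frames must stay below the 40% lesion threshold,
# lesion frames above it, with a safety margin against frame noise
burden_region <- function(is_nl) if (is_nl) c(0.20, 0.385) else c(0.405, 0.90)

#' Generate a synthetic serial IVUS-VH cohort
#'
#' Builds complete [patient_study()] objects for the configured numbers of
#' DM and non-DM patients. Generation is top-down so the pipeline can be
#' tested against exact known ground truth:
#'
#' 1. vessel length and a patient mean EEM CSA are drawn per group; the
#'    vessel is divided into consecutive `segment`-length stretches and each
#'    gets a baseline phenotype from the configured mixture, a baseline
#'    plaque-burden target (below the lesion threshold for NL, above it
#'    otherwise) and, for TCFA segments, an interior run of 4-6 frames with
#'    confluent NC abutting the lumen;
#' 2. follow-up targets come from the fate model (persistent / healed / new
#'    TCFA) plus per-segment draws of the plaque-area and PAV deltas (shared
#'    patient random intercept + segment noise); follow-up EEM per frame is
#'    solved so the segment hits both targeted deltas exactly on the
#'    noise-free profile;
#' 3. frames are synthesized every `frame_spacing_mm` at baseline and on a
#'    mildly stretched grid (piecewise-linear, up to `stretch_max`) at
#'    follow-up, with three landmark pairs (both ends + one mid-vessel);
#' 4. the follow-up NC/DC ratios are shifted uniformly (within each frame's
#'    phenotype-preserving bounds) so the patient's pullback-LAPS change
#'    matches its drawn target.
#'
#' The intended segment labels at both timepoints are attached to each study
#' as attribute `"intended"` and collected by [intended_labels()].
#'
#' @param gcfg A [generator_config()]; `gcfg$seed` makes the cohort fully
#'   reproducible.
#' @param cfg The [analysis_config()] the cohort is calibrated against.
#' @return List of `vh_patient_study` objects, class `vh_cohort`.
#' @export
generate_cohort <- function(gcfg = generator_config(),
                            cfg = analysis_config()) {
  validate_generator_config(gcfg)
  set.seed(gcfg$seed)
  n <- gcfg$n_dm + gcfg$n_nondm
  groups <- rep(c("DM", "non_DM"), c(gcfg$n_dm, gcfg$n_nondm))
  ids <- c(sprintf("DM%02d", seq_len(gcfg$n_dm)),
           sprintf("ND%02d", seq_len(gcfg$n_nondm)))
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    cohort[[i]] <- generate_patient(ids[i], groups[i], gcfg, cfg)
  }
  names(cohort) <- ids
  class(cohort) <- "vh_cohort"
  attr(cohort, "generator_config") <- gcfg
  cohort
}

#' @export
print.vh_cohort <- function(x, ...) {
  groups <- vapply(x, function(s) s$group, character(1))
  cat(sprintf("Synthetic IVUS-VH cohort: %d patients (%d DM, %d non-DM)\n",
              length(x), sum(groups == "DM"), sum(groups == "non_DM")))
  invisible(x)
}

#' Intended segment labels of a generated cohort
#'
#' @param cohort A `vh_cohort` from [generate_cohort()].
#' @return Data frame: `patient_id`, `group`, `segment_index`,
#'   `intended_bl`, `intended_fu`.
#' @export
intended_labels <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) attr(s, "intended")))
}

# one segment's role for a baseline coordinate p, given segment parameters.
# The run interval carries a +/- 0.24 mm margin: narrower than the frame
# spacing (so no extra baseline frame joins the run) but wide enough that a
# stretched follow-up grid still lands >= 3 frames inside a 4-frame run.
segment_role <- function(phen, run, p) {
  if (phen == "TCFA" && !is.null(run) &&
      p >= run[1] - 0.24 && p <= run[2] + 0.24) return("TCFA_run")
  if (phen == "TCFA") return("ThCFA")   # off-run frames of a TCFA segment
  phen
}

# synthesize one frame at baseline coordinate p; 'sp' is the per-segment
# parameter list, 'tp' "bl" or "fu"
synth_frame <- function(p, sp, tp, gcfg) {
  t_rel <- (p - sp$lo) / (sp$hi - sp$lo)
  bump_b <- sp$bump_amp * (1 - (2 * t_rel - 1)^2)       # lesion burden bump
  bump_e <- 1 + sp$eem_bump * (1 - (2 * t_rel - 1)^2)   # remodeling bump
  e0 <- sp$eem * bump_e
  if (tp == "bl") {
    phen <- sp$phen_bl; run <- sp$run_bl
    b0 <- clamp(sp$burden + bump_b, sp$b_lim[1], sp$b_lim[2])
    b <- clamp(b0 + rnorm(1, 0, 0.003), sp$b_lim[1], sp$b_lim[2])
    eem <- e0 * (1 + rnorm(1, 0, 0.01))
    plaque <- eem * b
  } else {
    phen <- sp$phen_fu; run <- sp$run_fu
    b0 <- clamp(sp$burden + bump_b, sp$b_lim[1], sp$b_lim[2])
    plaque <- max(e0 * b0 + sp$d_plaque, 0.3)
    bf <- clamp(sp$c_scale * b0 + rnorm(1, 0, 0.003),
                sp$b_lim_fu[1], sp$b_lim_fu[2])
    eem <- plaque / bf
    b <- bf
  }
  role <- segment_role(phen, run, p)
  rt <- role_targets[[role]]
  # composition targets vary between segments (sp$comp_jit), with only a
  # small frame-level jitter so the within-segment NC/DC ratio stays flat
  nc <- clamp(rt$nc + sp$comp_jit[1] + rnorm(1, 0, 0.003),
              rt$nc_lim[1], rt$nc_lim[2])
  dc <- clamp(rt$dc * (1 + sp$comp_jit[2]) + rnorm(1, 0, 0.001),
              rt$dc_lim[1], rt$dc_lim[2])
  ff <- clamp(rt$ff + sp$comp_jit[3] + rnorm(1, 0, 0.003),
              rt$ff_lim[1], rt$ff_lim[2])
  total <- gcfg$characterized_frac * plaque
  arc <- if (rt$arc == "contact") clamp(rnorm(1, 70, 20), 35, 160) else
    runif(1, 0, 20)
  c(lumen = eem - plaque, eem = eem,
    f = (1 - nc - dc - ff) * total, ff = ff * total,
    nc = nc * total, dc = dc * total, arc = arc)
}

generate_patient <- function(patient_id, group, gcfg, cfg) {
  sl <- cfg$segment_length_mm
  h <- gcfg$frame_spacing_mm
  len_par <- gcfg$vessel_length_mm[[group]]
  L <- clamp(rnorm(1, len_par$mean, len_par$sd),
             gcfg$min_length_mm, gcfg$max_length_mm)
  L <- floor(L / h) * h
  n_seg <- floor(L / sl + 1e-9)
  frames_per_seg <- round(sl / h)

  # patient-level draws
  eem_p <- max(rnorm(1, gcfg$eem_mean_mm2[[group]],
                     gcfg$eem_sd_patient_mm2), 8)
  u_plaque <- rnorm(1)   # patient random intercepts (standardized)
  u_pav <- rnorm(1)
  laps_target <- rnorm(1, gcfg$delta_pullback_laps[[group]]$mean,
                       gcfg$delta_pullback_laps[[group]]$sd)

  mix <- unlist(gcfg$baseline_mix[[group]])
  p_pers <- gcfg$fates$persistent_tcfa[[group]]
  p_new <- gcfg$fates$new_tcfa[[group]]
  rho <- gcfg$patient_intercept_frac

  dP <- gcfg$delta_plaque_area_mm2[[group]]
  dV <- gcfg$delta_pav_pct[[group]]

  # per-segment parameters (+ one tail stretch beyond the last full segment)
  segs <- vector("list", n_seg + 1L)
  eta <- 0
  intended <- data.frame(patient_id = character(0), group = character(0),
                         segment_index = integer(0),
                         intended_bl = character(0),
                         intended_fu = character(0))
  for (k in seq_len(n_seg + 1L)) {
    tail_seg <- k > n_seg
    lo <- (k - 1) * sl
    hi <- if (tail_seg) max(L, lo + sl) else lo + sl
    eta <- 0.7 * eta + rnorm(1, 0, gcfg$eem_sd_segment_rel * sqrt(1 - 0.49))
    phen_bl <- if (tail_seg) "NL" else
      sample(names(mix), 1, prob = mix)
    is_nl <- phen_bl == "NL"
    burden <- if (is_nl) clamp(rnorm(1, 0.33, 0.02), 0.24, 0.37) else
      clamp(rnorm(1, 0.47, 0.03), 0.42, 0.58)
    run_bl <- NULL
    if (phen_bl == "TCFA") {
      rl <- sample(4:6, 1)
      off <- sample(seq(1, frames_per_seg - 1 - rl), 1)
      run_bl <- lo + c(off, off + rl - 1) * h
    }
    # fate
    if (tail_seg) {
      phen_fu <- "NL"
    } else if (phen_bl == "TCFA") {
      phen_fu <- if (runif(1) < p_pers) "TCFA" else "ThCFA"
    } else {
      phen_fu <- if (runif(1) < p_new) "TCFA" else phen_bl
    }
    run_fu <- NULL
    if (phen_fu == "TCFA") {
      if (!is.null(run_bl)) run_fu <- run_bl else {
        rl <- sample(4:6, 1)
        off <- sample(seq(1, frames_per_seg - 1 - rl), 1)
        run_fu <- lo + c(off, off + rl - 1) * h
      }
    }
    d_plaque <- if (tail_seg) 0 else
      dP$mean + dP$sd * (sqrt(rho) * u_plaque + sqrt(1 - rho) * rnorm(1))
    d_pav <- if (tail_seg) 0 else
      dV$mean + dV$sd * (sqrt(rho) * u_pav + sqrt(1 - rho) * rnorm(1))

    b_lim <- burden_region(is_nl)
    b_lim_fu <- burden_region(phen_fu == "NL")
    sp <- list(lo = lo, hi = hi, eem = eem_p * (1 + eta),
               burden = burden, b_lim = b_lim, b_lim_fu = b_lim_fu,
               bump_amp = if (is_nl) 0.005 else runif(1, 0.01, 0.04),
               eem_bump = if (runif(1) < 0.2) runif(1, 0.04, 0.10) else
                 runif(1, 0, 0.02),
               phen_bl = phen_bl, phen_fu = phen_fu,
               run_bl = run_bl, run_fu = run_fu,
               comp_jit = c(rnorm(1, 0, 0.012), rnorm(1, 0, 0.10),
                            rnorm(1, 0, 0.015)),
               d_plaque = d_plaque, d_pav = d_pav)
    # solve the follow-up burden scale on the noise-free profile so the
    # segment hits its PAV delta given its plaque delta
    pg <- seq(lo, min(hi - h / 2, L), by = h)
    tr <- (pg - lo) / (hi - lo)
    b0 <- clamp(burden + sp$bump_amp * (1 - (2 * tr - 1)^2),
                b_lim[1], b_lim[2])
    e0 <- sp$eem * (1 + sp$eem_bump * (1 - (2 * tr - 1)^2))
    pl0 <- e0 * b0
    r_bl <- sum(pl0) / sum(e0)
    r_fu <- clamp(r_bl + d_pav / 100,
                  b_lim_fu[1] + 0.002, b_lim_fu[2] - 0.002)
    # new TCFA arising in a no-lesion segment implies lesion formation:
    # burden must clear the lesion threshold at follow-up
    if (phen_fu != "NL" && is_nl) r_fu <- max(r_fu, 0.43)
    pl1 <- pmax(pl0 + d_plaque, 0.3)
    sp$c_scale <- r_fu * sum(pl1 / b0) / sum(pl1)
    segs[[k]] <- sp
    if (!tail_seg) {
      intended <- rbind(intended, data.frame(
        patient_id = patient_id, group = group, segment_index = k - 1L,
        intended_bl = phen_bl, intended_fu = phen_fu))
    }
  }

  seg_of <- function(p) pmin(floor(p / sl + 1e-9) + 1L, n_seg + 1L)

  build_frames <- function(pos, tp) {
    rows <- t(vapply(seq_along(pos), function(j) {
      synth_frame(pos[j], segs[[seg_of(pos[j])]], tp, gcfg)
    }, numeric(7)))
    data.frame(frame_index = seq_along(pos) - 1L,
               axial_position_mm = pos,
               lumen_csa_mm2 = rows[, "lumen"],
               eem_csa_mm2 = rows[, "eem"],
               f_area_mm2 = rows[, "f"],
               ff_area_mm2 = rows[, "ff"],
               nc_area_mm2 = rows[, "nc"],
               dc_area_mm2 = rows[, "dc"],
               nc_lumen_arc_deg = rows[, "arc"])
  }

  # registration geometry: anchors at both ends + one mid-vessel landmark,
  # snapped to the frame grids so landmark pairs are exact
  m <- round(L * runif(1, 0.4, 0.6) / h) * h
  s1 <- runif(1, 1 - gcfg$stretch_max, 1 + gcfg$stretch_max)
  s2 <- runif(1, 1 - gcfg$stretch_max, 1 + gcfg$stretch_max)
  gm <- max(round(m * s1 / h) * h, h)
  gL <- gm + max(round((L - m) * s2 / h) * h, h)
  bl_anchor <- c(0, m, L)
  fu_anchor <- c(0, gm, gL)
  ginv <- function(q) approx(fu_anchor, bl_anchor, xout = q, rule = 2)$y

  pos_bl <- seq(0, L, by = h)
  pos_fu_grid <- seq(0, gL, by = h)
  p_equiv <- ginv(pos_fu_grid)
  # snap positions that are numerically at a segment boundary
  near <- abs(p_equiv - round(p_equiv / sl) * sl) < 1e-6
  p_equiv[near] <- round(p_equiv[near] / sl) * sl

  bl_frames <- build_frames(pos_bl, "bl")
  fu_frames <- build_frames(p_equiv, "fu")
  fu_frames$axial_position_mm <- pos_fu_grid

  lp <- data.frame(
    baseline_frame_index = as.integer(round(bl_anchor / h)),
    follow_up_frame_index = as.integer(round(fu_anchor / h)))

  # covariates (LDLc change correlated with the patient plaque intercept)
  cv <- gcfg$covariates
  r_ldl <- cv$ldl_plaque_corr[[group]]
  ldl_bl <- rnorm(1, cv$ldl_baseline_mmol_l[[group]]$mean,
                  cv$ldl_baseline_mmol_l[[group]]$sd)
  ldl_change <- cv$ldl_change_mmol_l[[group]]$mean +
    cv$ldl_change_mmol_l[[group]]$sd *
    (r_ldl * u_plaque + sqrt(1 - r_ldl^2) * rnorm(1))
  covariates <- list(
    ldl_baseline_mmol_l = ldl_bl,
    ldl_follow_up_mmol_l = ldl_bl + ldl_change,
    ldl_change_mmol_l = ldl_change,
    glycemia_baseline_mmol_l = rnorm(1, cv$glycemia_baseline_mmol_l[[group]]$mean,
                                     cv$glycemia_baseline_mmol_l[[group]]$sd),
    hscrp_baseline_mg_l = max(rnorm(1, cv$hscrp_baseline_mg_l[[group]]$mean,
                                    cv$hscrp_baseline_mg_l[[group]]$sd), 0.05)
  )

  make_study <- function(fu_fr) {
    patient_study(
      patient_id = patient_id, group = group,
      baseline = pullback(bl_frames, 0L, nrow(bl_frames) - 1L,
                          timepoint = "baseline", vessel_id = patient_id,
                          cfg = cfg),
      follow_up = pullback(fu_fr, 0L, nrow(fu_fr) - 1L,
                           timepoint = "follow_up", vessel_id = patient_id,
                           cfg = cfg),
      landmark_pairs = lp, covariates = covariates)
  }
  study <- make_study(fu_frames)

  # pullback-LAPS calibration: the patient's pullback-LAPS change is pushed
  # toward its drawn target by shifting NC/DC ratios. The shift is uniform
  # within each 5-mm segment (so the segment's maximum moves by exactly that
  # amount), two-sided (follow-up segments shift with the needed change,
  # baseline segments against it) and distributed across segments by
  # waterfilling within each segment's phenotype-preserving headroom.
  sp_tab <- partition_segments(study, cfg = cfg)
  fd <- attr(sp_tab, "frames")
  current <- laps_pullback(sp_tab$laps_fu) - laps_pullback(sp_tab$laps_bl)
  n_an <- nrow(sp_tab)
  side_caps <- function(frames, side) {
    bounds <- ratio_bounds(frames, cfg)
    lo <- hi <- numeric(n_an)
    rows_l <- vector("list", n_an)
    for (j in seq_len(n_an)) {
      f_j <- fd[[j]][[side]]
      rows <- match(f_j$frame_index, frames$frame_index)
      rows_l[[j]] <- rows
      amax <- rows[which.max(f_j$frame_laps)]
      lo[j] <- cfg$laps_coeffs$nc_dc * (bounds$rlo[amax] - bounds$r[amax])
      hi[j] <- cfg$laps_coeffs$nc_dc * (bounds$rhi[amax] - bounds$r[amax])
    }
    list(lo = lo, hi = hi, rows = rows_l)
  }
  cap_fu <- side_caps(fu_frames, "follow_up")
  cap_bl <- side_caps(bl_frames, "baseline")
  # component k <= n_an: shift of follow-up segment k (adds c_k / n_an);
  # component k > n_an: negated shift of baseline segment k (adds c_k / n_an)
  delta <- waterfill((laps_target - current) * n_an,
                     c(cap_fu$lo, -cap_bl$hi), c(cap_fu$hi, -cap_bl$lo))
  dr_fu <- numeric(nrow(fu_frames))
  dr_bl <- numeric(nrow(bl_frames))
  for (j in seq_len(n_an)) {
    dr_fu[cap_fu$rows[[j]]] <- delta[j] / cfg$laps_coeffs$nc_dc
    dr_bl[cap_bl$rows[[j]]] <- -delta[n_an + j] / cfg$laps_coeffs$nc_dc
  }
  fu_frames <- adjust_nc_dc(fu_frames, dr_fu, cfg)
  bl_frames <- adjust_nc_dc(bl_frames, dr_bl, cfg)
  study <- make_study(fu_frames)

  attr(study, "intended") <- intended
  attr(study, "laps_delta_target") <- laps_target
  attr(study, "laps_delta_precal") <- current
  study
}

# feasible NC/DC ratio window per frame: DC is the free knob (NC and FF are
# fixed; F compensates so characterized tissue is unchanged) and the window
# keeps each frame inside its phenotype's classification region
ratio_bounds <- function(frames, cfg) {
  nc <- frames$nc_area_mm2
  dc <- frames$dc_area_mm2
  ff <- frames$ff_area_mm2
  total <- frames$f_area_mm2 + ff + nc + dc
  r <- ifelse(nc == 0, 0, pmin(nc / pmax(dc, cfg$dc_epsilon_mm2),
                               cfg$nc_dc_ratio_cap))
  nc_frac <- nc / total
  dc_frac <- dc / total
  # lower bound on DC' (=> upper bound on r'):
  #   FcP frames (DC >= 10.5%) must keep DC above the FcP threshold
  dc_lo <- ifelse(nc_frac < 0.10 & dc_frac >= 0.105, 0.108 * total,
                  pmax(nc / cfg$nc_dc_ratio_cap, cfg$dc_epsilon_mm2))
  # upper bound on DC' (=> lower bound on r'):
  #   non-NC-rich, non-FcP frames must stay below the FcP threshold;
  #   F must retain at least 5% of characterized tissue
  dc_hi <- pmin(ifelse(nc_frac < 0.10 & dc_frac < 0.105, 0.090 * total,
                       total), 0.95 * total - nc - ff)
  rlo <- pmin(nc / dc_hi, r)
  rhi <- pmax(pmin(nc / dc_lo, cfg$nc_dc_ratio_cap), r)
  data.frame(r = r, rlo = rlo, rhi = rhi)
}

# shift each frame's NC/DC ratio by dr (scalar or per-frame), within the
# frame's feasible window
adjust_nc_dc <- function(frames, dr, cfg) {
  b <- ratio_bounds(frames, cfg)
  nc <- frames$nc_area_mm2
  ff <- frames$ff_area_mm2
  total <- frames$f_area_mm2 + ff + nc + frames$dc_area_mm2
  r_new <- clamp(b$r + dr, b$rlo, b$rhi)
  dc_new <- ifelse(nc > 0, nc / r_new, frames$dc_area_mm2)
  frames$dc_area_mm2 <- dc_new
  frames$f_area_mm2 <- total - nc - ff - dc_new
  frames
}

# distribute 'need' over components, each clamped to [lo, hi]
waterfill <- function(need, lo, hi) {
  n <- length(lo)
  delta <- numeric(n)
  active <- rep(TRUE, n)
  for (it in 1:20) {
    if (abs(need) < 1e-9 || !any(active)) break
    step <- need / sum(active)
    d2 <- clamp(delta + ifelse(active, step, 0), lo, hi)
    need <- need - sum(d2 - delta)
    delta <- d2
    active <- delta > lo + 1e-12 & delta < hi - 1e-12
  }
  delta
}
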