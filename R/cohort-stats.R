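#' Compare a numeric variable between two groups
#'
#' Two-sided Welch (unequal-variance) t test when the samples can be assumed
#' normal, two-sided Mann-Whitney U (Wilcoxon rank-sum) test otherwise.
#' Normality is a caller decision (recorded in the result); the package's
#' group-stats tables use the t test for means-based variables and
#' Mann-Whitney for skewed deltas.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2).
#' @param normality Logical: assume normality (t test) or not (Mann-Whitney).
#' @param variable Optional variable name carried into the result.
#' @return List of class `vh_group_comparison`: `variable`, `test`
#'   (`"t"` or `"mann_whitney"`), `statistic`, `p`, per-group `n`, `mean`,
#'   `sd`.
#' @export
compare_numeric <- function(group_a, group_b, normality = TRUE,
                            variable = NA_character_) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("compare_numeric() needs n >= 2 per group", call. = FALSE)
  }
  if (normality) {
    ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
    test <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                              correct = TRUE, exact = FALSE))
    test <- "mann_whitney"
  }
  out <- list(variable = variable, test = test,
              statistic = unname(ht$statistic), p = ht$p.value,
              n = c(a = length(group_a), b = length(group_b)),
              mean = c(a = mean(group_a), b = mean(group_b)),
              sd = c(a = sd(group_a), b = sd(group_b)))
  class(out) <- "vh_group_comparison"
  out
}

#' Compare a 2x2 categorical table between groups
#'
#' Two-sided Fisher exact test on a 2x2 contingency table of non-negative
#' integer counts.
#'
#' @param table A 2x2 matrix of counts.
#' @param variable Optional variable name.
#' @return A `vh_group_comparison` list with `test = "fisher"`, `p` and
#'   `odds_ratio`.
#' @export
compare_categorical <- function(table, variable = NA_character_) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  ht <- stats::fisher.test(table)
  out <- list(variable = variable, test = "fisher", statistic = NA_real_,
              p = ht$p.value, odds_ratio = unname(ht$estimate),
              counts = table)
  class(out) <- "vh_group_comparison"
  out
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y Equal-length numeric vectors (n >= 3), neither constant.
#' @param variable Optional variable name.
#' @return List: `variable`, `r`, `p`, `n`.
#' @export
correlate <- function(x, y, variable = NA_character_) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("correlate() needs equal-length vectors with n >= 3", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(variable = variable, r = unname(ht$estimate), p = ht$p.value,
       n = length(x))
}

#' @export
print.vh_group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s test, p = %.4g\n",
              ifelse(is.na(x$variable), "comparison", x$variable),
              x$test, x$p))
  invisible(x)
}

#' Mixed-effect group test on clustered segment deltas
#'
#' Fits `delta ~ group + (1 | patient_id)` — a patient random intercept
#' corrects for the clustering of multiple 5-mm segments within each patient
#' — and reports the fixed group-effect estimate, its standard error and a
#' two-sided p value (Satterthwaite degrees of freedom). A singular fit
#' (random-intercept variance estimated at 0) falls back to the ordinary
#' fixed-effect model and is flagged, never silent.
#'
#' @param data Data frame with columns named by `delta`, `group`,
#'   `patient_id`.
#' @param delta,group,patient_id Column names (strings).
#' @return List of class `vh_mixed_effect`: `estimate`, `se`, `p`,
#'   `random_intercept_var`, `singular` flag, `n_patients`, `n_segments`.
#' @export
mixed_effect_group_test <- function(data, delta = "delta",
                                    group = "group",
                                    patient_id = "patient_id") {
  df <- data.frame(y = data[[delta]],
                   g = factor(data[[group]]),
                   pid = factor(data[[patient_id]]))
  if (nlevels(df$g) != 2) stop("group must have exactly 2 levels", call. = FALSE)
  fit <- tryCatch(
    lmerTest::lmer(y ~ g + (1 | pid), data = df,
                   control = lme4::lmerControl(calc.derivs = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # inestimable random intercept (e.g. one segment per patient):
    # flagged fixed-effect fallback
    singular <- TRUE
    ri_var <- 0
  } else {
    singular <- lme4::isSingular(fit, tol = 1e-5)
    co <- coef(summary(fit))
    vc <- as.data.frame(lme4::VarCorr(fit))
    ri_var <- vc$vcov[vc$grp == "pid"]
  }
  if (singular) {
    lm_fit <- stats::lm(y ~ g, data = df)
    cl <- coef(summary(lm_fit))
    out <- list(estimate = cl[2, 1], se = cl[2, 2], p = cl[2, 4],
                random_intercept_var = 0, singular = TRUE)
  } else {
    out <- list(estimate = co[2, "Estimate"], se = co[2, "Std. Error"],
                p = co[2, "Pr(>|t|)"], random_intercept_var = ri_var,
                singular = FALSE)
  }
  out$n_patients <- nlevels(df$pid)
  out$n_segments <- nrow(df)
  class(out) <- "vh_mixed_effect"
  out
}

#' @export
print.vh_mixed_effect <- function(x, ...) {
  cat(sprintf(
    "Mixed-effect group contrast: estimate %.4g (SE %.4g), p = %.4g%s\n",
    x$estimate, x$se, x$p,
    if (x$singular) " [singular fit; fixed-effect fallback]" else ""))
  cat(sprintf("  patient random-intercept variance %.4g; %d patients, %d segments\n",
              x$random_intercept_var, x$n_patients, x$n_segments))
  invisible(x)
}

#' Group-statistics table over segment pairs
#'
#' Builds the per-variable DM vs non-DM comparison table over the pooled
#' segment-pair rows of a cohort: per-group mean ± SD of baseline,
#' follow-up and delta values for every morphometric and compositional index
#' plus LAPS, with the between-group p value (plain two-sample test and,
#' for deltas, the patient-clustered mixed-effect p side by side) and
#' within-group baseline-vs-follow-up p values.
#'
#' @param segments Data frame of pooled segment-pair rows with `group` and
#'   `patient_id` columns (see [analyze_cohort()]).
#' @param variables Character vector of base variable names (without the
#'   `_bl`/`_fu`/`delta_` affixes). Default: the reported index families.
#' @param normality Logical, passed to [compare_numeric()].
#' @param bh_adjust If `TRUE`, append Benjamini-Hochberg adjusted
#'   between-group p values (off by default; the primary tables are
#'   unadjusted).
#' @return Data frame, one row per variable and timepoint/delta family.
#' @export
group_stats_table <- function(segments,
                              variables = c("mean_lumen_csa_mm2",
                                            "mean_eem_csa_mm2",
                                            "mean_plaque_csa_mm2",
                                            "pav_pct",
                                            "mean_f_frac", "mean_ff_frac",
                                            "mean_nc_frac", "mean_dc_frac",
                                            "mean_f_area_mm2",
                                            "mean_ff_area_mm2",
                                            "mean_nc_area_mm2",
                                            "mean_dc_area_mm2",
                                            "mean_nc_lumen_arc_deg",
                                            "laps"),
                              normality = TRUE, bh_adjust = FALSE) {
  a <- segments[segments$group == "DM", ]
  b <- segments[segments$group == "non_DM", ]
  rows <- list()
  for (v in variables) {
    for (tp in c("bl", "fu", "delta")) {
      col <- if (tp == "delta") paste0("delta_", v) else paste0(v, "_", tp)
      if (!col %in% names(segments)) next
      cmp <- compare_numeric(a[[col]], b[[col]], normality = normality,
                             variable = col)
      p_mixed <- if (tp == "delta") {
        tryCatch(mixed_effect_group_test(segments, delta = col)$p,
                 error = function(e) NA_real_)
      } else NA_real_
      within_p <- function(g) {
        if (tp != "delta") return(NA_real_)
        stats::t.test(g[[col]])$p.value  # paired BL vs FU == one-sample on delta
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, quantity = tp, test = cmp$test,
        dm_n = cmp$n[["a"]], dm_mean = cmp$mean[["a"]], dm_sd = cmp$sd[["a"]],
        nondm_n = cmp$n[["b"]], nondm_mean = cmp$mean[["b"]],
        nondm_sd = cmp$sd[["b"]],
        p = cmp$p, p_mixed = p_mixed,
        dm_within_p = within_p(a), nondm_within_p = within_p(b)
      )
    }
  }
  out <- do.call(rbind, rows)
  if (bh_adjust) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
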