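#' Phenotype transition matrix
#'
#' Cross-tabulates baseline versus follow-up segment phenotype labels over a
#' set of registered segment pairs, in the fixed severity order NL, PIT, FP,
#' FcP, ThCFA, TCFA, together with row-normalized transition proportions
#' (rows of all-zero counts stay zero).
#'
#' @param baseline,follow_up Phenotype labels of the segment pairs (character
#'   or factor), or a `vh_segment_pairs` data frame as the first argument.
#' @return List of class `vh_transition_matrix` with `counts` and
#'   `proportions` (6 x 6 matrices, baseline in rows) and `n`.
#' @export
transition_matrix <- function(baseline, follow_up = NULL) {
  if (is.data.frame(baseline)) {
    follow_up <- baseline$phenotype_fu
    baseline <- baseline$phenotype_bl
  }
  stopifnot(length(baseline) == length(follow_up))
  if (length(baseline) == 0) stop("transition_matrix() needs >= 1 pair",
                                  call. = FALSE)
  bl <- as_phenotype(baseline)
  fu <- as_phenotype(follow_up)
  counts <- table(baseline = bl, follow_up = fu)
  counts <- unclass(counts)[phenotype_levels, phenotype_levels]
  rs <- rowSums(counts)
  prop <- counts / ifelse(rs > 0, rs, 1)
  out <- list(counts = counts, proportions = prop, n = length(bl))
  class(out) <- "vh_transition_matrix"
  out
}

#' @export
print.vh_transition_matrix <- function(x, ...) {
  cat(sprintf("Phenotype transitions over %d segment pairs (baseline rows):\n",
              x$n))
  print(x$counts)
  invisible(x)
}

#' Classify TCFA fates over segment pairs
#'
#' Each registered segment pair gets one of four mutually exclusive fates:
#' `persistent` (TCFA at both timepoints), `healed` (baseline TCFA changing
#' into another phenotype), `new` (another baseline phenotype becoming TCFA
#' at follow-up), `never` (TCFA at neither). Rates are reported under both
#' denominator conventions; the primary convention divides new TCFAs by the
#' baseline non-TCFA count and persistent TCFAs by the baseline TCFA count.
#'
#' @inheritParams transition_matrix
#' @return List of class `vh_tcfa_fates`: `fate` (factor per pair), `counts`,
#'   and `rates` with `persistent_rate` (= persistent / baseline TCFA),
#'   `new_rate` (= new / baseline non-TCFA, primary) and
#'   `new_rate_all_segments` (= new / all segments, secondary).
#' @export
classify_tcfa_fates <- function(baseline, follow_up = NULL) {
  if (is.data.frame(baseline)) {
    follow_up <- baseline$phenotype_fu
    baseline <- baseline$phenotype_bl
  }
  bl <- as.character(as_phenotype(baseline))
  fu <- as.character(as_phenotype(follow_up))
  fate <- ifelse(bl == "TCFA" & fu == "TCFA", "persistent",
          ifelse(bl == "TCFA", "healed",
          ifelse(fu == "TCFA", "new", "never")))
  fate <- factor(fate, levels = c("persistent", "healed", "new", "never"))
  counts <- table(fate)
  n_bl_tcfa <- sum(bl == "TCFA")
  n_bl_other <- sum(bl != "TCFA")
  rates <- list(
    persistent_rate = if (n_bl_tcfa > 0) counts[["persistent"]] / n_bl_tcfa else NA_real_,
    healed_rate = if (n_bl_tcfa > 0) counts[["healed"]] / n_bl_tcfa else NA_real_,
    new_rate = if (n_bl_other > 0) counts[["new"]] / n_bl_other else NA_real_,
    new_rate_all_segments = counts[["new"]] / length(bl)
  )
  out <- list(fate = fate, counts = counts, rates = rates,
              n_baseline_tcfa = n_bl_tcfa, n_baseline_other = n_bl_other)
  class(out) <- "vh_tcfa_fates"
  out
}

#' @export
print.vh_tcfa_fates <- function(x, ...) {
  cat("TCFA fates:\n")
  print(x$counts)
  cat(sprintf("  persistent rate %.1f%% (of %d baseline TCFA), new rate %.1f%% (of %d baseline non-TCFA)\n",
              100 * x$rates$persistent_rate, x$n_baseline_tcfa,
              100 * x$rates$new_rate, x$n_baseline_other))
  invisible(x)
}

#' Share of segments carrying a phenotype
#'
#' Count and percentage (to one decimal, conventional half-up rounding) of
#' segments labeled with a given phenotype at one timepoint.
#'
#' @param labels Phenotype labels at the timepoint of interest, or a
#'   `vh_segment_pairs` data frame (then use `timepoint`).
#' @param label Phenotype of interest, e.g. `"TCFA"`.
#' @param timepoint `"baseline"` or `"follow_up"` when `labels` is a segment
#'   table.
#' @return List: `count`, `total`, `proportion`, `percent` (1 decimal).
#' @export
#' @examples
#' group_phenotype_share(rep(c("TCFA", "PIT"), c(228, 278)), "TCFA")$percent
group_phenotype_share <- function(labels, label,
                                  timepoint = c("baseline", "follow_up")) {
  if (is.data.frame(labels)) {
    timepoint <- match.arg(timepoint)
    labels <- if (timepoint == "baseline") labels$phenotype_bl else
      labels$phenotype_fu
  }
  labels <- as.character(as_phenotype(labels))
  if (length(labels) == 0) stop("no segments", call. = FALSE)
  count <- sum(labels == label)
  prop <- count / length(labels)
  # round half away from zero at 1 decimal (not banker's rounding)
  pct <- floor(1000 * prop + 0.5) / 10
  list(count = count, total = length(labels), proportion = prop,
       percent = pct)
}
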