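test_that("numeric group comparisons dispatch t or Mann-Whitney as asked", {
  a <- c(1.2, 0.8, 1.1, 0.9)
  same <- compare_numeric(a, a, normality = FALSE)
  expect_equal(same$test, "mann_whitney")
  expect_equal(same$p, 1)
  tt <- compare_numeric(a, a, normality = TRUE)
  expect_equal(tt$test, "t")
  expect_equal(tt$statistic, 0)
  sep <- compare_numeric(rep(0, 4), rep(10, 4), normality = FALSE)
  expect_lt(sep$p, 0.05)
  expect_error(compare_numeric(1, a), "n >= 2")
  expect_equal(unname(compare_numeric(a, a + 1)$mean), c(mean(a), mean(a) + 1))
})

test_that("Fisher's exact p matches direct hypergeometric enumeration", {
  expect_equal(compare_categorical(matrix(c(5, 5, 5, 5), 2))$p, 1)
  # oracle: enumerate all tables with the margins of [[10,0],[0,10]] and sum
  # the probabilities of those at most as likely as the observed table
  m <- matrix(c(10, 0, 0, 10), 2)
  x <- 0:10
  probs <- dhyper(x, 10, 10, 10)
  p_oracle <- sum(probs[probs <= dhyper(10, 10, 10, 10) * (1 + 1e-7)])
  expect_equal(compare_categorical(m)$p, p_oracle, tolerance = 1e-9)
  expect_equal(p_oracle, 2 * choose(10, 10) * choose(10, 0) / choose(20, 10),
               tolerance = 1e-12)  # ~1.08e-5
  # degenerate margin
  expect_equal(compare_categorical(matrix(c(0, 0, 3, 7), 2, byrow = TRUE))$p, 1)
  expect_error(compare_categorical(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("Fisher p is invariant to transpose and row/column swaps", {
  set.seed(5)
  for (rep in 1:10) {
    m <- matrix(rpois(4, 8), 2)
    p <- compare_categorical(m)$p
    expect_equal(compare_categorical(t(m))$p, p)
    expect_equal(compare_categorical(m[2:1, ])$p, p)
    expect_equal(compare_categorical(m[, 2:1])$p, p)
  }
})

test_that("correlation handles exact linear and degenerate inputs", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(correlate(x, 2 * x + 1)$r, 1)
  expect_equal(correlate(x, -x)$r, -1)
  expect_error(correlate(x, rep(2, 5)), "constant")
  expect_error(correlate(x, 1:3), "equal-length")
})

test_that("the generator's LDLc coupling yields the configured correlation", {
  # non-DM patients: configured r = 0.47 between LDLc change and the
  # patient-mean plaque-area change; check within 2 SE on the Fisher-z scale
  res <- canonical_analysis()
  coh <- canonical_cohort()
  nd <- res$patients[res$patients$group == "non_DM", ]
  ldl <- vapply(coh[nd$patient_id], function(s)
    s$covariates$ldl_change_mmol_l, numeric(1))
  ct <- correlate(ldl, nd$mean_delta_plaque_mm2)
  z <- atanh(ct$r); z0 <- atanh(0.47)
  expect_lt(abs(z - z0), 2 / sqrt(ct$n - 3))
})

test_that("the mixed model collapses to the plain comparison for single-segment patients", {
  set.seed(31)
  df <- data.frame(delta = rnorm(30), patient_id = sprintf("P%02d", 1:30),
                   group = rep(c("DM", "non_DM"), 15))
  me <- suppressMessages(mixed_effect_group_test(df))
  expect_true(me$singular)
  expect_equal(me$random_intercept_var, 0)
  lm_fit <- lm(delta ~ group, df)
  expect_equal(me$estimate, unname(coef(lm_fit)[2]), tolerance = 1e-6)
  expect_equal(me$p, summary(lm_fit)$coefficients[2, 4], tolerance = 1e-6)
})

test_that("clustering correction is anti-anticonservative on clustered data", {
  set.seed(41)
  hits <- 0
  for (rep in 1:5) {
    n_pat <- 12; n_seg <- 15
    pid <- rep(sprintf("P%02d", 1:n_pat), each = n_seg)
    grp <- rep(rep(c("DM", "non_DM"), n_pat / 2), each = n_seg)
    u <- rep(rnorm(n_pat, 0, 2), each = n_seg)   # strong patient clustering
    df <- data.frame(delta = u + rnorm(n_pat * n_seg, 0, 0.5),
                     patient_id = pid, group = grp)
    me <- mixed_effect_group_test(df)
    naive <- compare_numeric(df$delta[df$group == "DM"],
                             df$delta[df$group == "non_DM"])
    expect_gt(me$random_intercept_var, 0)
    if (me$p >= naive$p) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("the group-stats table covers every reported index family", {
  res <- canonical_analysis()
  gs <- res$group_stats
  need <- c("mean_lumen_csa_mm2", "mean_eem_csa_mm2", "mean_plaque_csa_mm2",
            "pav_pct", "mean_f_frac", "mean_ff_frac", "mean_nc_frac",
            "mean_dc_frac", "mean_f_area_mm2", "mean_ff_area_mm2",
            "mean_nc_area_mm2", "mean_dc_area_mm2", "mean_nc_lumen_arc_deg",
            "laps")
  expect_setequal(intersect(unique(gs$variable), need), need)
  expect_true(all(gs$quantity %in% c("bl", "fu", "delta")))
  expect_true(all(gs$p >= 0 & gs$p <= 1))
  expect_true(all(is.finite(gs$p_mixed[gs$quantity == "delta"])))
})
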