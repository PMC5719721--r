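# Default calibration of the synthetic IVUS-VH cohort generator.
# Group-level quantities are given for the diabetic (DM) and non-diabetic
# (non_DM) study arms; units are stated per field.
n_dm: 17            # patients in the DM arm
n_nondm: 44         # patients in the non-DM arm
frame_spacing_mm: 0.5      # gated VH frame spacing along the pullback (mm)
min_length_mm: 30.0        # inclusion minimum for pullback length (mm)
max_length_mm: 120.0       # clamp on drawn vessel length (mm)
characterized_frac: 0.92   # VH-characterized share of plaque CSA
patient_intercept_frac: 0.15 # share of per-segment delta variance that is
                             # between-patient (random intercept)
stretch_max: 0.10          # max relative pullback stretch between timepoints
vessel_length_mm:          # analyzed vessel length, Normal(mean, sd) per group
  DM:     {mean: 70.5, sd: 15.8}
  non_DM: {mean: 72.9, sd: 18.6}
eem_mean_mm2:              # patient-level mean EEM CSA (mm^2)
  DM: 15.79
  non_DM: 16.66
eem_sd_patient_mm2: 4.0    # between-patient SD of mean EEM CSA (mm^2)
eem_sd_segment_rel: 0.06   # relative between-segment EEM variation (AR(1))
delta_plaque_area_mm2:     # per-segment 1-year change of mean plaque CSA
  DM:     {mean: 0.21, sd: 0.97}
  non_DM: {mean: -0.47, sd: 1.15}
delta_pav_pct:             # per-segment 1-year change of PAV (percent points)
  DM:     {mean: 0.7, sd: 2.8}
  non_DM: {mean: -1.4, sd: 2.5}
delta_pullback_laps:       # per-patient 1-year change of pullback LAPS
  DM:     {mean: 0.13, sd: 1.79}
  non_DM: {mean: -0.23, sd: 1.66}
fates:                     # TCFA fate probabilities per segment pair
  new_tcfa:        {DM: 0.203, non_DM: 0.126}   # per baseline non-TCFA segment
  persistent_tcfa: {DM: 0.821, non_DM: 0.713}   # per baseline TCFA segment
baseline_mix:              # baseline segment phenotype mixture per group
  DM:     {NL: 0.08, PIT: 0.15, FP: 0.10, FcP: 0.05, ThCFA: 0.131, TCFA: 0.489}
  non_DM: {NL: 0.08, PIT: 0.15, FP: 0.10, FcP: 0.05, ThCFA: 0.169, TCFA: 0.451}
covariates:
  ldl_baseline_mmol_l:     # LDL cholesterol at baseline, Normal(mean, sd)
    DM:     {mean: 2.42, sd: 0.53}
    non_DM: {mean: 2.46, sd: 1.04}
  ldl_change_mmol_l:       # 1-year LDLc change
    DM:     {mean: -0.3, sd: 0.52}
    non_DM: {mean: -0.66, sd: 1.09}
  ldl_plaque_corr:         # correlation of LDLc change with patient-mean
    DM: 0.0                # plaque-area change
    non_DM: 0.47
  glycemia_baseline_mmol_l:
    DM:     {mean: 7.04, sd: 2.41}
    non_DM: {mean: 5.59, sd: 0.78}
  hscrp_baseline_mg_l:
    DM:     {mean: 2.28, sd: 2.53}
    non_DM: {mean: 3.14, sd: 4.31}
seed: 1
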