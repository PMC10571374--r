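#!/usr/bin/env Rscript
# Step 1: simulate the two hospital-like cohorts.
#
# The training-like cohort mirrors the development hospital: 180 patients,
# 47% PDAC, CR-POPF prevalence ~33%, with the planted per-stratum risk
# structure (low MPD index in PDAC; low MPD index / high BMI in non-PDAC).
# The validation-like cohort mirrors the second hospital: 366 patients,
# 37% PDAC, prevalence ~36% implied by the same risk structure.

suppressPackageStartupMessages(library(popfrisk))
dir.create("results", showWarnings = FALSE)

training <- generate_cohort(cohort_config(n = 180), seed = 101)
validation <- generate_cohort(
  cohort_config(n = 366, pdac_fraction = 137 / 366), seed = 202)

write_cohort_csv(training, "results/cohort_training.csv")
write_cohort_csv(validation, "results/cohort_validation.csv")

summarise <- function(cohort, label) {
  parts <- stratify_by_diagnosis(cohort)
  cat(sprintf(
    "%s: n = %d | PDAC %d / non-PDAC %d | CR-POPF %d (%.0f%%)\n",
    label, nrow(cohort), nrow(parts$PDAC), nrow(parts$`non-PDAC`),
    sum(cohort$cr_popf), 100 * mean(cohort$cr_popf)))
  cat(sprintf(
    "  medians: BMI %.1f, MPD index %.2f, thickness %.1f mm, PNI %.1f\n",
    stats::median(cohort$bmi), stats::median(cohort$mpd_index),
    stats::median(cohort$parenchymal_thickness),
    stats::median(cohort$pni)))
}
summarise(training, "training")
summarise(validation, "validation")
cat("cohorts written to results/cohort_{training,validation}.csv\n")
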