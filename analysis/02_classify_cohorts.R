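#!/usr/bin/env Rscript
# Classify the simulated cohorts (01) into tethering / rolling / adhesion /
# free, summarize each condition by the assay's percentage formula, and
# compare conditions: chi-square on adhesion and tethering counts,
# one-tailed t on rolling velocities, median fold change.

suppressMessages(library(rollflow))

traj <- read_trajectories("results/cohort_trajectories.csv")
fc <- flow_context(shear_dyn_cm2 = 0.05)
params <- classification_params()

summaries <- NULL; vels <- list()
for (cond in unique(traj$condition)) {
  cl <- classify_cohort(traj[traj$condition == cond, ], fc, params)
  summaries <- rbind(summaries, summarize_cohort(cl, cond, 0.05))
  vels[[cond]] <- rolling_velocities(cl)
}
write_summary(summaries, "results/cohort_summaries.csv")
print(summaries)

cmp <- compare_cohorts(summaries[summaries$condition == "adhesive", ],
                       summaries[summaries$condition == "weak", ],
                       vels[["adhesive"]], vels[["weak"]],
                       velocity_direction = "b_greater")
write_summary(cmp, "results/cohort_comparisons.csv")
print(cmp)

if (length(vels[["adhesive"]]) && length(vels[["weak"]])) {
  mfc <- median_fold_change(vels[["weak"]], vels[["adhesive"]])
  cat(sprintf(
    "median rolling-velocity change, weak relative to adhesive: %+.1f%%\n",
    mfc$percent_change))
}
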