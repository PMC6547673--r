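#!/usr/bin/env Rscript
# Simulate the two perfusion cohorts at the capture-optimal shear
# (0.05 dyn cm-2): an adhesive condition with the default catch-slip
# kinetics and a weakly adhesive condition (halved bond-formation and
# arrest rates). Writes the pooled labeled trajectory table plus per-track
# ground truth under results/.

suppressMessages(library(rollflow))

seed <- 20260926L
dir.create("results", showWarnings = FALSE)

fc <- flow_context(shear_dyn_cm2 = 0.05)
cfg_a <- simulation_config(flow = fc, bond = bond_model(),
                           n_arrivals = 100, n_fields = 3, seed = seed,
                           condition = "adhesive")
cfg_b <- simulation_config(flow = fc,
                           bond = bond_model(k_on = 0.03, k_arrest = 0.06),
                           n_arrivals = 100, n_fields = 3,
                           seed = seed + 1L, condition = "weak")
coh <- generate_two_condition_cohort(cfg_a, cfg_b)

write_trajectories(coh$trajectories, "results/cohort_trajectories.csv",
                   seed = seed, config = cfg_a)
write_summary(coh$classes, "results/cohort_truth_classes.csv", seed = seed)

cat(sprintf("simulated %d spheroids (%d rows) across two conditions\n",
            nrow(coh$classes), nrow(coh$trajectories)))
print(table(coh$classes$condition, coh$classes$true_class))
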