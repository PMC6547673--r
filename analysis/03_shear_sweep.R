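#!/usr/bin/env Rscript
# Sweep wall shear stress over the ascitic range 0.03-0.15 dyn cm-2 for
# both conditions: the catch-slip kinetics produce a capture optimum at
# 0.05 dyn cm-2 (threshold shear below, slip-dominated rupture and shorter
# field residence above). Writes the per-shear summary table, per-shear
# condition comparisons, a markdown report and a figure.

suppressMessages(library(rollflow))

seed <- 20260927L
dir.create("results", showWarnings = FALSE)

fc <- flow_context(shear_dyn_cm2 = 0.05)
cfg_a <- simulation_config(flow = fc, bond = bond_model(),
                           n_arrivals = 300, n_fields = 2, seed = seed,
                           condition = "adhesive")
cfg_b <- simulation_config(flow = fc,
                           bond = bond_model(k_on = 0.03, k_arrest = 0.06),
                           n_arrivals = 300, n_fields = 2,
                           seed = seed + 1L, condition = "weak")
sweep <- run_shear_sweep(cfg_a, cfg_b)

write_summary(sweep$summaries, "results/sweep_summaries.csv", seed = seed)
write_summary(sweep$stats, "results/sweep_stats.csv", seed = seed)
sweep_report_md(sweep, "results/sweep_report.md")

cat(sprintf("adhesion is maximal at %.2f dyn cm-2 for the adhesive cohort\n",
            optimal_shear(sweep, "adhesive")))
print(sweep$summaries[, c("condition", "shear_dyn_cm2", "n_total",
                          "pct_tether", "pct_adhesion")])

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(sweep$summaries,
              aes(shear_dyn_cm2, pct_adhesion, colour = condition)) +
    geom_line() + geom_point() +
    labs(x = "wall shear stress (dyn/cm2)",
         y = "% adhesion", colour = NULL) +
    theme_classic()
  ggsave("results/sweep_adhesion.pdf", p, width = 5, height = 3.5)
}
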