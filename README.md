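# rollflow

Rolling-adhesion analysis of tumor spheroids under microfluidic shear.

Ovarian cancer spreads through the peritoneal cavity: cancer-stem-cell
spheroids (70–100 µm) carried by ascitic flow must tether, roll and firmly
adhere to the mesothelial lining before invading it. The assay this package
implements perfuses fluorescently labeled spheroids over a
mesothelial-coated parallel-plate microchannel at ascitic wall shear stress
(0.03–0.15 dyn cm⁻²), images each field at 1 frame s⁻¹ for 30 s, and
classifies every transiting spheroid as **tethering** (transient capture and
release), **rolling** (sustained translation below the hydrodynamic velocity
over more than one spheroid diameter), **adhesion** (stationary through the
end of recording) or free. Cohorts are compared with chi-square tests on the
class counts and one-tailed Student t tests on rolling velocities.

The package is aimed at people analyzing (or simulating) low-shear
cell–surface adhesion assays: it provides

- **Hydrodynamics** — plane-Poiseuille wall shear stress
  `τ = 6μQ/(wh²)` with exact inversion, and the near-wall spheroid
  transport velocity `u_h = k_wall·(τ/μ)·d/2` used as the rolling
  reference (`flow_context()`, `hydrodynamic_velocity()`);
- **A synthetic cohort generator** — a discrete-time Markov chain over
  free/tethered/rolling/adherent with a two-pathway catch–slip off-rate
  `k_off(τ) = a·e^(−τ/f_c) + b·e^(τ/f_s)`, which reproduces the assay's
  catch-bond signature: capture peaks at 0.05 dyn cm⁻² inside the ascitic
  sweep (`simulate_trajectories()`, `bond_model()`), plus rendered 16-bit
  time-lapse TIFF stacks (`render_image_stack()`);
- **Detection and tracking** — background subtraction, Otsu + watershed
  segmentation, the 70–100 µm size gate, and flow-aware greedy linking
  (`detect_stack()`, `link_tracks()`);
- **Motion classification and statistics** — the four-way classifier with
  cohort percentages by the assay's formula, detachment-ramp survival
  curves, chi-square / one-tailed t / median fold changes
  (`classify_cohort()`, `summarize_cohort()`, `run_detachment()`,
  `chi_square_test()`).

All bond-kinetic rate defaults are calibration artifacts of this package
(no rates are available for the real system); see the methods vignette
(`vignettes/rolling-adhesion-methods.Rmd`).

## Worked example

Sweep both simulated conditions across the ascitic shear range and compare
them (this is `analysis/03_shear_sweep.R`):

```r
library(rollflow)
fc <- flow_context(shear_dyn_cm2 = 0.05)
cfg_a <- simulation_config(flow = fc, bond = bond_model(),
                           n_arrivals = 300, n_fields = 2,
                           seed = 20260927, condition = "adhesive")
cfg_b <- simulation_config(flow = fc,
                           bond = bond_model(k_on = 0.03, k_arrest = 0.06),
                           n_arrivals = 300, n_fields = 2,
                           seed = 20260928, condition = "weak")
sweep <- run_shear_sweep(cfg_a, cfg_b)
optimal_shear(sweep, "adhesive")
sweep$summaries[, c("condition", "shear_dyn_cm2", "n_total",
                    "pct_tether", "pct_adhesion")]
```

```
[1] 0.05
   condition shear_dyn_cm2 n_total pct_tether pct_adhesion
1   adhesive          0.03     600   43.33333     7.500000
2       weak          0.03     600   28.83333     2.833333
3   adhesive          0.04     600   33.33333    16.666667
4       weak          0.04     600   26.66667     7.500000
5   adhesive          0.05     600   24.33333    23.166667
6       weak          0.05     600   22.16667     9.166667
7   adhesive          0.07     600   26.50000    15.833333
8       weak          0.07     600   17.16667     8.333333
9   adhesive          0.10     600   25.50000    10.166667
10      weak          0.10     600   17.83333     3.500000
11  adhesive          0.15     600   23.66667     7.166667
12      weak          0.15     600   13.66667     2.166667
```

Adhesion peaks at 0.05 dyn cm⁻² for both cohorts — the catch-bond
optimum — and the adhesive condition adheres ~2.5-fold more there
(23.2% vs 9.2% of the 600 spheroids that transited each cohort's fields);
`sweep$stats` holds the per-shear chi-square comparisons. The numbered
scripts under `analysis/` run the full set of experiments (cohort
simulation, classification and comparison, shear sweep, image-based
re-extraction, detachment ramps) and write their tables under `results/`.

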