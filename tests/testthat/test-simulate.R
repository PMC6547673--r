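test_that("catch-slip off-rate is positive with a single interior minimum", {
  bm <- bond_model()
  tau <- seq(0, 0.5, by = 0.005)
  k <- bond_off_rate(bm, tau)
  expect_true(all(k > 0))
  i <- which.min(k)
  expect_gt(i, 1)
  expect_lt(i, length(tau))
  # decreasing before, increasing after the minimum (catch then slip)
  expect_true(all(diff(k[1:i]) < 0))
  expect_true(all(diff(k[i:length(k)]) > 0))
})

test_that("simulation is reproducible from its seed and respects k_on = 0", {
  fc <- default_flow_005()
  cfg <- simulation_config(flow = fc, n_arrivals = 30, n_fields = 2,
                           seed = 42)
  s1 <- simulate_trajectories(cfg)
  s2 <- simulate_trajectories(cfg)
  expect_identical(s1$trajectories, s2$trajectories)
  expect_identical(s1$truth, s2$truth)
  # no bond formation -> every spheroid stays free
  cfg0 <- simulation_config(flow = fc, bond = bond_model(k_on = 0),
                            n_arrivals = 50, n_fields = 2, seed = 7)
  s0 <- simulate_trajectories(cfg0)
  expect_true(all(s0$truth$latent_state == "free"))
  expect_true(all(s0$classes$true_class == "free"))
  cl <- classify_cohort(s0$trajectories, fc)
  sm <- summarize_cohort(cl, "x", 0.05)
  expect_equal(sm$pct_tether, 0)
  expect_equal(sm$pct_adhesion, 0)
})

test_that("state transitions match the chain's analytic per-step rates", {
  # chi-square goodness of fit of observed one-step transitions from the
  # tethered state against the competing-risk probabilities
  fc <- default_flow_005()
  bm <- bond_model()
  cfg <- simulation_config(flow = fc, bond = bm, n_arrivals = 600,
                           n_fields = 3, seed = 314)
  sim <- simulate_trajectories(cfg)
  tru <- sim$truth[order(sim$truth$track_id, sim$truth$frame), ]
  from <- tru$latent_state[-nrow(tru)]
  to <- tru$latent_state[-1]
  same <- tru$track_id[-nrow(tru)] == tru$track_id[-1]
  from <- from[same]; to <- to[same]
  obs <- table(factor(to[from == "tethered"],
                      levels = c("free", "tethered", "rolling", "adherent")))
  tau <- fc$shear_dyn_cm2
  rates <- c(free = bm$release_to_free_rate + bond_off_rate(bm, tau),
             rolling = bm$k_on, adherent = bm$k_arrest)
  total <- sum(rates)
  p_leave <- 1 - exp(-total)
  p <- c(free = unname(p_leave * rates["free"] / total),
         tethered = 1 - p_leave,
         rolling = unname(p_leave * rates["rolling"] / total),
         adherent = unname(p_leave * rates["adherent"] / total))
  expect_gt(sum(obs), 500)
  gof <- stats::chisq.test(obs, p = p[names(obs)])
  expect_gt(gof$p.value, 0.01)
})

test_that("track-level ground truth follows the observational definitions", {
  # ends arrested -> adhesion
  expect_equal(truth_track_class(c("free", "tethered", "adherent",
                                   "adherent"),
                                 c(130, 0, 0, 0), 85), "adhesion")
  # rolling run longer than a diameter -> rolling
  expect_equal(truth_track_class(c("free", rep("rolling", 4), "free"),
                                 c(130, 30, 30, 30, 30, 130), 85),
               "rolling")
  # short tether then release -> tethering
  expect_equal(truth_track_class(c("free", "tethered", "free", "free"),
                                 c(130, 0, 130, 130), 85), "tethering")
  # short rolling run then release is tethering, not rolling
  expect_equal(truth_track_class(c("free", "rolling", "free", "free"),
                                 c(130, 30, 130, 130), 85), "tethering")
  # never interacts -> free
  expect_equal(truth_track_class(rep("free", 5), rep(130, 5), 85), "free")
})

test_that("scripted cohorts hit their generative class probabilities", {
  fc <- default_flow_005()
  probs <- c(tethering = 0.2, rolling = 0.15, adhesion = 0.4, free = 0.25)
  sim <- simulate_cohort_from_probs(400, probs, fc, seed = 99)
  tab <- table(sim$classes$true_class)
  for (cls in names(probs)) {
    ci <- stats::binom.test(tab[[cls]], 400)$conf.int
    expect_true(probs[[cls]] >= ci[1] && probs[[cls]] <= ci[2],
                label = sprintf("%s generative prob inside exact CI", cls))
  }
  # determinism
  sim2 <- simulate_cohort_from_probs(400, probs, fc, seed = 99)
  expect_identical(sim$trajectories, sim2$trajectories)
})

test_that("capture increases with bond formation rate", {
  fc <- default_flow_005()
  strong <- simulation_config(flow = fc, bond = bond_model(k_on = 0.08),
                              n_arrivals = 250, n_fields = 2, seed = 5,
                              condition = "strong")
  weak <- simulation_config(flow = fc, bond = bond_model(k_on = 0.02),
                            n_arrivals = 250, n_fields = 2, seed = 6,
                            condition = "weak")
  coh <- generate_two_condition_cohort(strong, weak)
  tab <- table(coh$classes$condition,
               coh$classes$true_class != "free")
  p_strong <- tab["strong", "TRUE"] / sum(tab["strong", ])
  p_weak <- tab["weak", "TRUE"] / sum(tab["weak", ])
  expect_gt(p_strong, p_weak)
})

test_that("two-condition pooling validates labels and flow equality", {
  fc <- default_flow_005()
  a <- simulation_config(flow = fc, n_arrivals = 5, seed = 1,
                         condition = "A")
  b_other_flow <- simulation_config(flow = flow_context(shear_dyn_cm2 = 0.1),
                                    n_arrivals = 5, seed = 2,
                                    condition = "B")
  expect_error(generate_two_condition_cohort(a, b_other_flow),
               "flow context")
  expect_error(generate_two_condition_cohort(a, a), "distinct")
})

test_that("detachment survival is monotone, complete by ramp end, and
           trivially full when rupture is impossible", {
  fc <- default_flow_005()
  cfg <- simulation_config(flow = fc, seed = 11)
  ramp <- make_shear_ramp(0.5, 4, 8, 30)
  det <- simulate_detachment(cfg, ramp, 40)
  expect_true(all(diff(det$survival$fraction_remaining) <= 0))
  expect_equal(det$survival$fraction_remaining[8], 0)
  # EDTA collapses survival at or before 1 dyn/cm2
  cfg_edta <- simulation_config(flow = fc, seed = 11, edta = TRUE)
  ramp1 <- make_shear_ramp(0.25, 1, 4, 30)
  det_e <- simulate_detachment(cfg_edta, ramp1, 40)
  expect_equal(det_e$survival$fraction_remaining[
    det_e$survival$tau_dyn_cm2 >= 1], 0)
  # indestructible firm bonds survive every step
  cfg0 <- simulation_config(flow = fc,
                            bond = bond_model(firm_slip_amplitude = 0),
                            seed = 3)
  det0 <- simulate_detachment(cfg0, ramp, 25)
  expect_true(all(det0$survival$fraction_remaining == 1))
  expect_error(simulate_detachment(cfg, ramp, 0), "n_adherent")
})
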