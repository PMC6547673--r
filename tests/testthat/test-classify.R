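test_that("frame velocities are gap-aware and flag single detections", {
  tr <- track_from_speeds(c(134, 134))
  v <- frame_velocities(tr)
  expect_equal(v$speed_um_s, c(134, 134))
  # positions 0, 134, 268 at 1 s spacing
  tr2 <- data.frame(frame = c(0, 1, 2), x_um = c(0, 134, 268), y_um = 0,
                    diameter_um = 85)
  expect_equal(frame_velocities(tr2)$speed_um_s, c(134, 134))
  # a frame gap 3 -> 5 uses 2 s elapsed
  tr3 <- data.frame(frame = c(3, 5), x_um = c(0, 100), y_um = 0,
                    diameter_um = 85)
  v3 <- frame_velocities(tr3)
  expect_equal(v3$elapsed_s, 2)
  expect_equal(v3$speed_um_s, 50)
  v1 <- frame_velocities(data.frame(frame = 0, x_um = 0, y_um = 0,
                                    diameter_um = 85))
  expect_equal(nrow(v1), 0)
  expect_true(attr(v1, "single_frame"))
})

test_that("reference velocity: analytic value and empirical robustness", {
  fc <- default_flow_005()
  # analytic at the median diameter reproduces the hand value
  traj <- do.call(rbind, lapply(1:6, function(i) {
    tr <- track_from_speeds(rep(134, 8), diameter_um = 85, track_id = i)
    tr$condition <- "A"; tr$field_id <- 1L; tr
  }))
  ref_a <- reference_velocity(traj, fc, classification_params("analytic"))
  expect_equal(ref_a$u_ref_um_s, 134.0, tolerance = 1e-3)
  # all tracks exactly at u_h -> empirical percentile equals u_h
  ref_e <- reference_velocity(traj, NULL, classification_params("empirical"))
  expect_equal(ref_e$u_ref_um_s, 134)
  # adding one stationary track leaves the upper percentile unchanged
  stat_tr <- track_from_speeds(rep(0, 8), track_id = 99L)
  stat_tr$condition <- "A"; stat_tr$field_id <- 1L
  ref_e2 <- reference_velocity(rbind(traj, stat_tr), NULL,
                               classification_params("empirical"))
  expect_equal(ref_e2$u_ref_um_s, 134)
  # < 5 tracks falls back to analytic with a warning
  expect_warning(
    ref_f <- reference_velocity(traj[traj$track_id <= 2, ], fc,
                                classification_params("empirical")),
    "fewer than 5")
  expect_equal(ref_f$mode, "analytic")
})

test_that("classify_track reproduces the worked speed-pattern examples", {
  # stationary for the whole recording -> adhesion
  expect_equal(classify_track(track_from_speeds(rep(0, 29)), 134)$class,
               "adhesion")
  # constant transport at u_ref -> free
  expect_equal(classify_track(track_from_speeds(rep(134, 10)), 134)$class,
               "free")
  # sustained slow segment over > 1 diameter -> rolling at 20 um/s
  ct <- classify_track(track_from_speeds(c(134, rep(20, 6), 134)), 134)
  expect_equal(ct$class, "rolling")
  expect_equal(ct$rolling_velocity_um_s, 20)
  # one short slow interval then release -> tethering
  expect_equal(classify_track(track_from_speeds(c(134, 10, 134, 134)),
                              134)$class, "tethering")
  # slow segment with path below one diameter never rolls
  expect_equal(classify_track(track_from_speeds(c(134, 20, 20, 134)),
                              134)$class, "tethering")
  expect_error(classify_track(track_from_speeds(c(1, 2)), 0), "u_ref")
})

test_that("classifier agrees with the exhaustive segment-scan oracle", {
  withr::with_seed(2024, {
    params <- classification_params()
    mismatch <- 0
    for (i in 1:300) {
      tr <- random_oracle_track()
      got <- classify_track(tr, 134, params)$class
      want <- oracle_classify(tr, 134)
      if (got != want) mismatch <- mismatch + 1
    }
    expect_equal(mismatch, 0)
  })
})

test_that("rolling velocity matches the oracle's maximal-window value", {
  withr::with_seed(77, {
    for (i in 1:100) {
      tr <- random_oracle_track()
      ct <- classify_track(tr, 134)
      if (ct$class == "rolling") {
        expect_equal(ct$rolling_velocity_um_s,
                     oracle_rolling_velocity(tr, 134))
      } else if (oracle_classify(tr, 134) != "adhesion") {
        # only a track classified adherent may still contain a
        # diameter-spanning slow window
        expect_null(oracle_rolling_velocity(tr, 134))
      }
    }
  })
})

test_that("raising the rolling threshold never removes interactions", {
  withr::with_seed(11, {
    tracks <- replicate(150, random_oracle_track(), simplify = FALSE)
    count_interacting <- function(c_frac) {
      p <- classification_params(rolling_threshold_fraction = c_frac)
      sum(vapply(tracks, function(tr)
        classify_track(tr, 134, p)$class %in% c("rolling", "tethering"),
        logical(1)))
    }
    n_05 <- count_interacting(0.5)
    n_08 <- count_interacting(0.8)
    n_10 <- count_interacting(1.0)
    expect_lte(n_05, n_08)
    expect_lte(n_08, n_10)
  })
})

test_that("cohort summaries implement the percentage formula and pool by
           counts", {
  cl <- data.frame(
    track_id = 1:10,
    condition = "A", field_id = c(rep(1L, 7), rep(2L, 3)),
    diameter_um = 85,
    class = c(rep("adhesion", 2), rep("rolling", 3), "tethering",
              rep("free", 4)),
    rolling_velocity_um_s = c(NA, NA, 30, 35, 40, NA, NA, NA, NA, NA),
    n_frames = 10, single_frame = FALSE)
  sm <- summarize_cohort(cl, "A", 0.05)
  expect_equal(sm$n_total, 10)
  expect_equal(sm$pct_adhesion, 20)
  expect_equal(sm$pct_tether, 10)
  expect_equal(sm$median_rolling_velocity_um_s, 35)
  # duplicating every track leaves percentages unchanged
  cl2 <- rbind(cl, transform(cl, track_id = track_id + 100))
  sm2 <- summarize_cohort(cl2, "A", 0.05)
  expect_equal(sm2$pct_adhesion, sm$pct_adhesion)
  expect_equal(sm2$pct_tether, sm$pct_tether)
  # pooling two fields equals summing counts before dividing
  f1 <- summarize_cohort(cl[cl$field_id == 1, ], "A", 0.05)
  f2 <- summarize_cohort(cl[cl$field_id == 2, ], "A", 0.05)
  expect_equal(sm$pct_adhesion,
               100 * (f1$n_adhere + f2$n_adhere) /
                 (f1$n_total + f2$n_total))
  # and is NOT the mean of percentages in general
  expect_false(isTRUE(all.equal(sm$pct_adhesion,
                                mean(c(f1$pct_adhesion,
                                       f2$pct_adhesion)))))
  # empty cohort: explicit flag, no division by zero
  sm0 <- summarize_cohort(cl[0, ], "B", 0.05)
  expect_true(sm0$empty_cohort)
  expect_equal(sm0$n_total, 0)
})

test_that("latent classes are recovered on simulated cohorts", {
  fc <- default_flow_005()
  cfg <- simulation_config(flow = fc, n_arrivals = 150, n_fields = 2,
                           seed = 5)
  sim <- simulate_trajectories(cfg)
  cl <- classify_cohort(sim$trajectories, fc)
  m <- merge(cl[, c("track_id", "class")],
             sim$classes[, c("track_id", "true_class")])
  acc <- prop.table(table(m$true_class, m$class), 1)
  for (cls in c("free", "tethering", "adhesion"))
    expect_gte(acc[cls, cls], 0.9)
  # cohort percentage within the exact binomial CI of the truth fraction
  n <- nrow(m)
  for (cls in c("tethering", "adhesion")) {
    ci <- stats::binom.test(sum(m$class == cls), n)$conf.int
    p_true <- mean(m$true_class == cls)
    expect_true(p_true >= ci[1] && p_true <= ci[2])
  }
})

test_that("measured detachment curve matches the generator's survival", {
  fc <- default_flow_005()
  cfg <- simulation_config(flow = fc, seed = 8)
  ramp <- make_shear_ramp(0.5, 4, 8, 30)
  res <- run_detachment(cfg, ramp, 40)
  # positional jitter can push a rare surviving spheroid past the
  # stationarity threshold in one block, so allow a small discrepancy
  expect_lte(max(abs(res$measured$fraction_remaining -
                     res$simulated$fraction_remaining)), 0.075)
  expect_equal(res$measured$fraction_remaining[8],
               res$simulated$fraction_remaining[8])
  expect_error(detachment_fraction(integer(0), list(), ramp), "adherent")
  expect_error(detachment_fraction(1:3, list(data.frame()), ramp),
               "one observation block")
})
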