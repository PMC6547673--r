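test_that("rendering is reproducible, noise-only when empty, and centroids
           land within a pixel of truth", {
  traj <- data.frame(frame = 0:2, track_id = 1L,
                     x_um = 400, y_um = 300, diameter_um = 85,
                     condition = "A", field_id = 1L)
  s1 <- render_image_stack(traj, 900, 700, 3, seed = 1)
  s2 <- render_image_stack(traj, 900, 700, 3, seed = 1)
  expect_identical(unclass(s1), unclass(s2))
  # empty table -> pure noise frames
  s0 <- render_image_stack(traj[0, ], 900, 700, 2, seed = 2)
  expect_lt(max(unclass(s0)), 400)
  # stationary spheroid: centroid within 1 px of truth on any frame
  px <- attr(s1, "pixel_size_um")
  d <- detect_spheroids(unclass(s1)[, , 2], px)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x_um - 400), px)
  expect_lt(abs(d$y_um - 300), px)
  expect_lt(abs(d$diameter_um - 85), 6)
  expect_error(render_image_stack(traj, 900, 700, 3, pixel_size_um = 60),
               "2 px")
})

test_that("size gate separates in-range spheroids from small debris", {
  traj <- data.frame(frame = 0, track_id = 1:4,
                     x_um = c(150, 450, 750, 300),
                     y_um = c(150, 350, 550, 550),
                     diameter_um = c(80, 80, 80, 30),
                     condition = "A", field_id = 1L)
  st <- render_image_stack(traj, 900, 700, 1, seed = 3)
  d <- detect_spheroids(unclass(st)[, , 1], attr(st, "pixel_size_um"))
  expect_equal(nrow(d), 3)
  expect_gte(attr(d, "n_gate_rejected"), 1)
  # gate off finds the debris too
  d_all <- detect_spheroids(unclass(st)[, , 1],
                            attr(st, "pixel_size_um"), size_gate = NULL,
                            min_area_px = 9)
  expect_gte(nrow(d_all), 4)
})

test_that("blank frames yield zero detections with a warning", {
  blank <- matrix(100L, 80, 80)
  expect_warning(d <- detect_spheroids(blank, 3.25), "no detections")
  expect_equal(nrow(d), 0)
  noise <- matrix(stats::rpois(80 * 80, 100), 80, 80)
  d2 <- suppressWarnings(detect_spheroids(noise, 3.25))
  expect_equal(nrow(d2), 0)
  expect_error(detect_spheroids(noise, NULL), "calibration")
})

test_that("TIFF stacks round-trip through disk with their calibration", {
  traj <- data.frame(frame = 0:1, track_id = 1L, x_um = 400, y_um = 300,
                     diameter_um = 85, condition = "A", field_id = 1L)
  st <- render_image_stack(traj, 900, 700, 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".tif")
  write_tiff_stack(st, path)
  st2 <- read_tiff_stack(path)
  expect_equal(unclass(st2), unclass(st), ignore_attr = TRUE)
  expect_equal(attr(st2, "pixel_size_um"), attr(st, "pixel_size_um"))
})

test_that("linking recovers simple geometries exactly", {
  fc <- small_field_flow()
  # one spheroid alone -> one track reproducing its detections
  one <- data.frame(frame = 0:5, x_um = seq(0, 500, by = 100), y_um = 300,
                    diameter_um = 85)
  tr <- link_tracks(one, fc)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(tr$x_um, one$x_um)
  # two laterally well-separated spheroids -> two tracks, no switches
  two <- rbind(transform(one, y_um = 100),
               transform(one, y_um = 500, x_um = x_um + 30))
  tr2 <- link_tracks(two, fc)
  expect_equal(length(unique(tr2$track_id)), 2)
  sp <- split(tr2$y_um, tr2$track_id)
  expect_true(all(vapply(sp, function(y) length(unique(y)) == 1,
                         logical(1))))
  # row-order permutation invariance (up to track id relabeling)
  perm <- two[sample(nrow(two)), ]
  tr3 <- link_tracks(perm, fc)
  expect_equal(tr3[order(tr3$y_um, tr3$frame), c("frame", "x_um", "y_um")],
               tr2[order(tr2$y_um, tr2$frame), c("frame", "x_um", "y_um")],
               ignore_attr = TRUE)
  expect_equal(length(unique(tr3$track_id)), 2)
  expect_error(link_tracks(one, fc, dt_s = 0), "calibration")
})

test_that("rendered-stack round trip recovers a mixed-behavior cohort", {
  fc <- small_field_flow()
  u <- hydrodynamic_velocity(fc, 85)
  free1 <- data.frame(frame = 0:6, track_id = 1L,
                      x_um = 60 + u * (0:6), y_um = 120,
                      diameter_um = 85, condition = "A", field_id = 1L)
  free1 <- free1[free1$x_um < 850, ]
  adherent <- data.frame(frame = 0:9, track_id = 2L, x_um = 500,
                         y_um = 350, diameter_um = 90, condition = "A",
                         field_id = 1L)
  rolling <- data.frame(frame = 0:9, track_id = 3L,
                        x_um = 80 + 0.3 * u * (0:9), y_um = 570,
                        diameter_um = 80, condition = "A", field_id = 1L)
  traj <- rbind(free1, adherent, rolling)
  st <- render_image_stack(traj, fc$geometry$fov_x_um,
                           fc$geometry$fov_y_um, 10, seed = 22)
  dets <- detect_stack(st)
  tr <- link_tracks(dets, fc)
  truth <- traj
  truth$latent_state <- NA_character_
  ev <- evaluate_tracking(tr, truth, fov_x_um = fc$geometry$fov_x_um)
  expect_gte(ev$link_recovery, 0.95)
  expect_equal(ev$n_switches, 0L)
  # classification of the recovered tracks matches the designed behavior
  cl <- classify_cohort(tr, fc)
  expect_setequal(cl$class, c("free", "adhesion", "rolling"))
})

test_that("track QC is a pure, faithful summary", {
  tracks <- data.frame(frame = c(0, 1, 2, 0, 5),
                       track_id = c(1, 1, 1, 2, 3),
                       x_um = 1:5, y_um = 1, diameter_um = 85,
                       field_id = c(1, 1, 1, 1, 2))
  before <- tracks
  qc <- track_qc(tracks, n_gate_rejected = 4L)
  expect_identical(tracks, before)
  expect_equal(qc$n_tracks, 3)
  expect_equal(qc$n_detections, 5)
  expect_equal(qc$fraction_single_frame, 2 / 3)
  expect_equal(qc$n_gate_rejected, 4L)
  qc0 <- track_qc(tracks[0, ])
  expect_equal(qc0$n_tracks, 0)
})
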