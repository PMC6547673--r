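#' Simulation configuration for a synthetic perfusion cohort
#'
#' Bundles the flow context, bond kinetics and acquisition settings that
#' define one simulated perfusion experiment: spheroids of 70-100 um
#' diameter enter the imaged field in suspension, are transported at the
#' near-wall hydrodynamic velocity, and stochastically tether, roll and
#' arrest on the substrate following the catch-slip kinetics of the
#' [bond_model()]. Acquisition mirrors the assay: 1 frame per second for
#' 30 s per field, three or more fields per condition.
#'
#' @param flow A [flow_context()].
#' @param bond A [bond_model()].
#' @param diameter_range_um Spheroid diameter range (um); sizes are drawn
#'   uniformly within it. Must lie inside (0, channel height).
#' @param n_arrivals Integer: spheroids entering each field during the
#'   acquisition. `NULL` (default) draws a Poisson count per field with mean
#'   `density_per_mL/1000 * Q[uL/min]/60 * duration_s * min(1, fov_y/width)`,
#'   tying the suspension density to the field throughput.
#' @param density_per_mL Suspension density (spheroids per mL), default 1500.
#' @param dt_s Frame interval (s), default 1.
#' @param duration_s Acquisition duration per field (s), default 30; must be
#'   an integer multiple of `dt_s`.
#' @param n_fields Number of fields of view (default 3).
#' @param seed Master seed; per-field child streams are derived from it.
#' @param condition Condition label attached to every trajectory row.
#' @param edta Logical: EDTA mode (no new bonds, off-rates multiplied by
#'   `bond$edta_koff_factor`).
#' @param jitter_sd_um Gaussian positional jitter (um) applied to recorded
#'   positions of stationary (tethered/adherent) spheroids.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(flow = flow_context(shear_dyn_cm2 = 0.05),
                              bond = bond_model(),
                              diameter_range_um = c(70, 100),
                              n_arrivals = NULL,
                              density_per_mL = 1500,
                              dt_s = 1, duration_s = 30, n_fields = 3,
                              seed = 1, condition = "A",
                              edta = FALSE, jitter_sd_um = 1) {
  stopifnot(inherits(flow, "flow_context"), inherits(bond, "bond_model"))
  if (dt_s <= 0) stop("dt_s must be positive", call. = FALSE)
  n_frames <- duration_s / dt_s
  if (abs(n_frames - round(n_frames)) > 1e-9)
    stop("duration_s must be an integer multiple of dt_s", call. = FALSE)
  if (diameter_range_um[1] <= 0 ||
      diameter_range_um[2] > flow$geometry$height_um)
    stop("diameter range must lie within (0, channel height]", call. = FALSE)
  if (n_fields < 1) stop("n_fields must be >= 1", call. = FALSE)
  structure(list(flow = flow, bond = bond,
                 diameter_range_um = diameter_range_um,
                 n_arrivals = n_arrivals, density_per_mL = density_per_mL,
                 dt_s = dt_s, duration_s = duration_s,
                 n_frames = as.integer(round(n_frames)),
                 n_fields = as.integer(n_fields),
                 seed = seed, condition = condition,
                 edta = edta, jitter_sd_um = jitter_sd_um),
            class = "simulation_config")
}

#' Expected arrivals per field from the suspension density
#'
#' @param config A [simulation_config()].
#' @return Poisson mean of spheroid arrivals per field per acquisition.
#' @export
expected_arrivals <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  geom <- config$flow$geometry
  config$density_per_mL / 1000 *
    config$flow$flow_rate_uL_min / 60 * config$duration_s *
    min(1, geom$fov_y_um / geom$width_um)
}

# deterministic child stream derivation (Lehmer step), kept < 2^31
child_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + 7919 * as.numeric(i)) %% 2147483647)
}

empty_trajectory_table <- function() {
  data.frame(frame = integer(), track_id = integer(), x_um = numeric(),
             y_um = numeric(), diameter_um = numeric(),
             condition = character(), field_id = integer(),
             stringsAsFactors = FALSE)
}

# latent-state codes
.STATES <- c("free", "tethered", "rolling", "adherent")

#' Simulate spheroid trajectories under flow
#'
#' Discrete-time Markov chain at the frame interval: each spheroid enters
#' the upstream field edge at a random frame and transverse position, and
#' per interval either stays in its state or transitions with probability
#' `1 - exp(-rate * dt)` (competing exponential rates):
#' free -> tethered at `k_on`; tethered -> free at
#' `release_to_free_rate + k_off(tau)`, -> rolling at `k_on`, -> adherent at
#' `k_arrest`; rolling -> free at `k_off(tau)`, -> adherent at `k_arrest`.
#' Firm adhesion is absorbing at assay-scale shear. Per-interval advance is
#' `u_h` when free, `rho * u_h` when rolling, and zero (plus recorded
#' positional jitter) when tethered or adherent. Spheroids leave the record
#' when their downstream position exceeds the field.
#'
#' @param config A [simulation_config()].
#' @return A list of class `spheroid_cohort` with elements
#'   `trajectories` (frame, track_id, x_um, y_um, diameter_um, condition,
#'   field_id), `truth` (same rows plus `latent_state`), and `classes`
#'   (per-track ground-truth behavioral class, see [truth_track_class()]).
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$flow$shear_dyn_cm2 == 0)
    warning("zero shear: no hydrodynamic transport", call. = FALSE)
  bond <- config$bond
  tau <- config$flow$shear_dyn_cm2
  k_on <- if (config$edta) 0 else bond$k_on
  k_off <- bond_off_rate(bond, tau) *
    (if (config$edta) bond$edta_koff_factor else 1)
  rel <- bond$release_to_free_rate *
    (if (config$edta) bond$edta_koff_factor else 1)
  rho <- bond$rolling_speed_fraction
  dt <- config$dt_s
  n_frames <- config$n_frames
  geom <- config$flow$geometry

  field_tables <- lapply(seq_len(config$n_fields), function(f) {
    withr::with_seed(child_seed(config$seed, f), {
      n <- if (is.null(config$n_arrivals)) {
        stats::rpois(1, expected_arrivals(config))
      } else as.integer(config$n_arrivals)
      if (n == 0) return(NULL)
      rows <- vector("list", n)
      for (j in seq_len(n)) {
        d <- stats::runif(1, config$diameter_range_um[1],
                          config$diameter_range_um[2])
        u_h <- hydrodynamic_velocity(config$flow, d)
        entry <- sample.int(n_frames, 1) - 1L    # 0-based entry frame
        y <- stats::runif(1, d / 2, geom$fov_y_um - d / 2)
        # per-interval transition setup
        frames <- integer(0); xs <- numeric(0); states <- character(0)
        adv <- numeric(0)
        x <- 0; state <- "free"; t <- entry
        while (t < n_frames && x <= geom$fov_x_um) {
          frames <- c(frames, t); xs <- c(xs, x); states <- c(states, state)
          # displacement over [t, t+1] by state at t
          dx <- switch(state, free = u_h * dt, rolling = rho * u_h * dt,
                       tethered = 0, adherent = 0)
          adv <- c(adv, dx)
          x <- x + dx
          rates <- switch(state,
            free = c(tethered = k_on),
            tethered = c(free = rel + k_off, rolling = k_on,
                         adherent = bond$k_arrest),
            rolling = c(free = k_off, adherent = bond$k_arrest),
            adherent = c())
          total <- sum(rates)
          if (total > 0 && stats::runif(1) < 1 - exp(-total * dt))
            state <- sample(names(rates), 1, prob = rates)
          t <- t + 1L
        }
        n_obs <- length(frames)
        if (n_obs == 0) { rows[[j]] <- NULL; next }
        jit <- states %in% c("tethered", "adherent")
        x_rec <- xs + ifelse(jit, stats::rnorm(n_obs, 0, config$jitter_sd_um), 0)
        y_rec <- y + ifelse(jit, stats::rnorm(n_obs, 0, config$jitter_sd_um), 0)
        rows[[j]] <- data.frame(
          frame = frames, track_id = f * 100000L + j,
          x_um = x_rec, y_um = y_rec, diameter_um = d,
          condition = config$condition, field_id = f,
          latent_state = states,
          advance_um = adv, stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    })
  })
  truth <- do.call(rbind, field_tables)
  if (is.null(truth)) {
    truth <- cbind(empty_trajectory_table(),
                   data.frame(latent_state = character(),
                              advance_um = numeric()))
  }
  rownames(truth) <- NULL
  traj <- truth[, c("frame", "track_id", "x_um", "y_um", "diameter_um",
                    "condition", "field_id")]
  classes <- truth_track_classes(truth)
  structure(list(trajectories = traj,
                 truth = truth[, setdiff(names(truth), "advance_um")],
                 classes = classes, config = config),
            class = "spheroid_cohort")
}

#' Ground-truth behavioral class of one latent state sequence
#'
#' Derives the track-level class the observation process implies from the
#' latent per-frame states: `adhesion` if the track ends in a stationary
#' (tethered/adherent) run covering at least two observed frames;
#' otherwise `rolling` if some contiguous rolling run travels more than one
#' spheroid diameter; otherwise `tethering` if any tethered/rolling frame is
#' followed by a return to free transport; otherwise `free`. Censoring is
#' treated exactly as the classifier must treat it (a spheroid stationary
#' through the end of recording counts as adherent regardless of what it
#' would have done later).
#'
#' @param states Character vector of latent states, one per observed frame.
#' @param advance_um Per-interval true downstream advance (um); the last
#'   element (beyond the final frame) is ignored.
#' @param diameter_um Spheroid diameter (um).
#' @return One of `"adhesion"`, `"rolling"`, `"tethering"`, `"free"`.
#' @export
truth_track_class <- function(states, advance_um, diameter_um) {
  n <- length(states)
  if (n <= 1) return("free")
  # intervals are defined by the state at their starting frame
  int_state <- states[-n]
  stationary <- int_state %in% c("tethered", "adherent")
  # terminal stationary run
  m <- 0
  for (i in rev(seq_along(stationary))) {
    if (stationary[i]) m <- m + 1 else break
  }
  if (m >= 1 && m + 1 >= 2) return("adhesion")
  # rolling runs
  r <- rle(int_state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (r$values[k] == "rolling") {
      path <- sum(advance_um[starts[k]:ends[k]])
      if (path > diameter_um) return("rolling")
    }
  }
  # tethering: interaction followed by return to free
  interacting <- int_state %in% c("tethered", "rolling")
  if (any(interacting)) {
    last_int <- max(which(interacting))
    if (last_int < length(int_state) &&
        any(int_state[(last_int + 1):length(int_state)] == "free"))
      return("tethering")
    # any earlier interacting interval followed by free also qualifies
    first_int <- min(which(interacting))
    if (any(int_state[-seq_len(first_int)] == "free"))
      return("tethering")
  }
  "free"
}

truth_track_classes <- function(truth) {
  if (nrow(truth) == 0)
    return(data.frame(track_id = integer(), condition = character(),
                      field_id = integer(), diameter_um = numeric(),
                      true_class = character(), stringsAsFactors = FALSE))
  sp <- split(truth, truth$track_id)
  out <- lapply(sp, function(tr) {
    tr <- tr[order(tr$frame), ]
    data.frame(track_id = tr$track_id[1], condition = tr$condition[1],
               field_id = tr$field_id[1], diameter_um = tr$diameter_um[1],
               true_class = truth_track_class(tr$latent_state, tr$advance_um,
                                              tr$diameter_um[1]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate a cohort with prescribed class probabilities
#'
#' Scripted-cohort generator: each spheroid's behavioral class is drawn
#' directly from the supplied probabilities and a trajectory consistent
#' with that class is synthesized (free transit at the hydrodynamic
#' velocity; a one-to-two frame pause with release for tethering; a
#' sub-hydrodynamic run longer than one diameter for rolling; terminal
#' arrest for adhesion). Used for parameter-recovery validation, where the
#' generative class probabilities must be exact inputs rather than emergent
#' properties of the kinetic chain.
#'
#' @param n Number of spheroids.
#' @param probs Named numeric vector with entries `tethering`, `rolling`,
#'   `adhesion`, `free`; must sum to 1.
#' @param flow A [flow_context()].
#' @param diameter_range_um Diameter range (um).
#' @param rolling_speed_fraction Rolling speed as a fraction of u_h.
#' @param dt_s,duration_s Frame interval and duration (s).
#' @param seed Seed.
#' @param condition Condition label.
#' @param field_id Field id for all tracks.
#' @param jitter_sd_um Stationary positional jitter (um).
#' @param exact_fractions Logical: instead of i.i.d. multinomial class
#'   draws, fix the class counts at their expectations (largest-remainder
#'   rounding, random order), so the cohort's class fractions equal the
#'   generative probabilities exactly. Useful when validating the
#'   measurement pipeline in isolation from sampling noise.
#' @return A `spheroid_cohort` list (`trajectories`, `truth`, `classes`).
#' @export
simulate_cohort_from_probs <- function(n, probs, flow,
                                       diameter_range_um = c(70, 100),
                                       rolling_speed_fraction = 0.2,
                                       dt_s = 1, duration_s = 30,
                                       seed = 1, condition = "A",
                                       field_id = 1L, jitter_sd_um = 1,
                                       exact_fractions = FALSE) {
  stopifnot(inherits(flow, "flow_context"))
  need <- c("tethering", "rolling", "adhesion", "free")
  if (!all(need %in% names(probs)) || abs(sum(probs) - 1) > 1e-8)
    stop("probs must be named tethering/rolling/adhesion/free and sum to 1",
         call. = FALSE)
  n_frames <- as.integer(round(duration_s / dt_s))
  geom <- flow$geometry
  rho <- rolling_speed_fraction
  withr::with_seed(seed, {
    cls_vec <- if (exact_fractions) {
      base <- floor(n * probs[need])
      rem <- n - sum(base)
      frac <- n * probs[need] - base
      extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
      sample(rep(need, times = base))
    } else NULL
    rows <- vector("list", n)
    for (j in seq_len(n)) {
      d <- stats::runif(1, diameter_range_um[1], diameter_range_um[2])
      u_h <- hydrodynamic_velocity(flow, d)
      cls <- if (exact_fractions) cls_vec[j]
             else sample(need, 1, prob = probs[need])
      step_free <- u_h * dt_s
      max_transit <- ceiling(geom$fov_x_um / step_free)
      states <- switch(cls,
        free = rep("free", n_frames),
        tethering = {
          f1 <- sample(1:3, 1); t1 <- sample(1:2, 1)
          c(rep("free", f1), rep("tethered", t1),
            rep("free", n_frames))[1:n_frames]
        },
        rolling = {
          f1 <- sample(1:2, 1)
          n_r <- ceiling(1.5 * d / (rho * u_h * dt_s))
          n_r <- min(n_r, n_frames - f1 - 2L)
          c(rep("free", f1), rep("rolling", n_r),
            rep("free", n_frames))[1:n_frames]
        },
        adhesion = {
          f1 <- sample(1:2, 1); r1 <- sample(0:2, 1)
          c(rep("free", f1), rep("rolling", r1),
            rep("adherent", n_frames))[1:n_frames]
        })
      entry <- if (cls == "free") sample.int(n_frames, 1) - 1L
               else sample.int(3L, 1) - 1L
      y <- stats::runif(1, d / 2, geom$fov_y_um - d / 2)
      x <- 0; frames <- integer(0); xs <- numeric(0)
      st <- character(0); adv <- numeric(0)
      t <- entry; i <- 1
      while (t < n_frames && x <= geom$fov_x_um && i <= length(states)) {
        frames <- c(frames, t); xs <- c(xs, x); st <- c(st, states[i])
        dx <- switch(states[i], free = step_free,
                     rolling = rho * step_free, tethered = 0, adherent = 0)
        adv <- c(adv, dx)
        x <- x + dx; t <- t + 1L; i <- i + 1
      }
      n_obs <- length(frames)
      jit <- st %in% c("tethered", "adherent")
      rows[[j]] <- data.frame(
        frame = frames, track_id = as.integer(field_id) * 100000L + j,
        x_um = xs + ifelse(jit, stats::rnorm(n_obs, 0, jitter_sd_um), 0),
        y_um = y + ifelse(jit, stats::rnorm(n_obs, 0, jitter_sd_um), 0),
        diameter_um = d, condition = condition,
        field_id = as.integer(field_id),
        latent_state = st, advance_um = adv, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    traj <- truth[, c("frame", "track_id", "x_um", "y_um", "diameter_um",
                      "condition", "field_id")]
    structure(list(trajectories = traj,
                   truth = truth[, setdiff(names(truth), "advance_um")],
                   classes = truth_track_classes(truth)),
              class = "spheroid_cohort")
  })
}

#' Simulate stepwise shear-ramp detachment of firmly adherent spheroids
#'
#' Applies a [make_shear_ramp()] schedule to an initially adherent
#' population. At each step every surviving spheroid ruptures with
#' probability `1 - exp(-k_off_firm(tau) * hold)`; the survival curve is
#' therefore monotone non-increasing. Optionally emits a short stationary
#' observation block per step (survivors only) so the measurement-side
#' [detachment_fraction()] can recompute the curve from positions.
#'
#' @param config A [simulation_config()] (supplies bond model, flow
#'   geometry, jitter and EDTA flag).
#' @param ramp A [make_shear_ramp()] schedule.
#' @param n_adherent Number of initially adherent spheroids (>= 1).
#' @param observe_frames Frames per per-step observation block (0 disables
#'   block output).
#' @return A list with `survival` (data.frame: step, tau_dyn_cm2, hold_s,
#'   n_remaining, fraction_remaining), `initial_ids`, and `blocks` (list of
#'   per-step trajectory tables).
#' @export
simulate_detachment <- function(config, ramp, n_adherent,
                                observe_frames = 5L) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(ramp, "shear_ramp"))
  if (nrow(ramp) == 0) stop("empty ramp", call. = FALSE)
  if (n_adherent < 1) stop("n_adherent must be >= 1", call. = FALSE)
  geom <- config$flow$geometry
  withr::with_seed(child_seed(config$seed, 99991L), {
    ids <- seq_len(n_adherent)
    d <- stats::runif(n_adherent, config$diameter_range_um[1],
                      config$diameter_range_um[2])
    x0 <- stats::runif(n_adherent, 0.1 * geom$fov_x_um, 0.9 * geom$fov_x_um)
    y0 <- stats::runif(n_adherent, 0.1 * geom$fov_y_um, 0.9 * geom$fov_y_um)
    alive <- rep(TRUE, n_adherent)
    surv <- data.frame(step = ramp$step, tau_dyn_cm2 = ramp$tau_dyn_cm2,
                       hold_s = ramp$hold_s, n_remaining = NA_integer_,
                       fraction_remaining = NA_real_)
    blocks <- vector("list", nrow(ramp))
    for (s in seq_len(nrow(ramp))) {
      rate <- firm_off_rate(config$bond, ramp$tau_dyn_cm2[s],
                            edta = config$edta)
      p_rupture <- 1 - exp(-rate * ramp$hold_s[s])
      alive <- alive & (stats::runif(n_adherent) >= p_rupture)
      surv$n_remaining[s] <- sum(alive)
      surv$fraction_remaining[s] <- sum(alive) / n_adherent
      if (observe_frames > 0) {
        keep <- which(alive)
        blocks[[s]] <- if (length(keep) == 0) empty_trajectory_table() else
          do.call(rbind, lapply(keep, function(i) {
            nf <- as.integer(observe_frames)
            data.frame(frame = 0:(nf - 1L), track_id = ids[i],
                       x_um = x0[i] + stats::rnorm(nf, 0, config$jitter_sd_um),
                       y_um = y0[i] + stats::rnorm(nf, 0, config$jitter_sd_um),
                       diameter_um = d[i], condition = config$condition,
                       field_id = 1L, stringsAsFactors = FALSE)
          }))
      }
    }
    list(survival = surv, initial_ids = ids, blocks = blocks)
  })
}

#' Pool two simulated conditions into one labeled cohort
#'
#' Conditions must share the same flow context (comparisons are only
#' meaningful at equal shear); trajectories are pooled with their condition
#' labels and per-condition reproducibility follows from the per-condition
#' seeds.
#'
#' @param config_a,config_b Two [simulation_config()] objects sharing a
#'   flow context.
#' @return A `spheroid_cohort` list with pooled `trajectories`, `truth`,
#'   `classes`.
#' @export
generate_two_condition_cohort <- function(config_a, config_b) {
  stopifnot(inherits(config_a, "simulation_config"),
            inherits(config_b, "simulation_config"))
  if (!isTRUE(all.equal(config_a$flow, config_b$flow)))
    stop("conditions must share the same flow context", call. = FALSE)
  if (identical(config_a$condition, config_b$condition))
    stop("conditions must carry distinct labels", call. = FALSE)
  a <- simulate_trajectories(config_a)
  b <- simulate_trajectories(config_b)
  # disambiguate track ids across conditions
  if (nrow(b$trajectories) > 0) {
    off <- 10000000L
    b$trajectories$track_id <- b$trajectories$track_id + off
    b$truth$track_id <- b$truth$track_id + off
    b$classes$track_id <- b$classes$track_id + off
  }
  structure(list(trajectories = rbind(a$trajectories, b$trajectories),
                 truth = rbind(a$truth, b$truth),
                 classes = rbind(a$classes, b$classes)),
            class = "spheroid_cohort")
}
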