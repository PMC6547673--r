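#' Motion-classification parameters
#'
#' Operationalizes the assay's three behavioral definitions on 1 fps
#' trajectories. Tethering: transient capture followed by release into the
#' flow. Rolling: translation below the hydrodynamic reference velocity
#' sustained over more than one spheroid diameter. Adhesion: stationary
#' over consecutive frames through the end of recording.
#'
#' @param reference `"analytic"` (hydrodynamic velocity at the cohort
#'   median diameter, from the flow context) or `"empirical"` (upper
#'   percentile of all observed per-interval speeds).
#' @param rolling_threshold_fraction c in (0, 1]: a speed counts as
#'   sub-hydrodynamic when below `c * u_ref`. The default 0.5 follows the
#'   leukocyte-rolling convention; `c = 1` reproduces the literal
#'   "below the hydrodynamic velocity" reading, which at 1 fps with noise
#'   misclassifies free spheroids.
#' @param stationary_eps_um Stationarity threshold epsilon (um per frame):
#'   displacements below it count as arrest. Default 5 um, about 6% of a
#'   spheroid diameter and well above the simulator's 1 um jitter.
#' @param min_rolling_path_diameters Minimum summed path of a qualifying
#'   rolling segment, in units of the track-median diameter (default 1).
#' @param min_stationary_frames Minimum consecutive stationary frames for
#'   adhesion (default 2, i.e. one stationary interval).
#' @param arrest `"terminal"` (default: the stationary run must persist to
#'   the end of the track's observation) or `"anywhere"`.
#' @param empirical_percentile Percentile of observed speeds used by the
#'   empirical reference (default 90).
#' @param count_single_frame Logical: count single-frame tracks in the
#'   cohort denominator (default TRUE).
#' @return An object of class `classification_params`.
#' @export
classification_params <- function(reference = c("analytic", "empirical"),
                                  rolling_threshold_fraction = 0.5,
                                  stationary_eps_um = 5,
                                  min_rolling_path_diameters = 1,
                                  min_stationary_frames = 2,
                                  arrest = c("terminal", "anywhere"),
                                  empirical_percentile = 90,
                                  count_single_frame = TRUE) {
  reference <- match.arg(reference)
  arrest <- match.arg(arrest)
  c_frac <- rolling_threshold_fraction
  if (c_frac <= 0 || c_frac > 1)
    stop("rolling_threshold_fraction must be in (0, 1]", call. = FALSE)
  if (stationary_eps_um < 0)
    stop("stationary_eps_um must be >= 0", call. = FALSE)
  structure(list(reference = reference,
                 rolling_threshold_fraction = c_frac,
                 stationary_eps_um = stationary_eps_um,
                 min_rolling_path_diameters = min_rolling_path_diameters,
                 min_stationary_frames = as.integer(min_stationary_frames),
                 arrest = arrest,
                 empirical_percentile = empirical_percentile,
                 count_single_frame = isTRUE(count_single_frame)),
            class = "classification_params")
}

#' Per-interval speeds of one track
#'
#' Euclidean displacement between consecutive observed frames divided by
#' elapsed time; gap-aware (a skipped frame contributes one interval with
#' the longer elapsed time).
#'
#' @param track data.frame with columns `frame`, `x_um`, `y_um` for a
#'   single track.
#' @param dt_s Frame interval (s).
#' @return data.frame with one row per consecutive pair: `frame_from`,
#'   `frame_to`, `elapsed_s`, `displacement_um`, `speed_um_s`. Zero rows
#'   (with attribute `single_frame = TRUE`) for a single-detection track.
#' @export
frame_velocities <- function(track, dt_s = 1) {
  track <- track[order(track$frame), ]
  n <- nrow(track)
  if (n < 2) {
    out <- data.frame(frame_from = integer(), frame_to = integer(),
                      elapsed_s = numeric(), displacement_um = numeric(),
                      speed_um_s = numeric())
    attr(out, "single_frame") <- TRUE
    return(out)
  }
  dx <- diff(track$x_um); dy <- diff(track$y_um)
  dframes <- diff(track$frame)
  disp <- sqrt(dx^2 + dy^2)
  elapsed <- dframes * dt_s
  data.frame(frame_from = track$frame[-n], frame_to = track$frame[-1],
             elapsed_s = elapsed, displacement_um = disp,
             speed_um_s = disp / elapsed)
}

#' Reference (free-transport) velocity for a cohort
#'
#' Analytic mode returns the hydrodynamic velocity at the cohort's median
#' diameter; empirical mode returns an upper percentile of all observed
#' per-interval speeds, a robust stand-in for the free-transport speed that
#' is insensitive to a minority of slow (interacting) tracks.
#'
#' @param trajectories Trajectory table (shared schema).
#' @param flow A [flow_context()] (required for analytic mode and as the
#'   fallback when too few tracks exist for the empirical mode).
#' @param params A [classification_params()].
#' @param dt_s Frame interval (s).
#' @return List with `u_ref_um_s` and `mode` actually used.
#' @export
reference_velocity <- function(trajectories, flow = NULL,
                               params = classification_params(),
                               dt_s = 1) {
  mode <- params$reference
  if (mode == "empirical") {
    n_tracks <- length(unique(trajectories$track_id))
    if (n_tracks < 5) {
      if (is.null(flow))
        stop("empirical reference needs >= 5 tracks and no flow context ",
             "was given for the analytic fallback", call. = FALSE)
      warning("fewer than 5 tracks: falling back to analytic reference",
              call. = FALSE)
      mode <- "analytic"
    }
  }
  if (mode == "analytic") {
    if (is.null(flow)) stop("analytic reference requires a flow context",
                            call. = FALSE)
    d_med <- stats::median(trajectories$diameter_um)
    return(list(u_ref_um_s = hydrodynamic_velocity(flow, d_med),
                mode = "analytic"))
  }
  speeds <- unlist(lapply(split(trajectories, trajectories$track_id),
                          function(tr) frame_velocities(tr, dt_s)$speed_um_s))
  list(u_ref_um_s = unname(stats::quantile(speeds,
                                           params$empirical_percentile / 100,
                                           type = 7)),
       mode = "empirical")
}

#' Classify one track as tethering, rolling, adhesion or free
#'
#' Applies the operational rules with precedence
#' adhesion > rolling > tethering > free so the classes partition the
#' cohort:
#' \itemize{
#' \item adhesion — at least `min_stationary_frames` consecutive observed
#'   frames with per-frame displacement below epsilon; by default the run
#'   must persist to the end of the track's observation.
#' \item rolling — some maximal contiguous run of intervals all below
#'   `c * u_ref` whose summed path exceeds one track-median diameter; the
#'   rolling velocity is the mean speed over the qualifying run with the
#'   longest path.
#' \item tethering — at least one interval below `c * u_ref` (or below the
#'   stationarity threshold) followed by a return to `>= c * u_ref`.
#' \item free — none of the above (single-frame tracks are free, flagged).
#' }
#'
#' @param track data.frame (`frame`, `x_um`, `y_um`, `diameter_um`) of one
#'   track.
#' @param u_ref Reference velocity (um s-1), > 0.
#' @param params A [classification_params()].
#' @param dt_s Frame interval (s).
#' @return List of class `classified_track`: `track_id`, `class`,
#'   `rolling_velocity_um_s` (NA unless rolling), `n_frames`,
#'   `single_frame`, `segments` (data.frame of qualifying segment ranges).
#' @export
classify_track <- function(track, u_ref, params = classification_params(),
                           dt_s = 1) {
  if (!is.numeric(u_ref) || u_ref <= 0)
    stop("u_ref must be positive", call. = FALSE)
  track <- track[order(track$frame), ]
  tid <- if ("track_id" %in% names(track)) track$track_id[1] else NA_integer_
  v <- frame_velocities(track, dt_s)
  if (nrow(v) == 0) {
    return(structure(list(track_id = tid, class = "free",
                          rolling_velocity_um_s = NA_real_,
                          n_frames = nrow(track), single_frame = TRUE,
                          segments = NULL),
                     class = "classified_track"))
  }
  eps <- params$stationary_eps_um
  c_thr <- params$rolling_threshold_fraction * u_ref
  d_med <- stats::median(track$diameter_um)
  # per-frame displacement for stationarity: normalize by elapsed frames
  disp_per_frame <- v$displacement_um / (v$elapsed_s / dt_s)
  stationary <- disp_per_frame < eps
  slow <- v$speed_um_s < c_thr | stationary
  n_int <- nrow(v)

  # --- adhesion ---
  runs <- rle(stationary)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  adhesion <- FALSE
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    # frames covered by this stationary run of intervals
    frames_covered <- v$frame_to[ends[k]] - v$frame_from[starts[k]] + 1
    if (frames_covered >= params$min_stationary_frames) {
      if (params$arrest == "anywhere" || ends[k] == n_int) {
        adhesion <- TRUE
        break
      }
    }
  }
  if (adhesion) {
    return(structure(list(track_id = tid, class = "adhesion",
                          rolling_velocity_um_s = NA_real_,
                          n_frames = nrow(track), single_frame = FALSE,
                          segments = NULL),
                     class = "classified_track"))
  }

  # --- rolling: maximal contiguous slow runs with path > min diameters ---
  sruns <- rle(slow)
  s_ends <- cumsum(sruns$lengths); s_starts <- s_ends - sruns$lengths + 1
  best_path <- -Inf; best_k <- NA
  seg_tab <- NULL
  for (k in seq_along(sruns$values)) {
    if (!sruns$values[k]) next
    idx <- s_starts[k]:s_ends[k]
    path <- sum(v$displacement_um[idx])
    if (path > params$min_rolling_path_diameters * d_med) {
      seg_tab <- rbind(seg_tab, data.frame(
        frame_from = v$frame_from[s_starts[k]],
        frame_to = v$frame_to[s_ends[k]], path_um = path,
        mean_speed_um_s = mean(v$speed_um_s[idx])))
      if (path > best_path) { best_path <- path; best_k <- k }
    }
  }
  if (!is.null(seg_tab)) {
    idx <- s_starts[best_k]:s_ends[best_k]
    return(structure(list(track_id = tid, class = "rolling",
                          rolling_velocity_um_s = mean(v$speed_um_s[idx]),
                          n_frames = nrow(track), single_frame = FALSE,
                          segments = seg_tab),
                     class = "classified_track"))
  }

  # --- tethering: slow interval followed by return to fast ---
  tether <- FALSE
  if (any(slow)) {
    first_slow <- min(which(slow))
    if (first_slow < n_int && any(!slow[(first_slow + 1):n_int]))
      tether <- TRUE
  }
  cls <- if (tether) "tethering" else "free"
  structure(list(track_id = tid, class = cls,
                 rolling_velocity_um_s = NA_real_,
                 n_frames = nrow(track), single_frame = FALSE,
                 segments = NULL),
            class = "classified_track")
}

#' Classify every track of a cohort
#'
#' @param trajectories Trajectory table (shared schema).
#' @param flow A [flow_context()] or NULL (empirical reference only).
#' @param params A [classification_params()].
#' @param dt_s Frame interval (s).
#' @return data.frame with one row per track: `track_id`, `condition`,
#'   `field_id`, `diameter_um`, `class`, `rolling_velocity_um_s`,
#'   `n_frames`, `single_frame`; attribute `u_ref` records the reference
#'   velocity used.
#' @export
classify_cohort <- function(trajectories, flow = NULL,
                            params = classification_params(), dt_s = 1) {
  if (nrow(trajectories) == 0) {
    out <- data.frame(track_id = integer(), condition = character(),
                      field_id = integer(), diameter_um = numeric(),
                      class = character(), rolling_velocity_um_s = numeric(),
                      n_frames = integer(), single_frame = logical())
    attr(out, "u_ref") <- NA_real_
    return(out)
  }
  ref <- reference_velocity(trajectories, flow, params, dt_s)
  sp <- split(trajectories, trajectories$track_id)
  out <- do.call(rbind, lapply(sp, function(tr) {
    ct <- classify_track(tr, ref$u_ref_um_s, params, dt_s)
    data.frame(track_id = tr$track_id[1],
               condition = if ("condition" %in% names(tr)) tr$condition[1]
                           else NA_character_,
               field_id = if ("field_id" %in% names(tr)) tr$field_id[1]
                          else NA_integer_,
               diameter_um = stats::median(tr$diameter_um),
               class = ct$class,
               rolling_velocity_um_s = ct$rolling_velocity_um_s,
               n_frames = ct$n_frames, single_frame = ct$single_frame,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "u_ref") <- ref$u_ref_um_s
  attr(out, "reference_mode") <- ref$mode
  out
}

#' Cohort summary: counts, percentages, rolling velocities
#'
#' Percentages follow the assay's formula: the number of tethering or
#' adherent spheroids divided by the total number of spheroids that flew
#' through the field of observation during the acquisition, pooled across
#' fields of the same condition and shear (counts pool, not percentages).
#'
#' @param classified Output of [classify_cohort()] (possibly filtered to
#'   one condition).
#' @param condition Condition label for the summary row.
#' @param shear_dyn_cm2 Shear level annotation.
#' @param count_single_frame Logical: include single-frame tracks in the
#'   denominator (default TRUE; the assay's counting rule for spheroids
#'   visible in only one frame is a policy choice).
#' @return One-row data.frame of class `cohort_summary`: `condition`,
#'   `shear_dyn_cm2`, `n_total`, `n_tether`, `n_roll`, `n_adhere`,
#'   `pct_tether`, `pct_roll`, `pct_adhesion`,
#'   `median_rolling_velocity_um_s`, `empty_cohort`.
#' @export
summarize_cohort <- function(classified, condition = NA_character_,
                             shear_dyn_cm2 = NA_real_,
                             count_single_frame = TRUE) {
  cl <- classified
  if (!isTRUE(count_single_frame) && nrow(cl) > 0)
    cl <- cl[!cl$single_frame, ]
  n_total <- nrow(cl)
  if (n_total == 0) {
    out <- data.frame(condition = condition, shear_dyn_cm2 = shear_dyn_cm2,
                      n_total = 0L, n_tether = 0L, n_roll = 0L,
                      n_adhere = 0L, pct_tether = 0, pct_roll = 0,
                      pct_adhesion = 0,
                      median_rolling_velocity_um_s = NA_real_,
                      empty_cohort = TRUE, stringsAsFactors = FALSE)
    class(out) <- c("cohort_summary", "data.frame")
    return(out)
  }
  n_tether <- sum(cl$class == "tethering")
  n_roll <- sum(cl$class == "rolling")
  n_adhere <- sum(cl$class == "adhesion")
  rv <- cl$rolling_velocity_um_s[cl$class == "rolling"]
  out <- data.frame(
    condition = condition, shear_dyn_cm2 = shear_dyn_cm2,
    n_total = n_total, n_tether = n_tether, n_roll = n_roll,
    n_adhere = n_adhere,
    pct_tether = 100 * n_tether / n_total,
    pct_roll = 100 * n_roll / n_total,
    pct_adhesion = 100 * n_adhere / n_total,
    median_rolling_velocity_um_s =
      if (length(rv)) stats::median(rv) else NA_real_,
    empty_cohort = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Rolling velocities of the rolling tracks of a cohort
#'
#' @param classified Output of [classify_cohort()].
#' @return Numeric vector of rolling velocities (um s-1).
#' @export
rolling_velocities <- function(classified) {
  classified$rolling_velocity_um_s[classified$class == "rolling"]
}

#' Detachment survival curve measured from per-step observations
#'
#' Given the identities of the spheroids adherent before the ramp and one
#' short observation block per ramp step, computes the fraction of the
#' initial adherent set still present and still satisfying the adhesion
#' criterion at each step. The measured curve is reported as observed (it
#' is not forced to be monotone).
#'
#' @param initial_ids Track ids adherent before the ramp.
#' @param blocks List of per-step trajectory tables (one per ramp step; an
#'   absent spheroid counts as detached).
#' @param ramp The [make_shear_ramp()] applied.
#' @param params A [classification_params()] used for the adhesion check.
#' @param dt_s Frame interval of the observation blocks (s).
#' @return data.frame: `step`, `tau_dyn_cm2`, `n_remaining`,
#'   `fraction_remaining`.
#' @export
detachment_fraction <- function(initial_ids, blocks, ramp,
                                params = classification_params(),
                                dt_s = 1) {
  stopifnot(inherits(ramp, "shear_ramp"))
  if (length(initial_ids) == 0) stop("no initially adherent spheroids",
                                     call. = FALSE)
  if (length(blocks) != nrow(ramp))
    stop("one observation block per ramp step is required", call. = FALSE)
  out <- data.frame(step = ramp$step, tau_dyn_cm2 = ramp$tau_dyn_cm2,
                    n_remaining = NA_integer_, fraction_remaining = NA_real_)
  for (s in seq_len(nrow(ramp))) {
    blk <- blocks[[s]]
    still <- 0L
    if (!is.null(blk) && nrow(blk) > 0) {
      present <- intersect(unique(blk$track_id), initial_ids)
      for (id in present) {
        tr <- blk[blk$track_id == id, ]
        if (nrow(tr) < 2) next
        v <- frame_velocities(tr, dt_s)
        disp_per_frame <- v$displacement_um / (v$elapsed_s / dt_s)
        if (all(disp_per_frame < params$stationary_eps_um))
          still <- still + 1L
      }
    }
    out$n_remaining[s] <- still
    out$fraction_remaining[s] <- still / length(initial_ids)
  }
  out
}
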