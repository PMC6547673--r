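#' Detect fluorescent spheroids in one frame
#'
#' Median background subtraction, Otsu thresholding and connected-component
#' labelling, followed by the assay's size gate: components whose
#' equivalent diameter falls outside the gate are discarded. The equivalent
#' diameter is measured from the component's half-maximum footprint (for a
#' Gaussian-profiled spot this recovers the full width at half maximum,
#' i.e. the physical diameter) and centroids are intensity-weighted centers
#' of mass, sub-pixel.
#'
#' @param frame Numeric matrix of pixel counts (rows = y, cols = x).
#' @param pixel_size_um Pixel size (um per pixel).
#' @param size_gate Diameter gate in um, default `c(70, 100)`; `NULL`
#'   disables gating.
#' @param min_area_px Minimum component area in pixels (speckle rejection).
#' @return data.frame: `x_um`, `y_um`, `diameter_um`, `intensity`; zero
#'   rows (with a warning) for a blank or constant frame. Attribute
#'   `n_gate_rejected` counts components discarded by the gate.
#' @export
detect_spheroids <- function(frame, pixel_size_um, size_gate = c(70, 100),
                             min_area_px = 9) {
  if (is.null(pixel_size_um) || !is.numeric(pixel_size_um) ||
      pixel_size_um <= 0)
    stop("pixel size calibration missing or invalid", call. = FALSE)
  empty <- data.frame(x_um = numeric(), y_um = numeric(),
                      diameter_um = numeric(), intensity = numeric())
  attr(empty, "n_gate_rejected") <- 0L
  img <- frame - stats::median(frame)
  img[img < 0] <- 0
  mx <- max(img)
  if (mx <= 0) {
    warning("constant or saturated-flat frame: no detections",
            call. = FALSE)
    return(empty)
  }
  norm <- img / mx
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  # floor the threshold above the background noise so speckle does not
  # flood the labeller on signal-free frames
  noise_floor <- 5 * 1.4826 * stats::mad(frame) / mx
  th <- max(th, noise_floor)
  mask <- norm > th
  if (!any(mask) || all(mask)) {
    warning("degenerate threshold: no detections", call. = FALSE)
    return(empty)
  }
  # watershed on the masked intensity splits touching spheroids at their
  # intensity saddle
  lab <- EBImage::watershed(EBImage::Image(norm * mask), tolerance = 0.2,
                            ext = 2)
  lab <- EBImage::imageData(lab)
  fg <- which(lab > 0)
  if (length(fg) == 0) return(empty)
  comps <- split(fg, lab[fg])
  nr <- nrow(img)
  rows <- vector("list", length(comps))
  n_rej <- 0L
  th_abs <- th * mx
  for (k in seq_along(comps)) {
    idx <- comps[[k]]
    if (length(idx) < min_area_px) next
    inten <- img[idx]
    peak <- max(inten)
    # Gaussian-spot diameter from integrated mass: a spot of peak P and
    # width sigma holds mass 2*pi*sigma^2*P, of which a fraction t =
    # threshold/peak lies below the threshold, so correct the truncation
    # before inverting for sigma; FWHM = 2.3548 sigma is the diameter.
    t_frac <- min(th_abs / peak, 0.9)
    mass <- sum(inten) / (1 - t_frac)
    sigma_px <- sqrt(mass / (2 * pi * peak))
    d_um <- 2 * sqrt(2 * log(2)) * sigma_px * pixel_size_um
    if (!is.null(size_gate) &&
        (d_um < size_gate[1] || d_um > size_gate[2])) {
      n_rej <- n_rej + 1L
      next
    }
    w <- inten / sum(inten)
    rowi <- ((idx - 1L) %% nr) + 1L
    coli <- ((idx - 1L) %/% nr) + 1L
    rows[[k]] <- data.frame(
      x_um = (sum(coli * w) - 0.5) * pixel_size_um,
      y_um = (sum(rowi * w) - 0.5) * pixel_size_um,
      diameter_um = d_um, intensity = sum(inten))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  attr(out, "n_gate_rejected") <- n_rej
  out
}

#' Detect spheroids in every frame of a stack
#'
#' @param stack An `image_stack` (see [render_image_stack()] /
#'   [read_tiff_stack()]).
#' @param size_gate Diameter gate (um).
#' @param ... Passed to [detect_spheroids()].
#' @return data.frame of detections with a 0-based `frame` column;
#'   attribute `n_gate_rejected` totals gate rejections.
#' @export
detect_stack <- function(stack, size_gate = c(70, 100), ...) {
  px <- attr(stack, "pixel_size_um")
  n_frames <- dim(stack)[3]
  n_rej <- 0L
  dets <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    d <- suppressWarnings(
      detect_spheroids(unclass(stack)[, , f], px, size_gate, ...))
    n_rej <- n_rej + attr(d, "n_gate_rejected")
    if (nrow(d) > 0) {
      d$frame <- f - 1L
      dets[[f]] <- d
    }
  }
  out <- do.call(rbind, dets)
  if (is.null(out))
    out <- data.frame(x_um = numeric(), y_um = numeric(),
                      diameter_um = numeric(), intensity = numeric(),
                      frame = integer())
  rownames(out) <- NULL
  attr(out, "n_gate_rejected") <- n_rej
  out
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbor assignment between consecutive frames with a
#' flow-directional gate: a detection can extend a track if its downstream
#' displacement lies within `[-1 diameter, gate_factor * u_h * elapsed]`
#' and its lateral displacement within one diameter, where u_h is the
#' hydrodynamic transport velocity at the track's median diameter. The
#' assignment cost is the distance from the detection to the nearest of
#' three motion hypotheses for the track — stationary (arrest), free
#' convection at u_h, and the track's last observed velocity — so that
#' free transport, rolling and arrest are all linked correctly at 1 fps.
#' Unmatched detections open new tracks; a track tolerates up to `memory`
#' missed frames before closing. Input rows are stably sorted by frame
#' first, so linking is invariant to row-order permutations.
#'
#' @param detections data.frame with `frame`, `x_um`, `y_um`,
#'   `diameter_um` (as from [detect_stack()]).
#' @param flow A [flow_context()] (supplies the directional gate).
#' @param dt_s Frame interval (s); must be positive (calibration).
#' @param gate_factor Downstream gate in multiples of the expected free
#'   advance (default 1.5).
#' @param memory Missed frames tolerated (default 1).
#' @return Trajectory table (`frame`, `track_id`, `x_um`, `y_um`,
#'   `diameter_um`), sorted by track then frame.
#' @export
link_tracks <- function(detections, flow, dt_s = 1, gate_factor = 1.5,
                        memory = 1L) {
  stopifnot(inherits(flow, "flow_context"))
  if (!is.numeric(dt_s) || dt_s <= 0)
    stop("missing or invalid time calibration (dt_s)", call. = FALSE)
  need <- c("frame", "x_um", "y_um", "diameter_um")
  if (!all(need %in% names(detections)))
    stop("detections must have columns frame, x_um, y_um, diameter_um",
         call. = FALSE)
  det <- detections[order(detections$frame), , drop = FALSE]  # stable
  if (nrow(det) == 0)
    return(data.frame(frame = integer(), track_id = integer(),
                      x_um = numeric(), y_um = numeric(),
                      diameter_um = numeric()))
  # active track state
  tracks <- list()   # id -> list(x, y, frame, diam vector)
  assign_rows <- integer(nrow(det))   # track id per detection row
  next_id <- 1L
  for (f in sort(unique(det$frame))) {
    ridx <- which(det$frame == f)
    cand <- NULL
    for (tid in names(tracks)) {
      tr <- tracks[[tid]]
      gap <- f - tr$frame
      if (gap < 1 || gap > memory + 1) next
      d_tr <- stats::median(tr$diam)
      u_h <- hydrodynamic_velocity(flow, d_tr)
      max_dx <- gate_factor * u_h * gap * dt_s
      # motion-hypothesis predicted downstream advances
      pred_dx <- c(0, u_h * gap * dt_s)
      if (!is.null(tr$vx)) pred_dx <- c(pred_dx, tr$vx * gap)
      for (r in ridx) {
        dx <- det$x_um[r] - tr$x
        dy <- det$y_um[r] - tr$y
        if (dx < -d_tr || dx > max_dx || abs(dy) > d_tr) next
        cost <- sqrt(min((dx - pred_dx)^2) + dy^2)
        cand <- rbind(cand, data.frame(tid = as.integer(tid), r = r,
                                       cost = cost))
      }
    }
    used_t <- integer(0); used_r <- integer(0)
    if (!is.null(cand)) {
      cand <- cand[order(cand$cost), , drop = FALSE]
      for (i in seq_len(nrow(cand))) {
        if (cand$tid[i] %in% used_t || cand$r[i] %in% used_r) next
        tid <- cand$tid[i]; r <- cand$r[i]
        assign_rows[r] <- tid
        tr <- tracks[[as.character(tid)]]
        tr$vx <- (det$x_um[r] - tr$x) / (f - tr$frame)   # per-frame
        tr$x <- det$x_um[r]; tr$y <- det$y_um[r]; tr$frame <- f
        tr$diam <- c(tr$diam, det$diameter_um[r])
        tracks[[as.character(tid)]] <- tr
        used_t <- c(used_t, tid); used_r <- c(used_r, r)
      }
    }
    for (r in setdiff(ridx, used_r)) {
      assign_rows[r] <- next_id
      tracks[[as.character(next_id)]] <-
        list(x = det$x_um[r], y = det$y_um[r], frame = f,
             diam = det$diameter_um[r])
      next_id <- next_id + 1L
    }
    # drop stale tracks to keep the candidate scan small
    stale <- vapply(tracks, function(tr) f - tr$frame > memory + 1,
                    logical(1))
    tracks <- tracks[!stale]
  }
  out <- data.frame(frame = det$frame, track_id = assign_rows,
                    x_um = det$x_um, y_um = det$y_um,
                    diameter_um = det$diameter_um)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  out
}

#' Track quality-control report
#'
#' Pure summary of a track table: per-field counts, track-length
#' distribution, single-frame fraction and gate-rejection totals. Never
#' mutates its input.
#'
#' @param tracks Trajectory table.
#' @param n_gate_rejected Gate rejections carried over from detection
#'   (optional).
#' @return List: `n_tracks`, `n_detections`, `per_field` (data.frame),
#'   `track_length_table`, `fraction_single_frame`, `n_gate_rejected`.
#' @export
track_qc <- function(tracks, n_gate_rejected = NA_integer_) {
  if (nrow(tracks) == 0) {
    return(list(n_tracks = 0L, n_detections = 0L,
                per_field = data.frame(field_id = integer(),
                                       n_tracks = integer()),
                track_length_table = table(integer()),
                fraction_single_frame = NaN,
                n_gate_rejected = n_gate_rejected))
  }
  len <- table(tracks$track_id)
  per_field <- if ("field_id" %in% names(tracks)) {
    first <- tracks[!duplicated(tracks$track_id), ]
    as.data.frame(table(field_id = first$field_id),
                  responseName = "n_tracks")
  } else data.frame(field_id = NA_integer_,
                    n_tracks = length(unique(tracks$track_id)))
  list(n_tracks = length(len), n_detections = nrow(tracks),
       per_field = per_field,
       track_length_table = table(as.integer(len)),
       fraction_single_frame = mean(len == 1),
       n_gate_rejected = n_gate_rejected)
}

#' Evaluate tracking against simulator ground truth
#'
#' Matches recovered detections to ground-truth positions per frame
#' (nearest neighbor within a tolerance) and scores (a) link recovery —
#' the fraction of consecutive ground-truth observation pairs joined by
#' the same recovered track — and (b) identity switches — consecutive
#' recovered-track pairs whose matched truth ids differ.
#'
#' @param tracks Recovered trajectory table.
#' @param truth Ground-truth table (`frame`, `track_id`, `x_um`, `y_um`,
#'   `diameter_um`).
#' @param match_tol_um Matching tolerance (um), default 20.
#' @param fov_x_um Downstream field extent; when given, truth rows whose
#'   spheroid is not fully inside the field (center within one radius of
#'   the upstream or downstream edge) are excluded from link scoring — a
#'   partially visible spheroid is not detectable in principle.
#' @return List: `link_recovery`, `id_switch_rate`, `n_true_links`,
#'   `n_recovered_links`, `detection_recall`.
#' @export
evaluate_tracking <- function(tracks, truth, match_tol_um = 20,
                              fov_x_um = NULL) {
  if (!is.null(fov_x_um)) {
    r <- truth$diameter_um / 2
    truth <- truth[truth$x_um >= r & truth$x_um <= fov_x_um - r, ,
                   drop = FALSE]
  }
  truth <- truth[order(truth$track_id, truth$frame), ]
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  # match each recovered detection to a truth row on its frame
  truth_key <- rep(NA_integer_, nrow(tracks))
  for (f in unique(tracks$frame)) {
    ti <- which(truth$frame == f)
    ri <- which(tracks$frame == f)
    if (length(ti) == 0) next
    for (r in ri) {
      dd <- sqrt((truth$x_um[ti] - tracks$x_um[r])^2 +
                 (truth$y_um[ti] - tracks$y_um[r])^2)
      j <- which.min(dd)
      if (dd[j] <= match_tol_um) truth_key[r] <- truth$track_id[ti[j]]
    }
  }
  matched <- sum(!is.na(truth_key))
  # truth links recovered
  n_true <- 0L; n_rec <- 0L
  for (id in unique(truth$track_id)) {
    tf <- truth$frame[truth$track_id == id]
    if (length(tf) < 2) next
    pairs <- cbind(tf[-length(tf)], tf[-1])
    n_true <- n_true + nrow(pairs)
    for (p in seq_len(nrow(pairs))) {
      r1 <- which(tracks$frame == pairs[p, 1] & truth_key == id)
      r2 <- which(tracks$frame == pairs[p, 2] & truth_key == id)
      if (length(r1) && length(r2) &&
          any(outer(tracks$track_id[r1], tracks$track_id[r2], "==")))
        n_rec <- n_rec + 1L
    }
  }
  # identity switches along recovered tracks
  n_links <- 0L; n_switch <- 0L
  for (id in unique(tracks$track_id)) {
    i <- which(tracks$track_id == id)
    if (length(i) < 2) next
    keys <- truth_key[i]
    for (p in seq_len(length(i) - 1)) {
      if (is.na(keys[p]) || is.na(keys[p + 1])) next
      n_links <- n_links + 1L
      if (keys[p] != keys[p + 1]) n_switch <- n_switch + 1L
    }
  }
  list(link_recovery = if (n_true) n_rec / n_true else NaN,
       id_switch_rate = if (n_links) n_switch / n_links else NaN,
       n_true_links = n_true, n_recovered_links = n_rec,
       n_switches = n_switch, n_tracked_links = n_links,
       detection_recall = matched / nrow(truth))
}
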