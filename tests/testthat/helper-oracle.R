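# Independent brute-force oracles used by the tests. These deliberately
# re-derive everything from first principles (exhaustive window scans,
# textbook formulas) and share no code with the package implementation.

# exhaustive segment-scan motion classifier
oracle_classify <- function(track, u_ref, c_frac = 0.5, eps = 5,
                            min_stationary_frames = 2,
                            min_path_diameters = 1,
                            arrest = "terminal", dt = 1) {
  track <- track[order(track$frame), ]
  n <- nrow(track)
  if (n < 2) return("free")
  disp <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  dframes <- diff(track$frame)
  speed <- disp / (dframes * dt)
  disp_pf <- disp / dframes
  d_med <- stats::median(track$diameter_um)
  m <- length(speed)
  stationary <- disp_pf < eps
  slow <- speed < c_frac * u_ref | stationary

  # adhesion: any window [i,j] of all-stationary intervals covering enough
  # frames (and reaching the last interval in terminal mode)
  for (i in seq_len(m)) for (j in i:m) {
    if (all(stationary[i:j])) {
      frames_covered <- track$frame[j + 1] - track$frame[i] + 1
      if (frames_covered >= min_stationary_frames &&
          (arrest == "anywhere" || j == m))
        return("adhesion")
    }
  }
  # rolling: any all-slow window with path > min_path_diameters * d_med
  for (i in seq_len(m)) for (j in i:m) {
    if (all(slow[i:j]) && sum(disp[i:j]) > min_path_diameters * d_med)
      return("rolling")
  }
  # tethering: a slow interval with a later fast interval
  for (i in seq_len(m)) {
    if (slow[i] && i < m && any(!slow[(i + 1):m])) return("tethering")
  }
  "free"
}

# oracle rolling velocity: mean speed over the maximal all-slow window with
# the largest path among those exceeding the path threshold
oracle_rolling_velocity <- function(track, u_ref, c_frac = 0.5, eps = 5,
                                    min_path_diameters = 1, dt = 1) {
  track <- track[order(track$frame), ]
  disp <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  dframes <- diff(track$frame)
  speed <- disp / (dframes * dt)
  disp_pf <- disp / dframes
  d_med <- stats::median(track$diameter_um)
  slow <- speed < c_frac * u_ref | disp_pf < eps
  m <- length(speed)
  best <- NULL; best_path <- -Inf
  for (i in seq_len(m)) for (j in i:m) {
    if (!all(slow[i:j])) next
    maximal <- (i == 1 || !slow[i - 1]) && (j == m || !slow[j + 1])
    if (!maximal) next
    path <- sum(disp[i:j])
    if (path > min_path_diameters * d_med && path > best_path) {
      best_path <- path; best <- mean(speed[i:j])
    }
  }
  best
}

# random track with arbitrary speed patterns (mixture of arrest / slow /
# fast intervals, occasional frame gaps)
random_oracle_track <- function(u_ref = 134, d = NULL) {
  if (is.null(d)) d <- stats::runif(1, 70, 100)
  n_int <- sample(1:25, 1)
  kind <- sample(c("arrest", "slow", "fast"), n_int, replace = TRUE,
                 prob = c(0.3, 0.35, 0.35))
  step <- vapply(kind, function(k) switch(k,
    arrest = abs(stats::rnorm(1, 0, 2)),
    slow = stats::runif(1, 6, 0.49 * u_ref),
    fast = stats::runif(1, 0.51 * u_ref, 2 * u_ref)), numeric(1))
  frames <- cumsum(c(0, ifelse(stats::runif(n_int) < 0.1, 2, 1)))
  x <- cumsum(c(0, step * diff(frames)))
  data.frame(frame = frames, track_id = 1L, x_um = x,
             y_um = stats::rnorm(n_int + 1, 0, 0.5), diameter_um = d)
}

# textbook statistics
oracle_chi2_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

oracle_chi2_rxk <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}
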