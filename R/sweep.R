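#' Two-condition shear-stress sweep
#'
#' The assay's central experiment: for each shear level of the grid,
#' simulate both conditions at that shear, classify every track, summarize
#' the cohorts, and compare conditions with chi-square tests on adhesion
#' and tethering counts (and a one-tailed t test on rolling velocities
#' where both cohorts roll). The default grid is the ascitic range
#' 0.03-0.15 dyn cm-2.
#'
#' @param config_a,config_b [simulation_config()] templates for the two
#'   conditions; their flow context is rebuilt at each grid shear (same
#'   geometry, fluid and k_wall).
#' @param shear_grid Shear levels (dyn cm-2), non-empty.
#' @param params A [classification_params()].
#' @return List of class `shear_sweep`: `summaries` (one row per condition
#'   per shear), `stats` (per-shear comparisons), `classified` (list keyed
#'   by shear level).
#' @export
run_shear_sweep <- function(config_a, config_b,
                            shear_grid = c(0.03, 0.04, 0.05, 0.07, 0.1,
                                           0.15),
                            params = classification_params()) {
  stopifnot(inherits(config_a, "simulation_config"),
            inherits(config_b, "simulation_config"))
  if (length(shear_grid) == 0) stop("empty shear grid", call. = FALSE)
  summaries <- list(); stats_rows <- list(); classified <- list()
  for (tau in shear_grid) {
    fa <- flow_context(config_a$flow$geometry, config_a$flow$fluid,
                       shear_dyn_cm2 = tau, k_wall = config_a$flow$k_wall)
    ca <- config_a; ca$flow <- fa
    cb <- config_b; cb$flow <- fa
    sim_a <- simulate_trajectories(ca)
    sim_b <- simulate_trajectories(cb)
    cl_a <- classify_cohort(sim_a$trajectories, fa, params, ca$dt_s)
    cl_b <- classify_cohort(sim_b$trajectories, fa, params, cb$dt_s)
    sum_a <- summarize_cohort(cl_a, ca$condition, tau,
                              params$count_single_frame)
    sum_b <- summarize_cohort(cl_b, cb$condition, tau,
                              params$count_single_frame)
    summaries[[length(summaries) + 1]] <- rbind(sum_a, sum_b)
    cmp <- compare_cohorts(sum_a, sum_b,
                           rolling_velocities(cl_a),
                           rolling_velocities(cl_b))
    if (!is.null(cmp)) {
      cmp$shear_dyn_cm2 <- tau
      stats_rows[[length(stats_rows) + 1]] <- cmp
    }
    classified[[as.character(tau)]] <- list(a = cl_a, b = cl_b)
  }
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL
  stats_tab <- if (length(stats_rows)) do.call(rbind, stats_rows) else NULL
  structure(list(summaries = summaries, stats = stats_tab,
                 classified = classified, shear_grid = shear_grid),
            class = "shear_sweep")
}

#' Shear level of maximal adhesion for one condition
#'
#' @param sweep A [run_shear_sweep()] result (or its `summaries` table).
#' @param condition Condition label.
#' @param what Summary column to maximize (default `"pct_adhesion"`).
#' @return The shear level (dyn cm-2) at which the column is maximal.
#' @export
optimal_shear <- function(sweep, condition, what = "pct_adhesion") {
  tab <- if (inherits(sweep, "shear_sweep")) sweep$summaries else sweep
  tab <- tab[tab$condition == condition, ]
  tab$shear_dyn_cm2[which.max(tab[[what]])]
}

#' Run a detachment-ramp experiment end to end
#'
#' Simulates ramp-driven detachment of an initially adherent population,
#' then recomputes the survival curve from the per-step observation blocks
#' with the measurement-side [detachment_fraction()], returning both
#' curves.
#'
#' @param config A [simulation_config()].
#' @param ramp A [make_shear_ramp()].
#' @param n_adherent Initially adherent spheroids.
#' @param params A [classification_params()] for the measured curve.
#' @return List: `simulated` (generator survival), `measured`
#'   (position-derived survival), `ramp`.
#' @export
run_detachment <- function(config, ramp, n_adherent = 50,
                           params = classification_params()) {
  sim <- simulate_detachment(config, ramp, n_adherent)
  measured <- detachment_fraction(sim$initial_ids, sim$blocks, ramp,
                                  params, config$dt_s)
  list(simulated = sim$survival, measured = measured, ramp = ramp)
}

#' Markdown report juxtaposing two conditions across shear levels
#'
#' @param sweep A [run_shear_sweep()] result.
#' @param path Output markdown path (NULL returns the lines invisibly).
#' @return Character vector of markdown lines, invisibly.
#' @export
sweep_report_md <- function(sweep, path = NULL) {
  s <- sweep$summaries
  lines <- c("# Shear sweep report", "",
             "| shear (dyn/cm2) | condition | n | % tether | % adhesion | median rolling v (um/s) |",
             "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf(
      "| %.3g | %s | %d | %.1f | %.1f | %s |",
      s$shear_dyn_cm2[i], s$condition[i], s$n_total[i], s$pct_tether[i],
      s$pct_adhesion[i],
      if (is.na(s$median_rolling_velocity_um_s[i])) "-" else
        sprintf("%.1f", s$median_rolling_velocity_um_s[i])))
  }
  if (!is.null(sweep$stats)) {
    lines <- c(lines, "", "## Condition comparisons", "",
               "| shear | comparison | statistic | df | p | |",
               "|---|---|---|---|---|---|")
    st <- sweep$stats
    for (i in seq_len(nrow(st))) {
      lines <- c(lines, sprintf("| %.3g | %s | %.3f | %.3g | %.3g | %s |",
                                st$shear_dyn_cm2[i], st$comparison[i],
                                st$statistic[i], st$df[i], st$p_value[i],
                                st$stars[i]))
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
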