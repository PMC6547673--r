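#' Parallel-plate channel geometry
#'
#' Describes the rectangular microchannel the spheroids are perfused
#' through. Width must exceed height (plate approximation) and the channel
#' must be tall enough to admit the spheroids flowing through it.
#'
#' @param width_um Channel width w (um), the transverse dimension.
#' @param height_um Channel height h (um), the plate gap.
#' @param length_um Channel length (um).
#' @param fov_x_um,fov_y_um Imaged field of view extents (um); x is the
#'   downstream direction, origin at the upstream-left corner of the field.
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(width_um = 1000, height_um = 100,
                             length_um = 20000,
                             fov_x_um = 3300, fov_y_um = 2500) {
  if (!is.numeric(width_um) || !is.numeric(height_um) ||
      height_um <= 0 || width_um <= height_um)
    stop("invalid geometry: require width_um > height_um > 0", call. = FALSE)
  if (fov_x_um <= 0 || fov_y_um <= 0 || length_um <= 0)
    stop("invalid geometry: extents must be positive", call. = FALSE)
  structure(list(width_um = width_um, height_um = height_um,
                 length_um = length_um,
                 fov_x_um = fov_x_um, fov_y_um = fov_y_um),
            class = "channel_geometry")
}

#' Fluid properties of the perfusion buffer
#'
#' @param viscosity_cP Dynamic viscosity in centipoise. The default 0.9 cP
#'   is the viscosity of the binding buffer, within the measured range of
#'   ascitic fluid.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(viscosity_cP = 0.9) {
  if (!is.numeric(viscosity_cP) || viscosity_cP <= 0)
    stop("viscosity must be positive", call. = FALSE)
  structure(list(viscosity_cP = viscosity_cP), class = "fluid_properties")
}

#' Wall shear stress from volumetric flow rate
#'
#' Plane-Poiseuille relation for a wide rectangular channel,
#' tau = 6 mu Q / (w h^2), evaluated in CGS and reported in dyn cm-2.
#'
#' @param geometry A [channel_geometry()].
#' @param fluid A [fluid_properties()].
#' @param flow_rate_uL_min Volumetric flow rate Q (uL min-1), >= 0.
#' @return Wall shear stress tau in dyn cm-2.
#' @export
wall_shear_from_flow_rate <- function(geometry, fluid, flow_rate_uL_min) {
  stopifnot(inherits(geometry, "channel_geometry"),
            inherits(fluid, "fluid_properties"))
  if (any(flow_rate_uL_min < 0)) stop("flow rate must be >= 0", call. = FALSE)
  mu_P <- fluid$viscosity_cP / 100           # poise = dyn s cm-2
  Q_cm3_s <- flow_rate_uL_min * 1e-3 / 60
  w_cm <- geometry$width_um * 1e-4
  h_cm <- geometry$height_um * 1e-4
  6 * mu_P * Q_cm3_s / (w_cm * h_cm^2)
}

#' Volumetric flow rate producing a target wall shear stress
#'
#' Exact inverse of [wall_shear_from_flow_rate()].
#'
#' @inheritParams wall_shear_from_flow_rate
#' @param shear_dyn_cm2 Target wall shear stress (dyn cm-2), >= 0.
#' @return Flow rate Q in uL min-1.
#' @export
flow_rate_from_shear <- function(geometry, fluid, shear_dyn_cm2) {
  stopifnot(inherits(geometry, "channel_geometry"),
            inherits(fluid, "fluid_properties"))
  if (any(shear_dyn_cm2 < 0)) stop("shear stress must be >= 0", call. = FALSE)
  mu_P <- fluid$viscosity_cP / 100
  w_cm <- geometry$width_um * 1e-4
  h_cm <- geometry$height_um * 1e-4
  Q_cm3_s <- shear_dyn_cm2 * w_cm * h_cm^2 / (6 * mu_P)
  Q_cm3_s * 60 / 1e-3
}

#' Flow context: geometry, fluid and imposed flow
#'
#' Binds the channel geometry and fluid to an imposed flow, given either as
#' a wall shear stress or a flow rate (the other is derived so the two stay
#' mutually consistent under the plate formula).
#'
#' @inheritParams wall_shear_from_flow_rate
#' @param shear_dyn_cm2 Imposed wall shear stress (dyn cm-2); give this or
#'   `flow_rate_uL_min`.
#' @param flow_rate_uL_min Imposed flow rate (uL min-1).
#' @param k_wall Dimensionless near-wall drag correction in (0, 1] applied
#'   to the free-transport velocity of a spheroid translating next to the
#'   wall. The default 0.5676 is the classical translation factor for a
#'   sphere in contact with a plane wall in linear shear; `k_wall = 1`
#'   recovers the undisturbed fluid velocity at the sphere's center height.
#' @return An object of class `flow_context` with fields `geometry`,
#'   `fluid`, `shear_dyn_cm2`, `flow_rate_uL_min`, `k_wall`.
#' @export
flow_context <- function(geometry = channel_geometry(),
                         fluid = fluid_properties(),
                         shear_dyn_cm2 = NULL, flow_rate_uL_min = NULL,
                         k_wall = 0.5676) {
  if (is.null(shear_dyn_cm2) == is.null(flow_rate_uL_min))
    stop("give exactly one of shear_dyn_cm2 or flow_rate_uL_min",
         call. = FALSE)
  if (k_wall <= 0 || k_wall > 1)
    stop("k_wall must be in (0, 1]", call. = FALSE)
  if (is.null(shear_dyn_cm2)) {
    shear_dyn_cm2 <- wall_shear_from_flow_rate(geometry, fluid,
                                               flow_rate_uL_min)
  } else {
    flow_rate_uL_min <- flow_rate_from_shear(geometry, fluid, shear_dyn_cm2)
  }
  structure(list(geometry = geometry, fluid = fluid,
                 shear_dyn_cm2 = shear_dyn_cm2,
                 flow_rate_uL_min = flow_rate_uL_min,
                 k_wall = k_wall),
            class = "flow_context")
}

#' @export
print.flow_context <- function(x, ...) {
  cat(sprintf(
    "flow_context: tau = %.4g dyn cm-2, Q = %.4g uL min-1, mu = %.3g cP\n",
    x$shear_dyn_cm2, x$flow_rate_uL_min, x$fluid$viscosity_cP))
  cat(sprintf("  channel %g x %g um, fov %g x %g um, k_wall = %.4g\n",
              x$geometry$width_um, x$geometry$height_um,
              x$geometry$fov_x_um, x$geometry$fov_y_um, x$k_wall))
  invisible(x)
}

#' Near-wall hydrodynamic transport velocity of a spheroid
#'
#' Speed at which a non-interacting spheroid is carried by the near-wall
#' shear flow: the linear-shear fluid velocity at the spheroid's center
#' height, u = (tau/mu) * d/2, scaled by the near-wall drag correction
#' `k_wall` of the flow context. This is the reference velocity that the
#' rolling criterion compares against.
#'
#' @param flow A [flow_context()].
#' @param diameter_um Spheroid diameter d (um), 0 < d < channel height.
#' @return Transport velocity u_h in um s-1 (vectorized over `diameter_um`).
#' @export
hydrodynamic_velocity <- function(flow, diameter_um) {
  stopifnot(inherits(flow, "flow_context"))
  if (any(diameter_um <= 0) || any(diameter_um >= flow$geometry$height_um))
    stop("spheroid diameter must lie in (0, channel height)", call. = FALSE)
  mu_P <- flow$fluid$viscosity_cP / 100
  shear_rate <- flow$shear_dyn_cm2 / mu_P     # s-1
  flow$k_wall * shear_rate * diameter_um / 2
}

#' Stepwise shear-stress ramp schedule
#'
#' Builds the schedule of shear steps used by the detachment assay: shear is
#' raised stepwise and held at each level while adherent spheroids are
#' observed.
#'
#' @param start_dyn_cm2,max_dyn_cm2 First and last shear levels (dyn cm-2),
#'   0 <= start <= max. The last step equals `max_dyn_cm2` exactly.
#' @param n_steps Number of steps (>= 1).
#' @param hold_s Hold duration per step (s), or a vector of length `n_steps`.
#' @param spacing `"linear"` or `"geometric"` step spacing (geometric
#'   requires start > 0).
#' @return A data.frame of class `shear_ramp` with columns `step`,
#'   `tau_dyn_cm2`, `hold_s`.
#' @export
make_shear_ramp <- function(start_dyn_cm2, max_dyn_cm2, n_steps, hold_s = 30,
                            spacing = c("linear", "geometric")) {
  spacing <- match.arg(spacing)
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  if (start_dyn_cm2 < 0 || start_dyn_cm2 > max_dyn_cm2)
    stop("require 0 <= start <= max", call. = FALSE)
  if (any(hold_s <= 0)) stop("hold durations must be positive", call. = FALSE)
  tau <- if (n_steps == 1) max_dyn_cm2
  else if (spacing == "linear") seq(start_dyn_cm2, max_dyn_cm2,
                                    length.out = n_steps)
  else {
    if (start_dyn_cm2 <= 0)
      stop("geometric spacing requires start > 0", call. = FALSE)
    exp(seq(log(start_dyn_cm2), log(max_dyn_cm2), length.out = n_steps))
  }
  tau[n_steps] <- max_dyn_cm2
  out <- data.frame(step = seq_len(n_steps), tau_dyn_cm2 = tau,
                    hold_s = rep_len(hold_s, n_steps))
  class(out) <- c("shear_ramp", "data.frame")
  out
}
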