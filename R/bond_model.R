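#' Catch-slip adhesion bond model
#'
#' Kinetic parameters of the stochastic tether / roll / arrest model that
#' generates synthetic spheroid cohorts. The tether-scale off-rate follows
#' the two-pathway catch-slip law
#' \deqn{k_{off}(\tau) = a\,e^{-\tau/f_c} + b\,e^{\tau/f_s},}
#' with force proxied by wall shear stress, so bond lifetime peaks at an
#' intermediate shear — the signature of a catch bond with a threshold
#' shear for efficient capture. Firm (arrested) spheroids engage many bonds
#' that share load, so ramp-driven detachment of firm adhesion is governed
#' by a separate, much slower slip law
#' \deqn{k_{off}^{firm}(\tau) = b_f\,e^{\tau/f_{s,f}}.}
#'
#' All rate defaults are calibration artifacts of this package (no kinetic
#' rates are available for the real system); they are calibrated once so
#' that the capture optimum of a shear sweep sits at 0.05 dyn cm-2 and the
#' firm-bond survival curve vanishes by a 4 dyn cm-2 ramp end.
#'
#' @param k_on Bond formation rate while in wall contact (s-1); also the
#'   rate at which a tethered spheroid engages successive bonds and
#'   transitions into rolling.
#' @param a,f_c Catch-pathway amplitude (s-1) and shear scale (dyn cm-2).
#' @param b,f_s Slip-pathway amplitude (s-1) and shear scale (dyn cm-2).
#' @param k_arrest Rate of conversion to firm adhesion (s-1), from the
#'   tethered or rolling state.
#' @param release_to_free_rate Shear-independent baseline release rate of a
#'   tether (s-1), added to `k_off(tau)`.
#' @param rolling_speed_fraction rho in [0, 1): rolling translation speed as
#'   a fraction of the hydrodynamic transport velocity.
#' @param firm_slip_amplitude,firm_slip_scale Firm-bond slip law parameters
#'   b_f (s-1) and f_sf (dyn cm-2) used by the detachment ramp.
#' @param edta_koff_factor Multiplier applied to all off-rates in EDTA mode
#'   (calcium chelation abolishes selectin bonds); EDTA mode also sets
#'   `k_on` to zero.
#' @return An object of class `bond_model`.
#' @export
bond_model <- function(k_on = 0.06,
                       a = 1500, f_c = 0.005,
                       b = 0.06, f_s = 0.04,
                       k_arrest = 0.12,
                       release_to_free_rate = 0.1,
                       rolling_speed_fraction = 0.3,
                       firm_slip_amplitude = 4e-4,
                       firm_slip_scale = 0.45,
                       edta_koff_factor = 1000) {
  rates <- c(k_on, a, f_c, b, f_s, k_arrest, release_to_free_rate,
             firm_slip_amplitude, firm_slip_scale, edta_koff_factor)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("bond model rates and scales must be finite and >= 0",
         call. = FALSE)
  if (rolling_speed_fraction < 0 || rolling_speed_fraction >= 1)
    stop("rolling_speed_fraction must be in [0, 1)", call. = FALSE)
  structure(list(k_on = k_on, a = a, f_c = f_c, b = b, f_s = f_s,
                 k_arrest = k_arrest,
                 release_to_free_rate = release_to_free_rate,
                 rolling_speed_fraction = rolling_speed_fraction,
                 firm_slip_amplitude = firm_slip_amplitude,
                 firm_slip_scale = firm_slip_scale,
                 edta_koff_factor = edta_koff_factor),
            class = "bond_model")
}

#' Tether-scale off-rate of the catch-slip bond
#'
#' @param bond A [bond_model()].
#' @param tau_dyn_cm2 Wall shear stress (dyn cm-2), vectorized.
#' @return Off-rate k_off(tau) in s-1.
#' @export
bond_off_rate <- function(bond, tau_dyn_cm2) {
  stopifnot(inherits(bond, "bond_model"))
  catch <- if (bond$a > 0) bond$a * exp(-tau_dyn_cm2 / bond$f_c) else 0
  slip <- if (bond$b > 0) bond$b * exp(tau_dyn_cm2 / bond$f_s) else 0
  catch + slip
}

#' Firm-bond rupture rate under applied shear
#'
#' @inheritParams bond_off_rate
#' @param edta Logical; apply the EDTA off-rate multiplier.
#' @return Rupture rate in s-1.
#' @export
firm_off_rate <- function(bond, tau_dyn_cm2, edta = FALSE) {
  stopifnot(inherits(bond, "bond_model"))
  r <- bond$firm_slip_amplitude * exp(tau_dyn_cm2 / bond$firm_slip_scale)
  if (edta) r <- r * bond$edta_koff_factor
  r
}
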