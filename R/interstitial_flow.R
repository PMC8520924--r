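#' Series hydraulic resistance of a porous layer stack
#'
#' For Darcy flow through layers in series the resistances add:
#' \eqn{R = \sum_i L_i / K_i} (units 1/m). With the measured permeabilities
#' the 2-mm COL1 gel contributes 1.92e10 1/m and the 10-um endothelial
#' monolayer 4.07e10 1/m.
#'
#' @param layers list of [porous_layer()] objects.
#' @return total resistance in 1/m.
#' @export
series_resistance <- function(layers) {
  if (length(layers) < 1L) stop("'layers' must contain at least one layer")
  sum(vapply(layers, function(l) l$thickness / l$permeability, numeric(1)))
}

#' Darcy interstitial velocity under a hydrostatic head difference
#'
#' \deqn{v = \frac{\rho g \Delta h}{\mu \sum_i L_i/K_i}.}
#' With the default layer stack (2-mm COL1 gel at K = 1.04e-13 m^2 plus a
#' 10-um endothelial monolayer at K = 2.46e-16 m^2) and a 3-mm water head
#' this evaluates to 0.49 um/s.
#'
#' @param head_difference hydrostatic head difference (m); sign carries.
#' @param fluid a [fluid()].
#' @param layers list of [porous_layer()].
#' @return superficial Darcy velocity in m/s.
#' @export
darcy_velocity <- function(head_difference, fluid = lymphchip::fluid(),
                           layers = default_config()$layers) {
  R <- series_resistance(layers)
  fluid$density * fluid$g * head_difference / (fluid$viscosity * R)
}

#' Peclet number
#'
#' Ratio of convective to diffusive transport, `Pe = v L / D`. The default
#' length scale downstream is the ECM channel width (2 mm), the distance a
#' solute traverses across the gel.
#'
#' @param velocity m/s.
#' @param length_scale m.
#' @param diffusivity m^2/s.
#' @return dimensionless Peclet number.
#' @export
peclet <- function(velocity, length_scale, diffusivity) {
  .check_positive(length_scale, "length_scale")
  .check_positive(diffusivity, "diffusivity")
  velocity * length_scale / diffusivity
}

.reservoir_area <- function(geometry) {
  geometry$n_reservoirs_per_channel *
    pi * geometry$medium_reservoir_diameter^2 / 4
}

#' Transient decay of the hydrostatic head between two reservoir sets
#'
#' Integrates the closed two-reservoir system
#' \deqn{\frac{d\Delta h}{dt} = -Q(t)\left(\frac{1}{A_1}+\frac{1}{A_2}\right),
#'   \qquad Q = v\,A_{\mathrm{interface}},}
#' with `v` from [darcy_velocity()]. The ODE is linear, so the integrator
#' (classical fixed-step RK4 via deSolve) can be checked against the closed
#' form \eqn{\Delta h(t) = \Delta h_0 e^{-t/\tau}} with
#' \eqn{\tau = \mu R / (\rho g A_{\mathrm{interface}} (1/A_1 + 1/A_2))}.
#'
#' The gel interface area is `channel_length x ecm_channel_height`, and each
#' reservoir set is `n_reservoirs_per_channel` punched wells of
#' `medium_reservoir_diameter`; both depend on the configurable channel
#' length, which is echoed in the metadata. Alternatively `tau` may be
#' supplied directly (see [calibrate_tau()]), bypassing the geometric
#' derivation.
#'
#' @param head0 initial head difference (m), >= 0.
#' @param geometry a [device_geometry()].
#' @param fluid a [fluid()].
#' @param layers list of [porous_layer()].
#' @param t_end total simulated time (s); default 24 h.
#' @param dt output/integration step (s); default 60.
#' @param solutes optional list of [solute()]; Peclet time series are
#'   computed per solute from its gel diffusivity.
#' @param length_scale Peclet length scale (m); default the ECM channel width.
#' @param tau optional decay time constant (s) overriding the geometric one.
#' @return a `flow_state` data.frame with columns `time, head, velocity,
#'   flow` and one `Pe_<solute>` column per solute; attributes `tau`,
#'   `resistance`, `v0`, `channel_length`, `interface_area`,
#'   `reservoir_area`.
#' @export
head_decay <- function(head0, geometry = device_geometry(),
                       fluid = lymphchip::fluid(),
                       layers = default_config()$layers,
                       t_end = 24 * 3600, dt = 60,
                       solutes = default_config()$solutes,
                       length_scale = geometry$ecm_channel_width,
                       tau = NULL) {
  if (head0 < 0) stop("'head0' must be >= 0")
  if (dt <= 0 || t_end < dt) stop("need dt > 0 and t_end >= dt")
  R <- series_resistance(layers)
  A_int <- geometry$channel_length * geometry$ecm_channel_height
  A_res <- .reservoir_area(geometry)
  tau_geom <- fluid$viscosity * R /
    (fluid$density * fluid$g * A_int * (1 / A_res + 1 / A_res))
  if (is.null(tau)) tau <- tau_geom
  times <- seq(0, t_end, by = dt)
  # two reservoir levels as separate states: RK4 stages see the same Q, so
  # volume lost by one reservoir equals volume gained by the other to
  # roundoff at every step
  if (head0 == 0) {
    lv <- matrix(0, nrow = length(times), ncol = 2)
  } else {
    rate <- 1 / (tau * 2)  # each level covers half the head relaxation
    sol <- deSolve::ode(y = c(l1 = head0 / 2, l2 = -head0 / 2),
                        times = times,
                        func = function(t, y, p) {
                          q <- (y[1] - y[2]) * p$rate
                          list(c(-q, q))
                        },
                        parms = list(rate = rate), method = "rk4")
    lv <- sol[, c("l1", "l2"), drop = FALSE]
  }
  h <- lv[, 1] - lv[, 2]
  v <- fluid$density * fluid$g * h / (fluid$viscosity * R)
  Q <- v * A_int
  out <- data.frame(time = times, head = h, velocity = v, flow = Q,
                    level_high = lv[, 1], level_low = lv[, 2])
  for (s in solutes) {
    out[[paste0("Pe_", s$name)]] <- peclet(v, length_scale, s$gel_diffusivity)
  }
  structure(out, class = c("flow_state", "data.frame"),
            tau = tau, resistance = R, v0 = v[1],
            channel_length = geometry$channel_length,
            interface_area = A_int, reservoir_area = A_res,
            length_scale = length_scale)
}

#' Calibrate the head-decay time constant to measured velocity endpoints
#'
#' The geometric time constant depends on the channel length, which is
#' configurable rather than measured; given an observed velocity pair
#' (start, end of an interval) the exponential decay fixes
#' \eqn{\tau = t / \ln(v_0 / v_t)}. The measured endpoints of the device are
#' 0.49 and 0.09 um/s over 24 h.
#'
#' @param v_start velocity at t = 0 (any consistent units).
#' @param v_end velocity at `t_interval`.
#' @param t_interval elapsed time (s); default 24 h.
#' @return tau in seconds.
#' @export
calibrate_tau <- function(v_start = 0.49e-6, v_end = 0.09e-6,
                          t_interval = 24 * 3600) {
  .check_positive(v_start, "v_start")
  .check_positive(v_end, "v_end")
  .check_positive(t_interval, "t_interval")
  if (v_end >= v_start) stop("'v_end' must be smaller than 'v_start'")
  t_interval / log(v_start / v_end)
}

#' Two-reservoir volume bookkeeping for a flow state
#'
#' Cumulative volume lost by the high reservoir and gained by the low
#' reservoir, from the integrated reservoir levels, and their maximum
#' relative mismatch (conservation drift).
#'
#' @param state a `flow_state` from [head_decay()].
#' @return list with `v_out`, `v_in`, `max_rel_drift`.
#' @export
reservoir_volumes <- function(state) {
  A <- attr(state, "reservoir_area")
  v_out <- (state$level_high[1] - state$level_high) * A
  v_in <- (state$level_low - state$level_low[1]) * A
  denom <- max(abs(v_out), .Machine$double.eps)
  list(v_out = v_out, v_in = v_in,
       max_rel_drift = max(abs(v_out - v_in)) / denom)
}
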