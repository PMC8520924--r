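#' Meniscus (burst) pressure of a pinned meniscus in a rectangular channel
#'
#' Maximum pressure a meniscus pinned at the ECM-channel step edge withstands
#' before the hydrogel precursor bursts into the neighbouring channel.
#' Young-Laplace for a rectangular cross-section,
#' \deqn{\Delta P = -2\sigma\left(\frac{\cos\theta^*_h}{h} +
#'   \frac{\cos\theta^*_w}{w}\right),}
#' where the step edge augments each contact angle by the Gibbs pinning
#' criterion \eqn{\theta^* = \min(\theta + \beta, 180^\circ)} with
#' \eqn{\beta} the edge expansion angle. The value returned is the burst
#' pressure, floored at zero (a meniscus that cannot pin withstands nothing).
#'
#' @param sigma surface tension (N/m).
#' @param contact_angle_top_bottom equilibrium contact angle on the top and
#'   bottom walls (deg, acting over the channel height).
#' @param contact_angle_side equilibrium contact angle on the side walls
#'   (deg, acting over the channel width).
#' @param edge_expansion_angle Gibbs edge expansion angle at the step (deg).
#' @param channel_height,channel_width cross-section (m).
#' @return burst pressure in Pa (>= 0).
#' @export
meniscus_pressure <- function(sigma, contact_angle_top_bottom = 120,
                              contact_angle_side = 120,
                              edge_expansion_angle = 60,
                              channel_height = 1e-3, channel_width = 2e-3) {
  .check_positive(sigma, "sigma")
  .check_positive(channel_height, "channel_height")
  .check_positive(channel_width, "channel_width")
  for (a in c(contact_angle_top_bottom, contact_angle_side)) {
    if (a <= 0 || a > 180) stop("contact angles must lie in (0, 180] degrees")
  }
  if (edge_expansion_angle < 0) stop("edge_expansion_angle must be >= 0")
  th_h <- min(contact_angle_top_bottom + edge_expansion_angle, 180)
  th_w <- min(contact_angle_side + edge_expansion_angle, 180)
  dp <- -2 * sigma * (cospi(th_h / 180) / channel_height +
                      cospi(th_w / 180) / channel_width)
  max(dp, 0)
}

#' Poiseuille filling pressure of the hydrogel precursor
#'
#' Pressure drop driving laminar flow of the COL1 precursor along the filled
#' length of a rectangular duct, with the first-order aspect-ratio
#' correction:
#' \deqn{\Delta P = \frac{12\,\mu L Q}{w h^3 (1 - 0.63\,h/w)}.}
#' Valid for \eqn{w \ge h}; callers with a taller-than-wide duct should swap
#' the axes.
#'
#' @param flow_rate volumetric filling rate Q (m^3/s).
#' @param viscosity precursor viscosity (Pa s); COL1 precursor default 0.01.
#' @param channel_width,channel_height duct cross-section (m), `width >= height`.
#' @param filled_length length of duct already filled (m).
#' @return pressure drop in Pa.
#' @export
filling_pressure <- function(flow_rate, viscosity = 0.01,
                             channel_width = 2e-3, channel_height = 1e-3,
                             filled_length = 10e-3) {
  .check_positive(flow_rate, "flow_rate")
  .check_positive(viscosity, "viscosity")
  .check_positive(channel_width, "channel_width")
  .check_positive(channel_height, "channel_height")
  .check_positive(filled_length, "filled_length")
  if (channel_height > channel_width) {
    stop("channel_height exceeds channel_width; swap the axes so that ",
         "width >= height")
  }
  12 * viscosity * filled_length * flow_rate /
    (channel_width * channel_height^3 *
       (1 - 0.63 * channel_height / channel_width))
}

#' Filling stability map over a range of fill rates
#'
#' For each volumetric filling rate, compares the Poiseuille filling
#' pressure against the meniscus burst pressure at the step edge; the gel
#' stays confined while the margin `p_meniscus - p_filling` is positive.
#' When the margin changes sign inside the scanned range, the critical rate
#' is located by bisection (relative tolerance 1e-6).
#'
#' @param fill_rates volumetric rates to scan (m^3/s).
#' @param geometry a [device_geometry()].
#' @param fluid a [fluid()] (supplies the surface tension).
#' @param viscosity precursor viscosity (Pa s).
#' @param contact_angle_top_bottom,contact_angle_side,edge_expansion_angle
#'   pinning parameters, degrees (see [meniscus_pressure()]).
#' @return a data.frame with one row per rate
#'   (`fill_rate, p_filling, p_meniscus, margin, stable`) and attributes
#'   `critical_rate` (NA when no transition in range) and `channel_length`.
#' @export
filling_stability_map <- function(fill_rates, geometry = device_geometry(),
                                  fluid = lymphchip::fluid(),
                                  viscosity = 0.01,
                                  contact_angle_top_bottom = 120,
                                  contact_angle_side = 120,
                                  edge_expansion_angle = 60) {
  if (length(fill_rates) < 1L) stop("'fill_rates' must be nonempty")
  pm <- meniscus_pressure(fluid$surface_tension,
                          contact_angle_top_bottom, contact_angle_side,
                          edge_expansion_angle,
                          geometry$ecm_channel_height,
                          geometry$ecm_channel_width)
  pf <- function(q) filling_pressure(q, viscosity,
                                     geometry$ecm_channel_width,
                                     geometry$ecm_channel_height,
                                     geometry$channel_length)
  p_fill <- vapply(fill_rates, pf, numeric(1))
  margin <- pm - p_fill
  out <- data.frame(fill_rate = fill_rates, p_filling = p_fill,
                    p_meniscus = pm, margin = margin, stable = margin > 0)
  crit <- NA_real_
  if (any(margin > 0) && any(margin <= 0)) {
    lo <- max(fill_rates[margin > 0])
    hi <- min(fill_rates[margin <= 0])
    crit <- stats::uniroot(function(q) pm - pf(q), c(lo, hi),
                           tol = lo * 1e-6)$root
  } else if (pm > 0) {
    # margin is linear in Q: the closed-form crossing, reported even when
    # outside the scanned range
    crit <- pm / (pf(1))
  }
  attr(out, "critical_rate") <- crit
  attr(out, "channel_length") <- geometry$channel_length
  out
}
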