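# Loading protocols and shock-pulse dosimetry.
#
# The clinical dose measure is the energy flux density (EFD, a.k.a. PII):
# the acoustic intensity integrated over the positive-pressure time,
# PII = I * Tp with plane-wave intensity I = rho*c*v^2/2, i.e.
# PII = v^2 * Z * Tp / 2 with Z = rho*c the acoustic impedance of the
# medium facing the applicator. Tp is the time for the pressure pulse to
# reach 90% of its positive maximum.

#' Construct a shock pulse
#'
#' A single smooth positive velocity lobe
#' `v(t) = v_peak * sin^2(pi t / t_total)` for `t <= t_total`. Either the
#' peak velocity or a target energy flux density must be given; with
#' `efd_target` the amplitude is calibrated through [calibrate_pulse()].
#'
#' @param efd_target target energy flux density, J/m^2 (0.12 mJ/mm^2 =
#'   120 J/m^2). Ignored when `v_peak` is given.
#' @param v_peak peak particle velocity, m/s.
#' @param t_total pulse duration, s (default 5 microseconds, the clinical
#'   shockwave time scale).
#' @param Z acoustic impedance of the coupled medium, kg m^-2 s^-1
#'   (default water-like 1.5e6; the saturated soft tissues of the model all
#'   have undrained impedance within ~10% of this).
#' @return A list of class `shock_pulse` with fields `v_peak, t_total, Tp,
#'   Z, PII`.
#' @examples
#' shock_pulse(efd_target = 0.33e3)  # 0.33 mJ/mm^2
#' @export
shock_pulse <- function(efd_target = NULL, v_peak = NULL, t_total = 5e-6,
                        Z = 1.5e6) {
  Tp <- t_total * asin(sqrt(0.9)) / pi  # sin^2 lobe reaches 0.9 of its max
  if (is.null(v_peak)) {
    if (is.null(efd_target)) stop("give either efd_target or v_peak")
    v_peak <- calibrate_pulse(efd_target, Z, Tp)
  }
  stopifnot(v_peak >= 0, t_total > 0)
  structure(list(v_peak = v_peak, t_total = t_total, Tp = Tp, Z = Z,
                 PII = efd(v_peak, Z, Tp)), class = "shock_pulse")
}

#' Pulse velocity profile
#'
#' @param t time, s (vectorised).
#' @param pulse a [shock_pulse()].
#' @return velocity, m/s.
#' @export
pulse_profile <- function(t, pulse) {
  ifelse(t >= 0 & t <= pulse$t_total,
         pulse$v_peak * sin(pi * t / pulse$t_total)^2, 0)
}

#' Positive-pressure time Tp of a sampled trace
#'
#' First time at which a pressure trace reaches 90% of its positive
#' maximum, with linear interpolation between samples.
#'
#' @param t sample times, s.
#' @param p pressure samples, Pa.
#' @return Tp, s.
#' @export
tp_from_profile <- function(t, p) {
  pmax_ <- max(p)
  if (pmax_ <= 0) stop("trace has no positive maximum", call. = FALSE)
  thr <- 0.9 * pmax_
  k <- which(p >= thr)[1]
  if (k == 1) return(t[1])
  t[k - 1] + (thr - p[k - 1]) / (p[k] - p[k - 1]) * (t[k] - t[k - 1])
}

#' Energy flux density of a pulse
#'
#' `PII = v_peak^2 * Z * Tp / 2` (J/m^2); divide by 1000 for mJ/mm^2.
#'
#' @param v_peak peak particle velocity, m/s.
#' @param Z acoustic impedance, kg m^-2 s^-1.
#' @param Tp positive-pressure time, s.
#' @return energy flux density, J/m^2.
#' @export
efd <- function(v_peak, Z, Tp) v_peak^2 * Z * Tp / 2

#' Calibrate pulse amplitude to a target dose
#'
#' Inverts [efd()]: `v_peak = sqrt(2 * PII / (Z * Tp))`.
#'
#' @param target_PII target energy flux density, J/m^2.
#' @param Z acoustic impedance, kg m^-2 s^-1.
#' @param Tp positive-pressure time, s.
#' @return peak velocity, m/s.
#' @export
calibrate_pulse <- function(target_PII, Z, Tp) {
  stopifnot(target_PII > 0, Z > 0, Tp > 0)
  sqrt(2 * target_PII / (Z * Tp))
}

new_protocol <- function(name, fixed = NULL, driven = list(),
                         ext_force = NULL, confine_lateral = FALSE) {
  structure(list(name = name, fixed = fixed, driven = driven,
                 ext_force = ext_force, confine_lateral = confine_lateral),
            class = "mca_protocol")
}

#' Loading protocols
#'
#' Boundary-condition drivers consumed by [simulate_mca()]. Sets may be
#' given as particle index vectors or as [boundary_sets()] names (`"top"`,
#' `"bottom"`, `"applicator"`). The bottom layer is clamped in all
#' protocols.
#'
#' * `protocol_compression()`: constant downward velocity on the top layer
#'   (the verification driver; the physical test runs at 0.001 m/s, scaled
#'   up here with damping and a kinetic-energy guard).
#' * `protocol_displacement()`: prescribed total displacement reached at
#'   constant velocity over `t_load`, then held (the validation driver).
#' * `protocol_pulse()`: a [shock_pulse()] velocity profile on the
#'   applicator plate, directed along `dir`.
#' * `protocol_fixed()`: clamped sets only (free relaxation elsewhere).
#'
#' @param v compression speed, m/s (positive = downward).
#' @param top,bottom,on driven/clamped sets (indices or set names).
#' @param u_total prescribed displacement, m.
#' @param t_load time over which `u_total` is reached, s.
#' @param pulse a [shock_pulse()].
#' @param dir unit drive direction for the pulse (default -x: the plate
#'   pushes into the joint).
#' @param ext_force optional list(idx, fvec, scale) applying a constant (or
#'   `scale(t)`-modulated) force per particle.
#' @param confine_lateral zero all lateral velocities (1D column runs).
#' @return An `mca_protocol`.
#' @name protocols
NULL

#' @rdname protocols
#' @export
protocol_compression <- function(v, top = "top", bottom = "bottom",
                                 confine_lateral = FALSE) {
  new_protocol("velocity-compression", fixed = bottom,
               driven = list(list(name = "top", idx = top, dir = c(0, 0, -1),
                                  vel = function(t) rep(v, length(t)))),
               confine_lateral = confine_lateral)
}

#' @rdname protocols
#' @export
protocol_displacement <- function(u_total, t_load, top = "top",
                                  bottom = "bottom",
                                  confine_lateral = FALSE) {
  v <- u_total / t_load
  new_protocol("prescribed-displacement", fixed = bottom,
               driven = list(list(name = "top", idx = top, dir = c(0, 0, -1),
                                  vel = function(t) ifelse(t < t_load, v, 0))),
               confine_lateral = confine_lateral)
}

#' @rdname protocols
#' @export
protocol_pulse <- function(pulse, on = "applicator", bottom = "bottom",
                           dir = c(-1, 0, 0)) {
  force(pulse)
  new_protocol("shock-pulse", fixed = bottom,
               driven = list(list(name = "applicator", idx = on, dir = dir,
                                  vel = function(t) pulse_profile(t, pulse))))
}

#' @rdname protocols
#' @export
protocol_fixed <- function(bottom = "bottom", ext_force = NULL,
                           confine_lateral = FALSE) {
  new_protocol("fixed", fixed = bottom, ext_force = ext_force,
               confine_lateral = confine_lateral)
}
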