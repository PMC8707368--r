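# Closed-form verification oracles. These ship with the package (not only
# with its tests) so that the verification battery can be rerun against any
# material set.

#' Confined (oedometer) modulus
#'
#' Drained: `K + 4G/3`; undrained: `K + alpha^2 M + 4G/3`. This is the
#' modulus governing 1D (laterally confined) compression and longitudinal
#' wave propagation.
#'
#' @param material single-row material tibble.
#' @param fluid a [fluid_model()].
#' @param drained logical.
#' @return modulus, Pa.
#' @examples
#' m <- dplyr::filter(builtin_materials(), name == "cortical")
#' confined_modulus(m, drained = TRUE) / 1e9  # 21.4 GPa
#' @export
confined_modulus <- function(material, fluid = fluid_model(),
                             drained = TRUE) {
  m <- material_constants(material, fluid)
  if (drained || !m$poroelastic) m$K + 4 * m$G / 3
  else m$K + m$alpha^2 * m$M + 4 * m$G / 3
}

#' Consolidation coefficient
#'
#' `cv = (k/mu) * M * (K + 4G/3) / (Ku + 4G/3)` with `Ku = K + alpha^2 M`:
#' the diffusivity of pore pressure under 1D confined consolidation.
#'
#' @inheritParams confined_modulus
#' @return cv, m^2/s.
#' @export
consolidation_coefficient <- function(material, fluid = fluid_model()) {
  m <- material_constants(material, fluid)
  stopifnot(m$poroelastic)
  Kc <- m$K + 4 * m$G / 3
  (m$k / fluid$mu) * m$M * Kc / (Kc + m$alpha^2 * m$M)
}

#' 1D loading efficiency
#'
#' Initial undrained pore pressure per unit applied axial stress under
#' laterally confined conditions: `eta = alpha M / (Ku + 4G/3)`.
#'
#' @inheritParams confined_modulus
#' @return dimensionless loading efficiency.
#' @export
loading_efficiency <- function(material, fluid = fluid_model()) {
  m <- material_constants(material, fluid)
  m$alpha * m$M / (m$Ku + 4 * m$G / 3)
}

#' Terzaghi consolidation pressure
#'
#' Classical Fourier-series solution for a column of height `H` loaded
#' suddenly by an axial stress `load`, drained at `z = 0` and sealed at
#' `z = H`:
#' `p(z,t) = p0 * sum 4/((2n+1) pi) sin((2n+1) pi z / (2H)) *
#'   exp(-(2n+1)^2 pi^2 Tv / 4)`, with `Tv = cv t / H^2` and the initial
#' undrained pressure `p0 = eta * load` from [loading_efficiency()].
#'
#' @param z depth below the drained surface, m (vectorised).
#' @param t time after load application, s.
#' @param H drainage path length (column height), m.
#' @param load applied axial stress, Pa (compression positive).
#' @inheritParams confined_modulus
#' @param nterms series truncation (>= 20 enforced).
#' @return pore pressure, Pa.
#' @export
terzaghi_pressure <- function(z, t, H, load, material,
                              fluid = fluid_model(), nterms = 100) {
  stopifnot(all(z >= 0), all(z <= H + 1e-12), nterms >= 20)
  cv <- consolidation_coefficient(material, fluid)
  p0 <- loading_efficiency(material, fluid) * load
  Tv <- cv * t / H^2
  n <- 0:(nterms - 1)
  Mn <- (2 * n + 1) * pi / 2
  out <- vapply(z, function(zi) {
    sum(2 / Mn * sin(Mn * zi / H) * exp(-Mn^2 * Tv))
  }, numeric(1))
  p0 * out
}

#' Terzaghi consolidation verification run
#'
#' Simulates 1D consolidation of a laterally confined column (drained top,
#' sealed bottom, suddenly applied constant axial load) and compares the
#' pore-pressure profile against [terzaghi_pressure()] at the final time.
#' The oracle amplitude uses the measured interior axial stress (the
#' discrete column's true cross-section differs from the nominal box area
#' by a surface-cell fraction, so the nominal load would bias the
#' comparison).
#'
#' @param material_name tissue to test.
#' @param k_override permeability used for the run, m^2 (chosen so the
#'   consolidation time is a few hundred wave transits; the tabulated
#'   cancellous value consolidates faster than the column's wave-settling
#'   time and the cartilage value astronomically slower).
#' @param d element diameter, m.
#' @param width,H column cross-section width and height, m.
#' @param sigma0 applied axial stress, Pa.
#' @param Tv_end dimensionless consolidation time reached.
#' @param materials,fluid material table and fluid model.
#' @return list: `profile` tibble (z-depth, simulated and reference
#'   pressure), `rms_rel` (RMS error over the initial undrained pressure),
#'   `Tv`.
#' @export
terzaghi_test <- function(material_name = "cancellous", k_override = 2e-13,
                          d = 1e-3, width = 3e-3, H = 20e-3, sigma0 = 1e5,
                          Tv_end = 0.35, materials = builtin_materials(),
                          fluid = fluid_model()) {
  mats <- materials
  mats$k[mats$name == material_name] <- k_override
  m <- mats[mats$name == material_name, ]
  pk <- pack_block(width, width, H, d, region = material_name)
  bs <- boundary_sets(pk)
  zr <- range(pk$particles$z); Hc <- diff(zr)
  cv <- consolidation_coefficient(m, fluid)
  qs <- quasi_static_pars(pk, mats, fluid, TRUE, 25, 1)
  t_ramp <- 5 * Hc / material_constants(m, fluid)$cp_u
  t_end <- Tv_end * Hc^2 / cv
  prot <- protocol_fixed(bottom = "bottom",
    ext_force = list(idx = bs$top,
                     fvec = c(0, 0, -sigma0 * width^2 / length(bs$top)),
                     scale = function(t) pmin(t / t_ramp, 1)))
  prot$confine_lateral <- TRUE
  p <- pk$particles
  prs <- vapply(seq(0.05, 0.95, by = 0.1), function(zf) {
    which.min((p$z - (zr[1] + zf * Hc))^2 + (p$x - width / 2)^2 +
                (p$y - width / 2)^2)
  }, integer(1))
  res <- simulate_mca(pk, prot, t_end = t_end, materials = mats,
                      fluid = fluid, poro = TRUE, damping = qs$damping,
                      drained = bs$top, probes = prs, monitor_every = 5)
  tr <- res$probes
  tf <- max(tr$t)
  sim <- tr[tr$t == tf, ]
  zd <- Hc - (p$z[sim$particle] - zr[1])
  t1 <- min(tr$t[tr$t >= 1.5 * t_ramp])
  sigma_meas <- -mean(tr$s_zz[tr$t == t1])
  # linear load ramp: consolidation clock starts at the ramp midpoint
  t_eff <- tf - t_ramp / 2
  ref <- terzaghi_pressure(zd, t_eff, Hc, sigma_meas, m, fluid)
  p0 <- loading_efficiency(m, fluid) * sigma_meas
  list(profile = tibble::tibble(z_depth = zd, p_sim = sim$p_fluid,
                                p_ref = ref),
       rms_rel = sqrt(mean((sim$p_fluid - ref)^2)) / p0,
       Tv = cv * t_eff / Hc^2, sigma_meas = sigma_meas,
       zeta_drift = glance(res)$zeta_drift)
}
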