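# Biot coupling and Darcy exchange: formula-level operations mirroring the
# compiled core, exposed for direct use and for unit testing. The coupled
# behaviour is exercised through simulate_mca(poro = TRUE), which performs
# per step: (1) Darcy exchange, (2) storage-law pressure update from the
# volumetric strain and fluid-content increments, (3) the effective-stress
# contribution to the next solid update.

#' Effective-stress correction
#'
#' Pore pressure loads only the diagonal stress components (tension-positive
#' convention): `sigma_total = sigma_solid - alpha * p * I`; the deviator is
#' untouched.
#'
#' @param sigma_solid 3x3 skeleton (effective) stress tensor, Pa.
#' @param p pore pressure, Pa.
#' @param alpha Biot coefficient.
#' @return 3x3 total stress tensor, Pa.
#' @export
effective_stress <- function(sigma_solid, p, alpha) {
  sigma_solid - alpha * p * diag(3)
}

#' Storage-law pressure increment
#'
#' `dp = M * (d_zeta_in - alpha * d_eps_vol)` with tension-positive
#' volumetric strain: compression (negative `d_eps_vol`) raises the pore
#' pressure, inflow (`d_zeta_in > 0`) raises it.
#'
#' @param d_eps_vol volumetric strain increment.
#' @param d_zeta_in fluid-content increment (inflow positive).
#' @param alpha Biot coefficient.
#' @param M Biot storage modulus, Pa.
#' @return pressure increment, Pa.
#' @export
pressure_update <- function(d_eps_vol, d_zeta_in, alpha, M) {
  M * (d_zeta_in - alpha * d_eps_vol)
}

#' Darcy inter-particle volume flux
#'
#' `Q = k_h S (p_i - p_j) / (mu r)` with the harmonic-mean pair
#' permeability `k_h = 2 k_i k_j / (k_i + k_j)`; positive from i to j.
#' The per-particle fluid-content increments over `dt` are `-Q dt / V` for
#' i and `+Q dt / V` for j (antisymmetric, so total content is conserved).
#'
#' @param p_i,p_j pore pressures, Pa.
#' @param k_i,k_j permeabilities, m^2.
#' @param S contact area, m^2.
#' @param r centre distance, m.
#' @param mu fluid viscosity, Pa s.
#' @return volume flux, m^3/s.
#' @export
darcy_exchange <- function(p_i, p_j, k_i, k_j = k_i, S, r, mu = 1e-3) {
  if (any(c(k_i, k_j) < 0)) stop("negative permeability", call. = FALSE)
  kh <- 2 * k_i * k_j / (k_i + k_j)
  kh * S * (p_i - p_j) / (mu * r)
}
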