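# Solid-phase solver surface: pair tractions, stress homogenisation,
# invariants, time-step bound, and the simulate_mca() driver around the
# compiled core.

mat_for_core <- function(materials, fluid) {
  mc <- material_constants(materials, fluid)
  mc$alpha[!mc$poroelastic] <- 0
  mc$M[!mc$poroelastic] <- 0
  mc$k[!mc$poroelastic] <- 0
  mc
}

#' Stable explicit time step
#'
#' CFL-type bound `dt = safety * d / max(cp)` over the materials present in
#' the packing. When a fluid model is supplied the undrained P-wave speed
#' `sqrt((K + alpha^2 M + 4G/3)/rho)` is used, which is the speed actually
#' realised by a coupled run at short times.
#'
#' @param packing an `mca_packing`.
#' @param materials material table.
#' @param fluid a [fluid_model()], or `NULL` for a dry (drained) bound.
#' @param safety dimensionless safety factor.
#' @return time step, s.
#' @examples
#' stable_dt(pack_block(5e-3, 5e-3, 5e-3, 1e-3), builtin_materials(),
#'           fluid = NULL)
#' @export
stable_dt <- function(packing, materials = builtin_materials(), fluid = NULL,
                      safety = 0.2) {
  present <- unique(packing$particles$region)
  mc <- material_constants(materials, fluid %||% fluid_model())
  mc <- mc[mc$name %in% present, ]
  cp <- if (is.null(fluid)) mc$cp else mc$cp_u
  safety * packing$d / max(cp)
}

#' Pair tractions of the many-body elastic law
#'
#' Per-side normal response `sigma_n^(i) = 2 G_i eps_i + Lambda_i` with
#' `Lambda_i = (K_i - 2G_i/3) eps_vol_i - alpha_i p_i`, solved for the
#' partition of the total pair strain between dissimilar materials so that
#' the interface is in equilibrium (`sigma_n^(i) = sigma_n^(j)`); tangential
#' traction `tau = 2 G_h gamma` with the pair shear stiffness
#' `G_h = 2 G_i G_j / (G_i + G_j)`.
#'
#' @param eps_n pair normal strain `(r - r0)/r0`.
#' @param gamma accumulated tangential shear strain (3-vector, perpendicular
#'   to the bond normal).
#' @param mat_i,mat_j single-row material tibbles (columns `G`, `K`).
#' @param eps_vol_i,eps_vol_j particle volumetric strains.
#' @param p_i,p_j pore pressures, Pa.
#' @param alpha_i,alpha_j Biot coefficients.
#' @return list with `sigma_n` (Pa), `tau` (Pa 3-vector) and the per-side
#'   normal strains `eps_i`, `eps_j`.
#' @examples
#' m <- dplyr::filter(builtin_materials(), name == "cortical")
#' pair_tractions(-1e-3, c(0, 0, 0), m, m)$sigma_n  # = 2 G eps = -11.1 MPa
#' @export
pair_tractions <- function(eps_n, gamma = c(0, 0, 0), mat_i, mat_j = mat_i,
                           eps_vol_i = 0, eps_vol_j = 0, p_i = 0, p_j = 0,
                           alpha_i = 0, alpha_j = 0) {
  Gi <- mat_i$G; Gj <- mat_j$G
  Li <- (mat_i$K - 2 * Gi / 3) * eps_vol_i - alpha_i * p_i
  Lj <- (mat_j$K - 2 * Gj / 3) * eps_vol_j - alpha_j * p_j
  eps_i <- (4 * Gj * eps_n + Lj - Li) / (2 * (Gi + Gj))
  eps_j <- 2 * eps_n - eps_i
  Gh <- 2 * Gi * Gj / (Gi + Gj)
  list(sigma_n = 2 * Gi * eps_i + Li, tau = 2 * Gh * gamma,
       eps_i = eps_i, eps_j = eps_j)
}

#' Averaged stress of one automaton
#'
#' Homogenises contact tractions over the automaton volume:
#' `sigma_ab = (1/V) sum_j q_j S_j n_a t_b`, symmetrised. `q` is the
#' centre-to-contact distance (half the pair distance).
#'
#' @param normals matrix (n_contacts x 3) of unit bond normals.
#' @param tractions matrix (n_contacts x 3) of traction vectors, Pa.
#' @param S contact areas, m^2 (recycled).
#' @param q centre-to-contact distances, m (recycled).
#' @param V automaton volume, m^3.
#' @return symmetric 3x3 stress tensor, Pa.
#' @export
average_stress <- function(normals, tractions, S, q, V) {
  if (is.null(dim(normals))) normals <- matrix(normals, ncol = 3)
  if (is.null(dim(tractions))) tractions <- matrix(tractions, ncol = 3)
  S <- rep_len(S, nrow(normals)); q <- rep_len(q, nrow(normals))
  sig <- matrix(0, 3, 3)
  for (k in seq_len(nrow(normals)))
    sig <- sig + q[k] * S[k] * tcrossprod(normals[k, ], tractions[k, ])
  sig <- (sig + t(sig)) / (2 * V)
  sig
}

#' Stress invariants and recovered strain measure
#'
#' From a tension-positive total stress tensor: hydrostatic pressure
#' `p_hydro = -tr(sigma)/3` (positive in compression) and the distortional
#' (von Mises equivalent) strain `eps_eq = sqrt(2/3 e:e)` with `e` the
#' deviatoric strain recovered by inverse isotropic Hooke's law from the
#' effective stress. Pore pressure is hydrostatic, so the deviator — and
#' hence `eps_eq` — needs no effective-stress correction.
#'
#' @param sigma 3x3 stress tensor or a tibble of 6 Voigt components
#'   (`sxx, syy, szz, sxy, sxz, syz`), Pa.
#' @param G shear modulus, Pa (recycled over rows for the tibble form).
#' @return tibble with `p_hydro` (Pa) and `eps_eq` (dimensionless).
#' @export
strain_invariants <- function(sigma, G) {
  if (is.matrix(sigma))
    sigma <- tibble::tibble(sxx = sigma[1, 1], syy = sigma[2, 2],
                            szz = sigma[3, 3], sxy = sigma[1, 2],
                            sxz = sigma[1, 3], syz = sigma[2, 3])
  m <- (sigma$sxx + sigma$syy + sigma$szz) / 3
  e <- cbind(sigma$sxx - m, sigma$syy - m, sigma$szz - m,
             sigma$sxy, sigma$sxz, sigma$syz) / (2 * G)
  eps_eq <- sqrt(2 / 3 * (e[, 1]^2 + e[, 2]^2 + e[, 3]^2 +
                            2 * (e[, 4]^2 + e[, 5]^2 + e[, 6]^2)))
  tibble::tibble(p_hydro = -m, eps_eq = eps_eq)
}

resolve_sets <- function(protocol, packing) {
  # boundary sets may be given as index vectors or as set names
  bs <- NULL
  get_idx <- function(x) {
    if (is.numeric(x)) return(as.integer(x))
    if (is.null(bs)) bs <<- boundary_sets(packing)
    out <- bs[[x]]
    if (is.null(out)) stop("unknown boundary set: ", x, call. = FALSE)
    out
  }
  protocol$fixed <- if (is.null(protocol$fixed)) integer(0) else
    get_idx(protocol$fixed)
  protocol$driven <- purrr::map(protocol$driven, function(st) {
    st$idx <- get_idx(st$idx)
    st
  })
  if (!is.null(protocol$ext_force))
    protocol$ext_force$idx <- get_idx(protocol$ext_force$idx)
  protocol
}

#' Run the bonded-particle poroelastic solver
#'
#' Explicit velocity-Verlet integration of the automaton ensemble under a
#' loading protocol (see [protocol_compression()], [protocol_displacement()],
#' [protocol_pulse()]), with optional Biot/Darcy fluid coupling. Darcy
#' exchange is automatically substepped when the pore-pressure diffusivity
#' of a present material exceeds the explicit limit at the mechanical step.
#'
#' @param packing an `mca_packing`.
#' @param protocol an `mca_protocol`.
#' @param t_end simulated time, s.
#' @param materials,fluid material table and fluid model.
#' @param dt time step, s; default [stable_dt()] at `safety`.
#' @param safety CFL safety factor used when `dt` is NULL.
#' @param damping mass-proportional damping coefficient, 1/s.
#' @param poro enable pore-fluid coupling.
#' @param drained particle indices held at p = 0 (drained patches);
#'   default sealed everywhere.
#' @param probes particle indices whose fields are recorded every monitor
#'   step.
#' @param monitor_every record cadence in steps (default ~400 samples).
#' @param v0 optional N x 3 initial velocity matrix.
#' @param track_max track per-particle temporal maxima of compressive
#'   hydrostatic pressure, fluid pressure, distortional strain.
#' @param surface_comp strength (0-1) of the free-surface stiffness
#'   compensation: automata with missing contacts redistribute that share of
#'   the lost load onto their remaining bonds. Default: 1 for free-surface
#'   runs, 0 under lateral kinematic confinement (a confined boundary loses
#'   no load path, so there is nothing to redistribute).
#' @return An `mca_result`: list with `fields` (per-particle tibble),
#'   `trace` (time series tibble), `probes` (long tibble), and `meta`.
#' @export
simulate_mca <- function(packing, protocol, t_end,
                         materials = builtin_materials(),
                         fluid = fluid_model(), dt = NULL, safety = 0.2,
                         damping = 0, poro = TRUE, drained = integer(0),
                         probes = integer(0), monitor_every = NULL,
                         v0 = NULL, track_max = TRUE, surface_comp = NULL) {
  stopifnot(inherits(packing, "mca_packing"), inherits(protocol, "mca_protocol"))
  mc <- mat_for_core(materials, fluid)
  present <- unique(packing$particles$region)
  if (!all(present %in% mc$name))
    stop("packing regions missing from material table: ",
         paste(setdiff(present, mc$name), collapse = ", "), call. = FALSE)
  if (is.null(dt))
    dt <- stable_dt(packing, materials, if (poro) fluid else NULL, safety)
  n_steps <- max(2L, as.integer(ceiling(t_end / dt)))
  if (is.null(monitor_every))
    monitor_every <- max(1L, n_steps %/% 400L)

  protocol <- resolve_sets(protocol, packing)
  if (is.null(surface_comp))
    surface_comp <- if (isTRUE(protocol$confine_lateral)) 0 else 1
  # velocities are sampled at step midpoints (second-order consistent with
  # the drift, and prescribed displacements integrate exactly to +- dt/2)
  tgrid <- (seq_len(n_steps) - 0.5) * dt
  driven <- purrr::map(protocol$driven, function(st) {
    list(idx = st$idx - 1L, dir = st$dir, vel = st$vel(tgrid))
  })
  ext <- protocol$ext_force
  ext_c <- if (is.null(ext)) list() else
    list(idx = ext$idx - 1L, fvec = ext$fvec, scale = ext$scale(tgrid))

  # Darcy substepping against the explicit diffusion limit
  n_sub <- 1L
  if (poro) {
    pe <- mc[mc$poroelastic & mc$name %in% present, ]
    if (nrow(pe)) {
      Dmax <- max(pe$k * pe$M / fluid$mu)
      n_sub <- max(1L, as.integer(ceiling(Dmax * dt / (0.2 * packing$d^2))))
      if (n_sub > 1)
        message("Darcy exchange substepped x", n_sub,
                " (pore-pressure diffusivity exceeds the mechanical step)")
    }
  }

  pos <- as.matrix(packing$particles[, c("x", "y", "z")])
  vel0 <- if (is.null(v0)) matrix(0, nrow(pos), 3) else v0
  mat_id <- match(packing$particles$region, mc$name) - 1L
  res <- mca_run_cpp(pos, vel0, mat_id, packing$d,
                     as.matrix(packing$bonds[, c("i", "j")]) - 1L,
                     packing$bonds$r0, packing$bonds$S,
                     list(G = mc$G, K = mc$K, rho = mc$rho, alpha = mc$alpha,
                          M = mc$M, k = mc$k, poroelastic = mc$poroelastic),
                     fluid$mu, dt, n_steps, damping,
                     protocol$fixed - 1L, driven,
                     isTRUE(protocol$confine_lateral), poro,
                     as.integer(drained) - 1L, ext_c, monitor_every,
                     as.integer(probes) - 1L, track_max, n_sub, surface_comp)

  fields <- packing$particles |>
    dplyr::mutate(
      sxx = res$sigma[, 1], syy = res$sigma[, 2], szz = res$sigma[, 3],
      sxy = res$sigma[, 4], sxz = res$sigma[, 5], syz = res$sigma[, 6],
      p_fluid = res$p, eps_vol = res$eps_vol, eps_eq = res$eps_eq,
      p_hydro = -(res$sigma[, 1] + res$sigma[, 2] + res$sigma[, 3]) / 3,
      max_p_hydro = res$maxima[, 1], max_p_fluid = res$maxima[, 2],
      max_eps_eq = res$maxima[, 3])

  trace <- tibble::tibble(t = res$monitor$t, ke = res$monitor$ke,
                          pe = res$monitor$pe,
                          zeta_total = res$monitor$zeta_total)
  for (k in seq_along(driven)) {
    nm <- protocol$driven[[k]]$name %||% paste0("set", k)
    dirk <- protocol$driven[[k]]$dir
    trace[[paste0("force_", nm)]] <- -as.vector(res$set_force[[k]] %*% dirk)
    trace[[paste0("disp_", nm)]] <- res$set_disp[[k]]
  }

  probes_tb <- NULL
  if (length(probes)) {
    pr <- res$probes
    probes_tb <- purrr::map_dfr(seq_along(probes), function(k) {
      tibble::tibble(t = res$monitor$t, particle = probes[k],
                     p_fluid = pr$p_fluid[[k]], p_hydro = pr$p_hydro[[k]],
                     s_zz = pr$s_zz[[k]], eps_eq = pr$eps_eq[[k]])
    })
  }

  structure(list(fields = fields, trace = trace, probes = probes_tb,
                 final = list(pos = res$pos, vel = res$vel, zeta = res$zeta),
                 meta = list(dt = dt, n_steps = n_steps, damping = damping,
                             poro = poro, n_sub = n_sub,
                             protocol = protocol$name, d = packing$d,
                             t_end = t_end)),
            class = "mca_result")
}

#' @export
print.mca_result <- function(x, ...) {
  cat("<mca_result> ", nrow(x$fields), " particles, ", x$meta$n_steps,
      " steps of dt = ", format(x$meta$dt), " s (", x$meta$protocol, ")\n",
      sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn simulate_mca per-particle field tibble of a run.
#' @param x an `mca_result`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.mca_result <- function(x, ...) x$fields

#' @describeIn simulate_mca one-row run summary: energies, kinetic-energy
#'   ratio (quasi-static guard), peak fields, fluid-content drift.
#' @exportS3Method generics::glance
glance.mca_result <- function(x, ...) {
  tr <- x$trace
  tail_i <- which(tr$t >= 0.5 * max(tr$t))
  tibble::tibble(
    n_particles = nrow(x$fields), n_steps = x$meta$n_steps, dt = x$meta$dt,
    ke_final = tr$ke[nrow(tr)], pe_final = tr$pe[nrow(tr)],
    ke_ratio = max(tr$ke[tail_i]) / max(tr$pe[tail_i], .Machine$double.eps),
    max_p_hydro = max(x$fields$max_p_hydro),
    max_p_fluid = max(x$fields$max_p_fluid),
    max_eps_eq = max(x$fields$max_eps_eq),
    zeta_drift = max(abs(tr$zeta_total - tr$zeta_total[1])))
}
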