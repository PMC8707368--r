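# FCC packings and the procedural layered knee analog.
#
# Particles sit on a face-centred-cubic lattice with nearest-neighbour
# distance d (the automaton diameter). The Voronoi cell of an FCC site is a
# rhombic dodecahedron: volume V = d^3/sqrt(2), 12 faces of area
# S = d^2/(2*sqrt(2)) at distance d/2 from the centre. Using these exact
# face areas in the stress homogenisation makes the bonded lattice reproduce
# isotropic Hooke's law under uniform strain.

fcc_sites <- function(lx, ly, lz, d) {
  a <- d * sqrt(2)
  basis <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  tol <- 1e-9 * d
  ni <- floor(lx / a) + 1L; nj <- floor(ly / a) + 1L; nk <- floor(lz / a) + 1L
  g <- expand.grid(i = 0:ni, j = 0:nj, k = 0:nk, b = 1:4)
  x <- (g$i + basis[g$b, 1]) * a
  y <- (g$j + basis[g$b, 2]) * a
  z <- (g$k + basis[g$b, 3]) * a
  keep <- x <= lx + tol & y <= ly + tol & z <= lz + tol
  tibble::tibble(x = x[keep], y = y[keep], z = z[keep])
}

make_packing <- function(particles, d) {
  pos <- as.matrix(particles[, c("x", "y", "z")])
  bl <- find_bonds_cpp(pos, 1.01 * d)
  S <- d^2 / (2 * sqrt(2))
  structure(list(
    particles = dplyr::mutate(particles, id = dplyr::row_number(),
                              .before = 1),
    bonds = tibble::tibble(i = bl$i + 1L, j = bl$j + 1L, r0 = bl$r0, S = S),
    d = d), class = "mca_packing")
}

#' Pack a rectangular block of particles
#'
#' Fills the box `[0,lx] x [0,ly] x [0,lz]` with an FCC lattice of automata
#' of diameter `d` and bonds all pairs closer than `1.01*d`. Interior
#' particles have exactly 12 bonded neighbours.
#'
#' @param lx,ly,lz box extents, m.
#' @param d automaton diameter, m.
#' @param region tissue label applied to every particle (must be a material
#'   name when the packing is simulated).
#' @return An `mca_packing`: a list with tibbles `particles`
#'   (`id, x, y, z, region`) and `bonds` (`i, j, r0, S`; 1-based indices),
#'   plus the diameter `d`.
#' @examples
#' p <- pack_block(5e-3, 5e-3, 5e-3, 1e-3)
#' nrow(p$particles)
#' @export
pack_block <- function(lx, ly, lz, d, region = "cortical") {
  if (min(lx, ly, lz) < 2 * d)
    stop("degenerate extent: each box side must be at least 2*d", call. = FALSE)
  pts <- fcc_sites(lx, ly, lz, d)
  pts$region <- region
  make_packing(pts, d)
}

#' Parameter set for the layered knee-joint analog
#'
#' A procedural stand-in for an anatomical knee: two bones (cancellous core,
#' cortical shell) separated by two articular cartilage plates and a joint
#' space holding a meniscus (fibrocartilage) ring with fibrous interior, the
#' whole soft-tissue band wrapped laterally by a capsule shell. A copper
#' applicator plate is attached to the outer capsule wall at meniscus height.
#' Defaults define a desk-scale analog (a 22 mm diameter, 30 mm tall,
#' slightly conical joint with a 2 mm condyle dome); the clinical
#' 20 x 20 x 1 mm applicator is scaled with the joint to 6 x 4 x 2 mm and
#' restricted to the meniscus band so it does not load the cartilage-plate
#' edges directly.
#'
#' Every feature measures at least 4 mm so the coarsest verification size
#' (d = 2 mm) still resolves each layer with two element diameters.
#'
#' @param width joint diameter, m.
#' @param t_cortical cortical plate/shell thickness, m.
#' @param h_cancellous cancellous band height per bone, m.
#' @param t_cartilage cartilage plate thickness, m.
#' @param h_meniscus joint-space (meniscus) height, m.
#' @param t_capsule capsule shell thickness, m.
#' @param meniscus_inner,meniscus_outer meniscus ring radii, m; fibrous
#'   tissue fills the rest of the joint space.
#' @param dome_sag condyle dome height of the soft band, m.
#' @param applicator c(width_y, height_z, thickness_x) of the copper plate, m.
#' @param include_applicator attach the applicator plate?
#' @return A list of class `knee_analog_spec`.
#' @export
knee_analog_spec <- function(width = 22e-3, t_cortical = 4e-3,
                             h_cancellous = 5e-3, t_cartilage = 4e-3,
                             h_meniscus = 4e-3, t_capsule = 4e-3,
                             meniscus_inner = 3e-3, meniscus_outer = 7e-3,
                             dome_sag = 2e-3,
                             applicator = c(6e-3, 4e-3, 2e-3),
                             include_applicator = TRUE) {
  sp <- list(width = width, t_cortical = t_cortical,
             h_cancellous = h_cancellous, t_cartilage = t_cartilage,
             h_meniscus = h_meniscus, t_capsule = t_capsule,
             meniscus_inner = meniscus_inner, meniscus_outer = meniscus_outer,
             dome_sag = dome_sag, applicator = applicator,
             include_applicator = include_applicator)
  stopifnot(all(unlist(sp[1:8]) > 0), dome_sag >= 0, length(applicator) == 3)
  stopifnot(dome_sag < h_cancellous, meniscus_inner < meniscus_outer,
            meniscus_outer <= width / 2 - t_capsule + 1e-12)
  sp$height <- 2 * t_cortical + 2 * h_cancellous + 2 * t_cartilage + h_meniscus
  class(sp) <- "knee_analog_spec"
  sp
}

#' Knee-analog variant for the shockwave sweep
#'
#' The dose levels are defined per unit applicator area, so the energy
#' density delivered to the joint — and with it the field amplitudes —
#' scales with the applicator-area-to-soft-tissue-volume ratio. This
#' variant enlarges the joint so that ratio matches the full-scale
#' proportions (a 20 x 20 mm plate on an anatomical knee) as closely as the
#' desk scale allows.
#'
#' @param width joint diameter, m.
#' @param ... passed to [knee_analog_spec()].
#' @export
knee_swt_spec <- function(width = 38e-3, ...) {
  knee_analog_spec(width = width, meniscus_inner = 7e-3,
                   meniscus_outer = 15e-3, ...)
}

check_resolution <- function(sp, d) {
  layers <- c(cortical_plate = sp$t_cortical, cancellous_band = sp$h_cancellous,
              cartilage_plate = sp$t_cartilage, meniscus_band = sp$h_meniscus,
              capsule_shell = sp$t_capsule,
              meniscus_ring = sp$meniscus_outer - sp$meniscus_inner)
  bad <- layers < d
  if (any(bad))
    stop("resolution error: layer(s) thinner than one element diameter: ",
         paste(names(layers)[bad], collapse = ", "), call. = FALSE)
  thin <- layers < 2 * d
  if (any(thin))
    warning("layer(s) thinner than 2*d (under-resolved): ",
            paste(names(layers)[thin], collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Build the layered knee-analog packing
#'
#' Generates one contiguous FCC lattice over the joint box (plus the
#' applicator slab) and labels each particle with its tissue region. All
#' inter-region interfaces are bonded. Labels carry both the material
#' (`region`) and the anatomical part (`part`, e.g. `tibia_cartilage`).
#'
#' @param spec a [knee_analog_spec()].
#' @param d automaton diameter, m.
#' @return An `mca_packing` with `region` and `part` columns.
#' @examples
#' pk <- knee_analog(knee_analog_spec(), d = 2e-3)
#' dplyr::count(pk$particles, region)
#' @export
knee_analog <- function(spec, d) {
  stopifnot(inherits(spec, "knee_analog_spec"))
  check_resolution(spec, d)
  W <- spec$width; H <- spec$height
  a_t <- max(spec$applicator[3], 0.75 * d)  # floor: at least one lattice plane
  marg <- 1e-3                # covers the conical taper on every side
  lx <- W + 2 * marg + if (spec$include_applicator) a_t else 0
  pts <- fcc_sites(lx, W + 2 * marg, H, d)
  pts$x <- pts$x - W / 2 - marg   # centre laterally; z stays [0, H]
  pts$y <- pts$y - W / 2 - marg

  z1 <- spec$t_cortical
  z2 <- z1 + spec$h_cancellous
  z3 <- z2 + spec$t_cartilage
  z4 <- z3 + spec$h_meniscus
  z5 <- z4 + spec$t_cartilage
  z6 <- z5 + spec$h_cancellous
  # slightly conical joint (anatomical shafts are not cylinders): every
  # lattice plane samples a different raster phase of the circular
  # boundaries, averaging the cross-section quantisation over z
  half <- W / 2 + 1e-3 * (pts$z / H - 0.5)
  rs <- sqrt(pts$x^2 + pts$y^2)
  tol <- 1e-9
  in_joint <- rs <= half + tol

  region <- character(nrow(pts))
  part <- character(nrow(pts))
  # the soft band follows a condyle-like dome (highest at the joint axis):
  # curved interfaces cut the lattice planes at varying phase, so effective
  # layer thicknesses average out across the cross-section instead of
  # jumping with the element size
  dome <- spec$dome_sag * (1 - pmin(rs / (W / 2), 1)^2)
  z <- pts$z - dome
  shell <- in_joint & rs > half - spec$t_cortical - tol
  # tibia (bottom) and femur (top) bone blocks: cancellous core in a
  # cortical shell (end plate + side walls)
  tb_idx <- in_joint & z < z2 - tol
  tb_cort <- tb_idx & (shell | z < z1 - tol)
  fb_idx <- in_joint & z >= z5 - tol
  fb_cort <- fb_idx & (shell | z >= z6 - tol)
  region[tb_idx] <- "cancellous"; part[tb_idx] <- "tibia_cancellous"
  region[tb_cort] <- "cortical";  part[tb_cort] <- "tibia_cortical"
  region[fb_idx] <- "cancellous"; part[fb_idx] <- "femur_cancellous"
  region[fb_cort] <- "cortical";  part[fb_cort] <- "femur_cortical"

  # soft-tissue band z in [z2, z5): capsule shell, fibrous margin, interior.
  # The cartilage plates span the full interior width (they cover the whole
  # condyle surface, confined between bone and joint space); the fibrous
  # margin separates only the meniscus band from the capsule.
  soft <- in_joint & z >= z2 - tol & z < z5 - tol
  caps <- soft & rs > half - spec$t_capsule - tol
  cart_band <- z < z3 - tol | z >= z4 - tol
  core <- soft & !caps
  cart <- core & cart_band
  menis <- core & !cart & rs > spec$meniscus_inner - tol &
    rs <= spec$meniscus_outer + tol
  fibc <- core & !cart & !menis
  region[caps] <- "capsule_shell"; part[caps] <- "capsule"
  region[fibc] <- "fibrous"; part[fibc] <- "fibrous_interior"
  region[menis] <- "fibrocartilage"; part[menis] <- "meniscus"
  tib_cart <- cart & z < z3 - tol
  region[cart] <- "cartilage"
  part[cart] <- ifelse(tib_cart[cart], "tibia_cartilage", "femur_cartilage")

  keep <- rep(TRUE, nrow(pts))
  if (spec$include_applicator) {
    zmid <- (z2 + z5) / 2
    app <- !in_joint & pts$x > 0 & pts$x <= half + a_t + tol &
      abs(pts$y) <= spec$applicator[1] / 2 + tol &
      abs(pts$z - zmid) <= spec$applicator[2] / 2 + tol
    region[app] <- "copper"; part[app] <- "applicator"
    keep <- in_joint | app
  } else keep <- in_joint

  pts$region <- region
  pts$part <- part
  pts <- pts[keep & nzchar(region), ]
  want <- c("cortical", "cancellous", "cartilage", "fibrocartilage",
            "fibrous", "capsule_shell",
            if (spec$include_applicator) "copper")
  missing <- setdiff(want, unique(pts$region))
  if (length(missing))
    stop("resolution error: region(s) received no particles: ",
         paste(missing, collapse = ", "), call. = FALSE)
  pk <- make_packing(pts, d)
  attr(pk, "spec") <- spec
  pk
}

#' Boundary index sets of a packing
#'
#' Identifies the top and bottom lattice layers (one FCC plane each) and,
#' for packings with an applicator, the copper plate and its outer face.
#' The sets are disjoint.
#'
#' @param packing an `mca_packing`.
#' @return A list of integer index vectors: `top`, `bottom`, and (if copper
#'   particles are present) `applicator` and `applicator_face`.
#' @export
boundary_sets <- function(packing) {
  p <- packing$particles
  if (!nrow(p)) stop("empty packing", call. = FALSE)
  lay <- 0.35 * packing$d          # < one FCC plane spacing (d/sqrt(2))
  out <- list(top = which(p$z > max(p$z) - lay),
              bottom = which(p$z < min(p$z) + lay))
  if (any(p$region == "copper")) {
    app <- which(p$region == "copper")
    out$applicator <- app
    out$applicator_face <- app[p$x[app] > max(p$x[app]) - lay]
    out$top <- setdiff(out$top, app)
    out$bottom <- setdiff(out$bottom, app)
  }
  if (!length(out$bottom)) stop("empty bottom boundary set", call. = FALSE)
  out
}

#' @export
print.mca_packing <- function(x, ...) {
  cat("<mca_packing> ", nrow(x$particles), " particles, ",
      nrow(x$bonds), " bonds, d = ", format(x$d), " m\n", sep = "")
  print(dplyr::count(x$particles, .data$region))
  invisible(x)
}
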