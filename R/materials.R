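#' Built-in tissue material table
#'
#' Elastic and poroelastic constants for the tissues of the knee-joint model:
#' matrix density `rho` (kg/m^3), matrix shear modulus `G` (Pa), drained
#' macroscopic bulk modulus `K` (Pa), solid-grain bulk modulus `Ks` (Pa),
#' porosity `theta`, and intrinsic permeability `k` (m^2), plus the copper
#' applicator plate modelled as a single-phase elastic solid.
#'
#' @return A tibble with one row per material and columns
#'   `name, rho, G, K, Ks, theta, k, poroelastic`.
#' @examples
#' builtin_materials()
#' @export
builtin_materials <- function() {
  tb <- tibble::tribble(
    ~name,            ~rho, ~G,        ~K,        ~Ks,    ~theta, ~k,
    "cortical",       1850, 5.55e9,    14e9,      17e9,   0.04,   3.6e-15,
    "cancellous",     700,  1.3e9,     3.3e9,     15e9,   0.7,    1.0e-11,
    "cartilage",      800,  0.0043e9,  0.00416e9, 3.4e9,  0.8,    4.8e-18,
    "fibrocartilage", 900,  0.130e9,   0.283e9,   2.3e9,  0.8,    9.5e-19,
    "fibrous",        1000, 0.00043e9, 0.00416e9, 2.3e9,  0.9,    7.5e-19,
    "capsule_shell",  1000, 1.2e9,     2.3e9,     2.3e9,  0.9,    1.0e-11,
    "copper",         8950, 41.6e9,    115e9,     NA,     NA,     NA
  )
  tb$poroelastic <- tb$name != "copper"
  validate_materials(tb)
  tb
}

#' Pore fluid model
#'
#' The interstitial fluid is treated as salt water: bulk modulus `Kf`
#' = 2.4 GPa and density 1000 kg/m^3. The dynamic viscosity defaults to that
#' of water at room temperature (1.0e-3 Pa s) and can be overridden.
#'
#' @param Kf fluid bulk modulus, Pa.
#' @param rho_f fluid density, kg/m^3.
#' @param mu dynamic viscosity, Pa s.
#' @return A list of class `fluid_model`.
#' @export
fluid_model <- function(Kf = 2.4e9, rho_f = 1000, mu = 1.0e-3) {
  stopifnot(Kf > 0, rho_f > 0, mu > 0)
  structure(list(Kf = Kf, rho_f = rho_f, mu = mu), class = "fluid_model")
}

validate_materials <- function(m) {
  stopifnot(all(m$K > 0), all(m$G > 0), all(m$rho > 0))
  pe <- m[m$poroelastic, ]
  if (nrow(pe)) {
    if (!all(pe$theta > 0 & pe$theta < 1))
      stop("invalid material: porosity must lie in (0, 1)", call. = FALSE)
    if (!all(pe$K <= pe$Ks))
      stop("invalid material: drained K must not exceed grain modulus Ks",
           call. = FALSE)
    if (!all(pe$k > 0))
      stop("invalid material: permeability must be positive", call. = FALSE)
  }
  nu <- (3 * m$K - 2 * m$G) / (2 * (3 * m$K + m$G))
  if (!all(nu > -1 & nu < 0.5))
    stop("invalid material: derived Poisson ratio outside (-1, 0.5)",
         call. = FALSE)
  invisible(m)
}

#' Derived isotropic elastic quantities
#'
#' Adds Young's modulus `E = 9KG/(3K+G)`, Poisson ratio
#' `nu = (3K-2G)/(2(3K+G))`, P-wave speed `cp = sqrt((K+4G/3)/rho)` and
#' S-wave speed `cs = sqrt(G/rho)` to a material table.
#'
#' @param materials a material tibble, see [builtin_materials()].
#' @return The input with columns `E`, `nu`, `cp`, `cs` appended.
#' @examples
#' derived_moduli(builtin_materials())
#' @export
derived_moduli <- function(materials) {
  validate_materials(materials)
  dplyr::mutate(materials,
    E  = 9 * .data$K * .data$G / (3 * .data$K + .data$G),
    nu = (3 * .data$K - 2 * .data$G) / (2 * (3 * .data$K + .data$G)),
    cp = sqrt((.data$K + 4 * .data$G / 3) / .data$rho),
    cs = sqrt(.data$G / .data$rho))
}

#' Biot effective-stress coefficient
#'
#' `alpha = 1 - K/Ks`: the fraction of pore pressure transmitted to the
#' total stress. Non-poroelastic rows get `alpha = NA`. A warning is issued
#' if `alpha < theta`, which standard micromechanical bounds disallow but
#' which can occur for tabulated tissue data.
#'
#' @inheritParams derived_moduli
#' @return The input with a column `alpha` appended.
#' @export
biot_alpha <- function(materials) {
  validate_materials(materials)
  out <- dplyr::mutate(materials,
    alpha = ifelse(.data$poroelastic, 1 - .data$K / .data$Ks, NA_real_))
  bad <- which(out$poroelastic & out$alpha < out$theta)
  if (length(bad))
    warning("alpha < theta for: ", paste(out$name[bad], collapse = ", "),
            " (outside the Biot-Willis bound; storage modulus still computed)",
            call. = FALSE)
  out
}

#' Biot storage modulus
#'
#' Standard Biot-Willis storage relation
#' `1/M = theta/Kf + (alpha - theta)/Ks`. For tabulated tissues with
#' `alpha < theta` (outside the Biot-Willis bound, e.g. a skeleton as stiff
#' as its grains) the grain-storage term is clamped at zero, leaving the
#' pure fluid storage `M = Kf/theta`; such rows are flagged with a warning
#' by [biot_alpha()].
#'
#' @inheritParams derived_moduli
#' @param fluid a [fluid_model()].
#' @return The input with columns `alpha` and `M` appended.
#' @export
biot_modulus <- function(materials, fluid = fluid_model()) {
  m <- if ("alpha" %in% names(materials)) materials else
    suppressWarnings(biot_alpha(materials))
  dplyr::mutate(m, M = ifelse(.data$poroelastic,
    1 / (.data$theta / fluid$Kf +
           pmax(.data$alpha - .data$theta, 0) / .data$Ks),
    NA_real_))
}

#' Skempton pore-pressure coefficient
#'
#' `B = alpha*M / (K + alpha^2*M)`: the ratio of induced pore pressure to
#' mean compressive stress under instantaneous undrained loading. Used by
#' the undrained verification oracle.
#'
#' @inheritParams biot_modulus
#' @return The input with columns `alpha`, `M` and `B` appended.
#' @export
skempton <- function(materials, fluid = fluid_model()) {
  m <- if ("M" %in% names(materials)) materials else
    biot_modulus(materials, fluid)
  dplyr::mutate(m, B = .data$alpha * .data$M /
                  (.data$K + .data$alpha^2 * .data$M))
}

#' Full poroelastic constant set
#'
#' Convenience pipeline: derived moduli + Biot constants + Skempton
#' coefficient (with undrained wave speed `cp_u`) in one call.
#'
#' @inheritParams biot_modulus
#' @return A tibble with all derived columns.
#' @export
material_constants <- function(materials = builtin_materials(),
                               fluid = fluid_model()) {
  materials |>
    derived_moduli() |>
    skempton(fluid) |>
    dplyr::mutate(
      Ku = ifelse(.data$poroelastic, .data$K + .data$alpha^2 * .data$M, .data$K),
      cp_u = sqrt((.data$Ku + 4 * .data$G / 3) / .data$rho))
}

#' Read or write a material table as structured configuration
#'
#' Materials round-trip through YAML (`.yml`/`.yaml`) or JSON (`.json`)
#' config blocks whose keys mirror the material table columns. Values are SI.
#'
#' @param path file path; format chosen by extension.
#' @param materials a material tibble.
#' @return `read_materials()` returns a material tibble;
#'   `write_materials()` returns `path` invisibly.
#' @export
read_materials <- function(path) {
  recs <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  tb <- if (is.data.frame(recs)) tibble::as_tibble(recs) else
    purrr::map_dfr(recs, tibble::as_tibble)
  tb <- dplyr::mutate(tb, dplyr::across(c("rho", "G", "K", "Ks", "theta", "k"),
                                        as.numeric))
  validate_materials(tb)
  tb
}

#' @rdname read_materials
#' @export
write_materials <- function(materials, path) {
  validate_materials(materials)
  base <- materials[, c("name", "rho", "G", "K", "Ks", "theta", "k",
                        "poroelastic")]
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(base, path, digits = NA, na = "null")
  } else {
    recs <- purrr::transpose(as.list(base) |> purrr::map(as.list))
    yaml::write_yaml(recs, path, precision = 17)
  }
  invisible(path)
}
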