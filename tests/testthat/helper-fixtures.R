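# Small fixtures shared across test files. Everything is generated in code.

mat_row <- function(nm) {
  tb <- builtin_materials()
  tb[tb$name == nm, ]
}

# two bonded automata on the lattice spacing (the smallest solvable system)
two_particle_packing <- function(d = 1e-3, region = "cortical") {
  structure(list(
    particles = tibble::tibble(id = 1:2, x = c(0, d), y = 0, z = 0,
                               region = region),
    bonds = tibble::tibble(i = 1L, j = 2L, r0 = d, S = d^2 / (2 * sqrt(2))),
    d = d), class = "mca_packing")
}

# free elastic block with a smooth (fundamental-mode) velocity seed
free_block_run <- function(t_end, d = 1e-3, n = 6, amp = 1e-3, ...) {
  pk <- pack_block(n * d, n * d, n * d, d)
  z <- pk$particles$z
  v0 <- cbind(0, 0, amp * sin(pi * z / max(z)))
  simulate_mca(pk, protocol_fixed(bottom = integer(0)), t_end = t_end,
               poro = FALSE, damping = 0, v0 = v0, surface_comp = 0, ...)
}
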