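test_that("pair tractions follow the per-side law and interface equilibrium", {
  cort <- mat_row("cortical")
  # 2G * eps with no volumetric term
  tr <- pair_tractions(-1e-3, c(0, 0, 0), cort, cort)
  expect_equal(tr$sigma_n, 2 * cort$G * -1e-3)
  expect_equal(tr$tau, c(0, 0, 0))
  # rest state carries nothing
  expect_equal(pair_tractions(0, c(0, 0, 0), cort, cort)$sigma_n, 0)
  # dissimilar pair: both sides report the same normal stress
  soft <- mat_row("cartilage")
  t2 <- pair_tractions(-1e-3, c(0, 0, 0), cort, soft,
                       eps_vol_i = -5e-4, eps_vol_j = -2e-3)
  other <- pair_tractions(-1e-3, c(0, 0, 0), soft, cort,
                          eps_vol_i = -2e-3, eps_vol_j = -5e-4)
  expect_equal(t2$sigma_n, other$sigma_n, tolerance = 1e-12)
  # with no volumetric offsets the soft side absorbs almost all of the
  # pair strain (in proportion to the shear-stiffness contrast)
  t3 <- pair_tractions(-1e-3, c(0, 0, 0), cort, soft)
  expect_gt(abs(t3$eps_j), 100 * abs(t3$eps_i))
})

test_that("stress homogenisation of a hydrostatic contact set recovers the mean stress", {
  d <- 1e-3
  V <- d^3 / sqrt(2); S <- d^2 / (2 * sqrt(2)); q <- d / 2
  # 12 FCC directions
  dirs <- rbind(
    expand.grid(x = c(-1, 1), y = c(-1, 1), z = 0),
    expand.grid(x = c(-1, 1), y = 0, z = c(-1, 1)),
    expand.grid(x = 0, y = c(-1, 1), z = c(-1, 1)))
  n <- as.matrix(dirs) / sqrt(2)
  p0 <- -2e6                       # uniform normal traction (compression)
  sig <- average_stress(n, p0 * n, S, q, V)
  expect_equal(sig, p0 * diag(3), tolerance = 1e-12)
  expect_equal(sig, t(sig))
  # no contacts, no stress
  expect_equal(average_stress(matrix(0, 0, 3), matrix(0, 0, 3), S, q, V),
               matrix(0, 3, 3))
})

test_that("strain invariants recover hydrostatic and deviatoric parts", {
  G <- 5.55e9
  # pure hydrostatic stress has zero distortional strain
  si <- strain_invariants(diag(c(-3e6, -3e6, -3e6)), G)
  expect_equal(si$p_hydro, 3e6)
  expect_equal(si$eps_eq, 0)
  # uniaxial stress: p = -tr/3, eps_eq = (2/3) |s| / (2G)
  si2 <- strain_invariants(diag(c(-1e6, 0, 0)), G)
  expect_equal(si2$p_hydro, 1e6 / 3)
  expect_equal(si2$eps_eq, (2 / 3) * 1e6 / (2 * G))
  # brute-force tensor oracle on a random symmetric stress
  set.seed(7)
  A <- matrix(rnorm(9, sd = 1e6), 3); A <- (A + t(A)) / 2
  e <- (A - diag(rep(sum(diag(A)) / 3, 3))) / (2 * G)
  ref <- sqrt(2 / 3 * sum(e * e))
  expect_equal(strain_invariants(A, G)$eps_eq, ref)
})

test_that("stable time step follows the fastest present wave speed", {
  pk <- pack_block(6e-3, 6e-3, 6e-3, 1e-3)
  dm <- derived_moduli(builtin_materials())
  expect_equal(stable_dt(pk, safety = 0.2),
               0.2 * 1e-3 / dm$cp[dm$name == "cortical"])
  # halving d halves dt
  pk2 <- pack_block(6e-3, 6e-3, 6e-3, 0.5e-3)
  expect_equal(stable_dt(pk2), stable_dt(pk) / 2)
  # copper is the fastest material when present
  pk$particles$region[1] <- "copper"
  expect_equal(stable_dt(pk, safety = 0.2),
               0.2 * 1e-3 / dm$cp[dm$name == "copper"])
})

test_that("force-free motion is rectilinear and momentum is conserved", {
  pk <- two_particle_packing()
  v0 <- rbind(c(1, 0.5, -0.2), c(1, 0.5, -0.2))  # rigid translation
  res <- simulate_mca(pk, protocol_fixed(bottom = integer(0)), t_end = 1e-6,
                      dt = 1e-9, poro = FALSE, damping = 0, v0 = v0)
  expect_equal(res$final$vel, v0, tolerance = 1e-9)
  expect_equal(max(abs(res$fields$sxx)), 0, tolerance = 1)
  # random internal motion in a free block: total momentum fixed
  blk <- pack_block(5e-3, 5e-3, 5e-3, 1e-3)
  set.seed(2)
  vr <- matrix(rnorm(3 * nrow(blk$particles), sd = 1e-3), ncol = 3)
  r2 <- simulate_mca(blk, protocol_fixed(bottom = integer(0)), t_end = 2e-5,
                     poro = FALSE, damping = 0, v0 = vr, surface_comp = 0)
  expect_equal(colSums(r2$final$vel), colSums(vr), tolerance = 1e-9)
})

test_that("a bonded pair oscillates at the linearised bond frequency", {
  d <- 1e-3
  pk <- two_particle_packing(d)
  v0 <- rbind(c(1e-4, 0, 0), c(-1e-4, 0, 0))
  res <- simulate_mca(pk, protocol_fixed(bottom = integer(0)), t_end = 2e-5,
                      dt = 1e-9, poro = FALSE, damping = 0, v0 = v0,
                      probes = 1, monitor_every = 1, surface_comp = 0)
  x <- res$probes$p_hydro
  peaks <- which(diff(sign(diff(x))) == -2) + 1
  f_meas <- 1 / mean(diff(res$probes$t[peaks]))
  # closed form: k_eff = S (2G + 3 lambda) / d, the 3 lambda term from the
  # bond's own volumetric strain (eps_vol = 3 eps_n for an isolated pair)
  m <- mat_row("cortical")
  S <- d^2 / (2 * sqrt(2)); lam <- m$K - 2 * m$G / 3
  keff <- S * (2 * m$G + 3 * lam) / d
  mass <- m$rho * d^3 / sqrt(2)
  f_ref <- sqrt(keff / (mass / 2)) / (2 * pi)
  expect_equal(f_meas, f_ref, tolerance = 0.02)
})

test_that("an undamped free block conserves energy over ten thousand steps", {
  res <- free_block_run(t_end = 6e-4, monitor_every = 1)
  expect_gt(res$meta$n_steps, 1e4)
  # the potential-energy estimate is a homogenised approximation, so audit
  # conservation through the kinetic-energy peaks of the oscillation
  ke <- res$trace$ke
  third <- length(ke) %/% 3
  expect_equal(max(ke[(2 * third):length(ke)]), max(ke[1:third]),
               tolerance = 0.01)
})

test_that("small rigid rotation produces no stress", {
  blk <- pack_block(5e-3, 5e-3, 5e-3, 1e-3)
  ctr <- colMeans(as.matrix(blk$particles[, c("x", "y", "z")]))
  om <- c(0, 0, 2)                          # rad/s about z
  rel <- sweep(as.matrix(blk$particles[, c("x", "y", "z")]), 2, ctr)
  v0 <- t(apply(rel, 1, function(r) c(om[2] * r[3] - om[3] * r[2],
                                      om[3] * r[1] - om[1] * r[3],
                                      om[1] * r[2] - om[2] * r[1])))
  res <- simulate_mca(blk, protocol_fixed(bottom = integer(0)), t_end = 5e-6,
                      poro = FALSE, damping = 0, v0 = v0, surface_comp = 0)
  # rotation by ~1e-5 rad: residual stress (from the spin-up transient of
  # initially non-rotating particles) stays far below G * angle
  expect_lt(max(abs(res$fields$szz)), 0.02 * 5.55e9 * 2 * 5e-6)
})

test_that("uniform block compression recovers E and nu for dissimilar tissues", {
  for (nm in c("cortical", "cartilage")) {
    et <- elasticity_test(nm, n = 8)
    expect_lt(abs(et$E_meas / et$E_ref - 1), 0.05)
    expect_lt(abs(et$nu_meas - et$nu_ref), 0.02)
    expect_lt(et$ke_ratio, 0.01)
  }
})
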