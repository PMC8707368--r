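test_that("effective stress shifts only the diagonal", {
  sig <- matrix(c(0, 2e5, 0, 2e5, 0, 0, 0, 0, 0), 3)  # pure shear
  tot <- effective_stress(sig, p = 1e5, alpha = 0.78)
  expect_equal(tot - diag(diag(tot)), sig - diag(diag(sig)))
  expect_equal(diag(tot), diag(sig) - 0.78 * 1e5 * c(1, 1, 1))
  expect_equal(effective_stress(sig, 0, 0.78), sig)
})

test_that("storage law reproduces drained and undrained limits", {
  mc <- material_constants()
  cart <- mc[mc$name == "cartilage", ]
  # sealed compression raises pressure by -M alpha d_eps
  dp <- pressure_update(-1e-4, 0, cart$alpha, cart$M)
  expect_equal(dp, -cart$M * cart$alpha * -1e-4)
  expect_gt(dp, 0)
  # drained path: inflow exactly balances the skeleton strain
  expect_equal(pressure_update(-1e-4, cart$alpha * -1e-4, cart$alpha, cart$M), 0)
})

test_that("Darcy pair flux is antisymmetric with harmonic-mean permeability", {
  Q <- darcy_exchange(1e3, 0, k_i = 1e-11, k_j = 1e-11, S = 1e-6, r = 1e-3)
  expect_equal(Q, 1e-8)
  expect_equal(darcy_exchange(5, 5, 1e-11, 1e-11, 1e-6, 1e-3), 0)
  # harmonic mean collapses to the smaller permeability
  Qh <- darcy_exchange(1e3, 0, 1e-11, 1e-17, 1e-6, 1e-3)
  expect_lt(Qh, 2 * darcy_exchange(1e3, 0, 1e-17, 1e-17, 1e-6, 1e-3) * 1.001)
  expect_error(darcy_exchange(1, 0, -1e-11, 1e-11, 1e-6, 1e-3), "negative")
})

test_that("sealed compression produces the Skempton pore pressure", {
  mats <- builtin_materials()
  mc <- material_constants(mats)
  for (nm in c("cartilage", "cancellous")) {
    d <- 1e-3; n <- 8; L <- n * d
    pk <- pack_block(L, L, L, d, region = nm)
    qs <- poromca:::quasi_static_pars(pk, mats, fluid_model(), TRUE, 25, 1)
    H <- diff(range(pk$particles$z))
    strain <- 1e-3
    prot <- protocol_compression(strain * H / qs$t_load)
    prot$confine_lateral <- TRUE
    res <- suppressMessages(
      simulate_mca(pk, prot, t_end = qs$t_load, damping = qs$damping,
                   poro = TRUE))
    f <- res$fields
    core <- abs(f$z - H / 2) < 0.3 * H &
      pmax(abs(f$x - L / 2), abs(f$y - L / 2)) < 0.3 * L
    B_meas <- mean(f$p_fluid[core]) / mean(f$p_hydro[core])
    B_ref <- mc$B[mc$name == nm]
    expect_lt(abs(B_meas / B_ref - 1), 0.05)
    # axial modulus matches the undrained confined modulus
    Mu <- mean(f$szz[core]) / (-strain)
    Mu_ref <- confined_modulus(mats[mats$name == nm, ], drained = FALSE)
    expect_lt(abs(Mu / Mu_ref - 1), 0.05)
    # sealed system: global fluid content conserved to round-off
    expect_lt(glance(res)$zeta_drift, 1e-12)
  }
})

test_that("closed two-particle exchange conserves fluid content", {
  # seed a pressure difference by compressing one side of a dissimilar pair
  # via the coupled solver, then verify the monitor's content bookkeeping
  pk <- pack_block(5e-3, 5e-3, 5e-3, 1e-3, region = "cancellous")
  bs <- boundary_sets(pk)
  res <- suppressMessages(simulate_mca(
    pk, protocol_compression(0.05), t_end = 2e-5, damping = 1e5, poro = TRUE))
  expect_lt(glance(res)$zeta_drift, 1e-12)
  expect_gt(max(res$fields$p_fluid), 0)
})

test_that("cartilage stays effectively undrained on the pulse time scale", {
  # low permeability prevents rapid outflow under dynamic loading
  pk <- pack_block(8e-3, 8e-3, 8e-3, 1e-3, region = "cartilage")
  pulse <- shock_pulse(efd_target = 120, t_total = 5e-6)
  res <- simulate_mca(pk, protocol_pulse(pulse, on = "top", dir = c(0, 0, -1)),
                      t_end = 1e-5, damping = 0, poro = TRUE)
  # fractional fluid redistribution below 1% of porosity
  expect_lt(max(abs(res$final$zeta)) / 0.8, 0.01)
  expect_gt(max(res$fields$max_p_fluid), 0)
})

test_that("column with a drained end relaxes toward zero excess pressure", {
  tz <- terzaghi_test(Tv_end = 0.35)
  # profile matches the series solution
  expect_lt(tz$rms_rel, 0.05)
  # pressure decays from the undrained value and vanishes at the drain
  expect_lt(max(tz$profile$p_sim), 1.05 * tz$sigma_meas)
  # excess pressure grows monotonically with depth below the drain
  expect_true(all(diff(tz$profile$p_sim[order(tz$profile$z_depth)]) > 0))
  expect_equal(tz$profile$p_sim[which.min(tz$profile$z_depth)] /
                 max(tz$profile$p_sim),
               tz$profile$p_ref[which.min(tz$profile$z_depth)] /
                 max(tz$profile$p_ref), tolerance = 0.2)
})
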