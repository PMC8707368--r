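test_that("pulse profile is a single calibrated sin^2 lobe", {
  p <- shock_pulse(v_peak = 10, t_total = 5e-6)
  expect_equal(pulse_profile(2.5e-6, p), 10)
  expect_equal(pulse_profile(5.1e-6, p), 0)
  expect_equal(pulse_profile(-1e-9, p), 0)
  # closed-form fluence integral int v^2 dt = (3/8) v^2 T, checked by
  # quadrature
  quad <- stats::integrate(function(t) pulse_profile(t, p)^2, 0, 5e-6,
                           subdivisions = 1000L)$value
  expect_equal(quad, 3 / 8 * 10^2 * 5e-6, tolerance = 1e-6)
  # fluence is invariant under time-grid refinement
  riemann <- function(n) {
    t <- seq(0, 5e-6, length.out = n)
    sum(pulse_profile(t, p)^2) * diff(t[1:2])
  }
  expect_lt(abs(riemann(2000) / riemann(1000) - 1), 0.01)
})

test_that("Tp is the 90%-rise time and is amplitude-invariant", {
  t <- seq(0, 5e-6, length.out = 4001)
  lobe <- sin(pi * t / 5e-6)^2
  tp <- tp_from_profile(t, lobe)
  # root of sin^2(pi t / T) = 0.9, found independently
  root <- stats::uniroot(function(x) sin(pi * x / 5e-6)^2 - 0.9,
                         c(0, 2.5e-6), tol = 1e-15)$root
  expect_equal(tp, root, tolerance = 1e-6)
  expect_equal(root / 5e-6, 0.39758, tolerance = 1e-4)
  expect_equal(tp_from_profile(t, 7 * lobe), tp, tolerance = 1e-9)
  # step function reaches 90% at the first sample
  expect_equal(tp_from_profile(t, rep(1, length(t))), 0)
  expect_error(tp_from_profile(t, -lobe), "positive")
})

test_that("energy flux density follows the plane-wave dose relation", {
  expect_equal(efd(10, 1.5e6, 4e-6), 300)     # 0.3 mJ/mm^2
  expect_equal(efd(0, 1.5e6, 4e-6), 0)
  expect_equal(efd(20, 1.5e6, 4e-6), 4 * efd(10, 1.5e6, 4e-6))
})

test_that("pulse calibration inverts the dose relation", {
  Tp <- 2e-6
  for (target in c(120, 330, 800)) {
    v <- calibrate_pulse(target, 1.5e6, Tp)
    expect_equal(efd(v, 1.5e6, Tp), target)
  }
  expect_equal(calibrate_pulse(480, 1.5e6, Tp),
               2 * calibrate_pulse(120, 1.5e6, Tp))
  expect_equal(calibrate_pulse(120, 3e6, Tp),
               calibrate_pulse(120, 1.5e6, Tp) / sqrt(2))
  # constructor wires the calibration through
  p <- shock_pulse(efd_target = 330)
  expect_equal(p$PII, 330)
})

test_that("protocols constrain the right boundary sets", {
  pk <- pack_block(6e-3, 6e-3, 6e-3, 1e-3)
  prot <- protocol_compression(0.01)
  r2 <- simulate_mca(pk, prot, t_end = 1e-5, poro = FALSE, damping = 1e5)
  bs <- boundary_sets(pk)
  disp <- r2$final$pos - as.matrix(pk$particles[, c("x", "y", "z")])
  expect_equal(max(abs(disp[bs$bottom, ])), 0)
  # top layer moved down by v * t
  expect_equal(mean(disp[bs$top, 3]), -0.01 * r2$meta$n_steps * r2$meta$dt,
               tolerance = 1e-6)
  # prescribed displacement stops at u_total
  r3 <- simulate_mca(pk, protocol_displacement(2e-5, 5e-6), t_end = 1e-5,
                     poro = FALSE, damping = 1e5)
  d3 <- r3$final$pos - as.matrix(pk$particles[, c("x", "y", "z")])
  expect_equal(mean(d3[bs$top, 3]), -2e-5, tolerance = 0.01)
})
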