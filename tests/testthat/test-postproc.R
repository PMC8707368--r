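fake_fields <- function(stress, strain, fluid, part = "tibia_cartilage") {
  tibble::tibble(part = part, region = "cartilage",
                 max_p_hydro = stress, max_eps_eq = strain,
                 max_p_fluid = fluid)
}

test_that("criteria masks implement the regeneration windows", {
  th <- criteria_thresholds()
  f <- fake_fields(c(0.5e6, 0, 3e6), c(1e-3, 0, 5e-3), c(68e3, 0, 3e6))
  m <- criteria_masks(f, th)
  expect_equal(m$crit_stress, c(TRUE, FALSE, FALSE))   # window, below, above
  expect_equal(m$crit_strain, c(TRUE, FALSE, TRUE))
  expect_equal(m$crit_fluid, c(TRUE, FALSE, FALSE))
  expect_equal(m$crit_all, c(TRUE, FALSE, FALSE))
  expect_equal(m$crit_onset, c(TRUE, FALSE, TRUE))
  # zero fields meet nothing; infinite windows catch everything
  z <- criteria_masks(fake_fields(0, 0, 0), th)
  expect_false(any(z$crit_stress | z$crit_strain | z$crit_fluid))
  wide <- criteria_thresholds(stress_lo = -1e30, stress_hi = 1e30,
                              no_genesis_below = -2e30,
                              fluid_lo = -1e30, fluid_hi = 1e30,
                              strain_lo = -1e30, strain_hi = 1e30)
  w <- criteria_masks(fake_fields(0, 0, 0), wide)
  expect_true(all(w$crit_all))
  # masks are pure: identical inputs, identical outputs
  expect_identical(criteria_masks(f, th), criteria_masks(f, th))
  expect_error(criteria_masks(tibble::tibble(a = 1), th), "lack")
})

test_that("criteria summary reports per-region volume fractions", {
  f <- fake_fields(c(0.5e6, 0.5e6, 0, 0), c(1e-3, 1e-3, 0, 0),
                   c(68e3, 68e3, 0, 0))
  sm <- criteria_summary(criteria_masks(f), by = "part")
  expect_equal(sm$frac_all, 0.5)
  expect_true(all(sm$frac_stress >= 0 & sm$frac_stress <= 1))
})

test_that("stiffness fit recovers known slopes", {
  u <- seq(0, 1e-4, length.out = 50)
  tr <- tibble::tibble(disp_top = u, force_top = 3e7 * u + 5)
  fit <- suppressWarnings(stiffness_fit(tr))  # lm flags the perfect fit
  expect_equal(fit$stiffness, 3e7)
  expect_equal(glance(fit)$r.squared, 1)
  # with noise: slope within two standard errors
  set.seed(11)
  tr2 <- tibble::tibble(disp_top = u, force_top = 3e7 * u + rnorm(50, 0, 50))
  f2 <- stiffness_fit(tr2, frac = c(0, 1))
  expect_lt(abs(f2$stiffness - 3e7), 2.5 * f2$se)
  expect_error(stiffness_fit(tr[1:2, ]), "few")
  expect_equal(tidy(f2)$term, "stiffness")
})

test_that("block stiffness scales with cross-section", {
  d <- 1e-3
  run <- function(ly) {
    pk <- pack_block(8e-3, ly, 8e-3, d)
    qs <- poromca:::quasi_static_pars(pk, builtin_materials(), NULL, FALSE,
                                      25, 1)
    H <- diff(range(pk$particles$z))
    v <- 2e-3 * H / qs$t_load
    res <- simulate_mca(pk, protocol_compression(v), t_end = qs$t_load,
                        poro = FALSE, damping = qs$damping)
    stiffness_fit(res$trace)$stiffness
  }
  k1 <- run(8e-3); k2 <- run(16e-3)
  expect_equal(k2 / k1, 2, tolerance = 0.05)
})

test_that("longitudinal pulse speed matches the P-wave speed", {
  ws <- wave_speed_test("cortical")
  expect_lt(abs(ws$cp_meas / ws$cp_ref - 1), 0.05)
})

test_that("dosimetry recomputed from the contact trace is self-consistent", {
  dc <- dosimetry_check(efd_target = 120)
  expect_lt(abs(dc$PII_measured / dc$PII_requested - 1), 0.20)
  expect_lt(abs(dc$Tp_measured / dc$Tp - 1), 0.10)
})

test_that("validation compression yields a monotone force-displacement curve", {
  vr <- suppressMessages(suppressWarnings(
    validation_run(knee_analog_spec(), d = 1.5e-3)))
  g <- glance(vr)
  expect_gt(g$force_at_max, 0)
  expect_equal(g$disp_max, 0.3e-3, tolerance = 0.02)
  # monotone trend over the loading ramp (small dynamic ripples allowed)
  cur <- vr$curve[vr$curve$disp > 0.05 * max(vr$curve$disp), ]
  expect_gt(stats::cor(cur$disp, cur$force, method = "spearman"), 0.99)
  expect_gt(cur$force[nrow(cur)], 0.9 * max(cur$force))
  expect_lt(g$ke_ratio, 0.01)
  expect_gt(glance(vr$fit)$r.squared, 0.99)
})
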