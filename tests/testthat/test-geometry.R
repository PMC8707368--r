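test_that("FCC block packing has full interior coordination and clean bonds", {
  pk <- pack_block(8e-3, 8e-3, 8e-3, 1e-3)
  deg <- tabulate(c(pk$bonds$i, pk$bonds$j), nbins = nrow(pk$particles))
  expect_equal(max(deg), 12)
  expect_gt(mean(deg == 12), 0.2)        # interior fraction
  # bonds sit on the lattice spacing and are duplicate-free
  expect_true(all(abs(pk$bonds$r0 - pk$d) / pk$d < 1e-9))
  key <- paste(pmin(pk$bonds$i, pk$bonds$j), pmax(pk$bonds$i, pk$bonds$j))
  expect_equal(anyDuplicated(key), 0L)
  expect_true(all(pk$bonds$i != pk$bonds$j))
  expect_error(pack_block(1e-3, 8e-3, 8e-3, 1e-3), "degenerate")
})

test_that("particle count scales inversely with element volume", {
  n1 <- nrow(pack_block(12e-3, 12e-3, 12e-3, 1e-3)$particles)
  n2 <- nrow(pack_block(12e-3, 12e-3, 12e-3, 0.5e-3)$particles)
  expect_equal(n2 / n1, 8, tolerance = 0.15)
})

test_that("knee analog populates every tissue region at all sweep sizes", {
  sp <- knee_analog_spec()
  want <- c("cortical", "cancellous", "cartilage", "fibrocartilage",
            "fibrous", "capsule_shell", "copper")
  for (d in c(2.0e-3, 1.0e-3)) {
    pk <- knee_analog(sp, d)
    expect_setequal(unique(pk$particles$region), want)
    expect_true(all(table(pk$particles$region) > 0))
  }
  # anatomical parts distinguish the two bones and cartilage plates
  pk <- knee_analog(sp, 1.5e-3)
  expect_true(all(c("tibia_cartilage", "femur_cartilage", "meniscus",
                    "applicator") %in% pk$particles$part))
})

test_that("knee analog is deterministic and geometry is label-independent", {
  sp <- knee_analog_spec()
  a <- knee_analog(sp, 1.5e-3)
  b <- knee_analog(sp, 1.5e-3)
  expect_identical(a$particles, b$particles)
  expect_identical(a$bonds, b$bonds)
  # positions come from the lattice alone, labels from the spec
  sp2 <- knee_analog_spec(include_applicator = FALSE)
  c1 <- knee_analog(sp2, 1.5e-3)
  srt <- function(df) {
    m <- as.matrix(as.data.frame(df[, c("x", "y", "z")]))
    unname(m[order(m[, 1], m[, 2], m[, 3]), ])
  }
  expect_equal(srt(a$particles[a$particles$region != "copper", ]),
               srt(c1$particles))
})

test_that("under-resolved layers error or warn by name", {
  sp <- knee_analog_spec()
  expect_error(knee_analog(sp, 4.5e-3), "meniscus")
  expect_warning(knee_analog(sp, 2.5e-3), "2\\*d")
})

test_that("boundary sets are disjoint single layers", {
  pk <- knee_analog(knee_analog_spec(), 1.5e-3)
  bs <- boundary_sets(pk)
  expect_length(intersect(bs$top, bs$bottom), 0)
  expect_length(intersect(bs$top, bs$applicator), 0)
  expect_gt(length(bs$bottom), 0)
  expect_true(all(pk$particles$region[bs$applicator] == "copper"))
  expect_true(all(bs$applicator_face %in% bs$applicator))
  # block fixture: one lattice plane per face
  blk <- pack_block(6e-3, 6e-3, 6e-3, 1e-3)
  bb <- boundary_sets(blk)
  expect_equal(length(unique(blk$particles$z[bb$top])), 1L)
  expect_equal(length(unique(blk$particles$z[bb$bottom])), 1L)
})
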