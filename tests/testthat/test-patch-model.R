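test_that("patch model is deterministic and respects UVC ranges", {
  m1 <- build_patch_model(1000, seed = 1)
  m2 <- build_patch_model(1000, seed = 1)
  expect_identical(m1$patches, m2$patches)
  expect_false(identical(m1$patches, build_patch_model(1000, seed = 2)$patches))

  p <- m1$patches
  expect_true(all(p$phi >= -pi & p$phi <= pi))
  expect_true(all(p$rho >= 0 & p$rho <= 1))
  expect_true(all(p$z >= 0 & p$z <= 1))
  expect_equal(sqrt(p$dx^2 + p$dy^2 + p$dz^2), rep(1, nrow(p)))
  expect_error(build_patch_model(5, seed = 1), "n_patches")
})

test_that("free-wall patch fraction matches the configured geometry", {
  m <- build_patch_model(1000, seed = 1)
  frac <- mean(abs(m$patches$phi) > pi / 2)
  expect_lt(abs(frac - m$free_wall_fraction), 0.05)
})

test_that("adjacency graph is connected for the intact myocardium", {
  for (s in 1:3) {
    m <- build_patch_model(500, seed = s)
    expect_equal(igraph::components(m$graph)$no, 1)
  }
})

test_that("zone classification follows scar-local normalised coordinates", {
  sc <- scar_definition("lv_free_wall", phi_range = c(pi / 2, pi),
                        rho_range = c(0.1, 0.9), z_range = c(0.3, 0.9))
  centre <- list(phi = 3 * pi / 4, rho = 0.5, z = 0.6)
  expect_equal(classify_zone(centre, sc), "dense")

  outside_z <- list(phi = 3 * pi / 4, rho = 0.5, z = 0.95)
  expect_equal(classify_zone(outside_z, sc), "healthy")

  # scar-local coordinate 0.95 on one axis: |0.95 - 0.5| = 0.45 exceeds the
  # boundary-zone half-width 5/12 ~= 0.4167, hence the low-density outer
  # region; 0.9 (distance 0.4) is still boundary zone
  edge_rho <- list(phi = 3 * pi / 4, rho = 0.1 + 0.8 * 0.95, z = 0.6)
  expect_equal(classify_zone(edge_rho, sc), "low")
  expect_equal(classify_zone(list(phi = 3 * pi / 4, rho = 0.1 + 0.8 * 0.9,
                                  z = 0.6), sc), "bz")

  # scar-local coordinate 0.1: |0.1 - 0.5| = 0.4 lies between the dense
  # half-width 1/3 and the boundary half-width 5/12, hence boundary zone
  expect_equal(classify_zone(list(phi = 3 * pi / 4, rho = 0.1 + 0.8 * 0.1,
                                  z = 0.6), sc), "bz")
  expect_equal(classify_zone(centre, scar_definition("none")), "healthy")
})

test_that("deterministic removal limits: certain and impossible", {
  m <- build_patch_model(500, seed = 2)
  all_rm <- scar_definition("lv_free_wall", p_dense = 1, p_bz = 1, p_low = 1)
  m1 <- apply_scar(m, all_rm, seed = 9)
  expect_true(all(m1$patches$removed[m1$patches$zone != "healthy"]))
  expect_false(any(m1$patches$removed[m1$patches$zone == "healthy"]))

  none_rm <- scar_definition("lv_free_wall", p_dense = 0, p_bz = 0, p_low = 0)
  m0 <- apply_scar(m, none_rm, seed = 9)
  expect_false(any(m0$patches$removed))
  expect_identical(apply_scar(m, all_rm, seed = 9)$patches,
                   m1$patches)
})

test_that("concentric scar enlargement never increases survivors", {
  m <- build_patch_model(800, seed = 4)
  centre <- c(3 * pi / 4, 0.5, 0.6)
  half <- cbind(phi = c(0.2, 0.4, 0.7), rho = c(0.1, 0.2, 0.35),
                z = c(0.1, 0.2, 0.3))
  survivors <- sapply(1:3, function(i) {
    sc <- scar_definition("lv_free_wall",
                          phi_range = centre[1] + c(-1, 1) * half[i, "phi"],
                          rho_range = centre[2] + c(-1, 1) * half[i, "rho"],
                          z_range = centre[3] + c(-1, 1) * half[i, "z"])
    sum(!apply_scar(m, sc, seed = 11)$patches$removed)
  })
  expect_true(all(diff(survivors) <= 0))
})

test_that("scar definition validates its invariants", {
  expect_error(scar_definition("lv_free_wall", p_dense = 0.5, p_bz = 0.7),
               "p_dense")
  expect_error(scar_definition("septum", rho_range = c(0.5, 1.2)), "rho_range")
  expect_error(scar_definition("septum", dense_fraction = 0.9,
                               bz_fraction = 0.8), "dense_fraction")
  expect_error(scar_definition("septum", slow_factor_dense = 0.8), "slowing")
})
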