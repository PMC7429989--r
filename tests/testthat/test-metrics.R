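window_over <- function(vcg, from_ms, to_ms) {
  i0 <- which(vcg$t == from_ms)
  i1 <- which(vcg$t == to_ms)
  vcgscar:::qrs_window(i0, i1, vcg$t, 0.15)
}

test_that("QRS areas follow signed trapezoidal integration", {
  fs <- 1000
  t <- seq(0, 200, 1)
  # x constant 1 mV over the window: rectangle of 100 mV.ms
  v1 <- vcg_trace(cbind(rep(1, length(t)), 0, 0), fs)
  a1 <- qrs_area(v1, window_over(v1, 50, 150))
  expect_equal(unname(a1["area_x"]), 100)
  expect_equal(unname(a1["qrs_area"]), 100)

  # 3-4-5 combination
  v2 <- vcg_trace(cbind(rep(0.03, length(t)), rep(0.04, length(t)), 0), fs)
  a2 <- qrs_area(v2, window_over(v2, 0, 100))
  expect_equal(unname(a2["qrs_area"]), 5)
  expect_equal(a2[["qrs_area"]]^2,
               a2[["area_x"]]^2 + a2[["area_y"]]^2 + a2[["area_z"]]^2,
               tolerance = 1e-12)

  # odd symmetry about the window midpoint integrates to zero
  x <- t - 100
  v3 <- vcg_trace(cbind(x, 0, 0), fs)
  expect_equal(unname(qrs_area(v3, window_over(v3, 50, 150))["area_x"]), 0)
})

test_that("weighted angles match hand-computed values", {
  fs <- 1000
  v <- vcg_trace(matrix(c(1, 0, 0), 10, 3, byrow = TRUE), fs)
  w <- window_over(v, 0, 9)
  expect_equal(weighted_angles(v, w), c(waa = 0, wae = 90))

  vy <- vcg_trace(matrix(c(0, 2, 0), 10, 3, byrow = TRUE), fs)
  expect_equal(weighted_angles(vy, window_over(vy, 0, 9)),
               c(waa = 90, wae = 0))

  # two samples: (1,0,0) with magnitude 1 and +y with magnitude 3;
  # circular azimuth mean = direction of (1,3); elevation mean = 22.5
  v2 <- vcg_trace(rbind(c(1, 0, 0), c(0, 3, 0)), fs)
  w2 <- vcgscar:::qrs_window(1, 2, v2$t, 0.15)
  ang <- weighted_angles(v2, w2)
  expect_equal(unname(ang["waa"]), atan2(3, 1) * 180 / pi)
  expect_equal(unname(ang["wae"]), 22.5)

  vz <- vcg_trace(matrix(0, 10, 3), fs)
  expect_error(weighted_angles(vz, window_over(vz, 0, 9)), "undefined angle")
})

test_that("dipole extrema obey the stated conventions", {
  fs <- 1000
  v <- vcg_trace(matrix(c(0, 0, 2), 20, 3, byrow = TRUE), fs)
  ext <- dipole_extrema(v, window_over(v, 5, 15))
  expect_equal(ext$vcg_mean_mag, 2)
  expect_equal(ext$vcg_max_mag, 2)
  expect_equal(ext$t_vcg_max, 5)          # constant trace: first sample wins
  expect_equal(unname(ext$mean_weighted_dipole), c(0, 0, 1))

  # unique interior peak
  xyz <- matrix(c(1, 0, 0), 21, 3, byrow = TRUE)
  xyz[11, ] <- c(0, 5, 0)
  vp <- vcg_trace(xyz, fs)
  extp <- dipole_extrema(vp, window_over(vp, 0, 20))
  expect_equal(extp$vcg_max_mag, 5)
  expect_equal(extp$t_vcg_max, 10)
  expect_equal(unname(extp$max_dipole), c(0, 5, 0))

  # equal maxima: the earlier time wins
  xyz[17, ] <- c(0, 0, 5)
  vt <- vcg_trace(xyz, fs)
  expect_equal(dipole_extrema(vt, window_over(vt, 0, 20))$t_vcg_max, 10)

  # mid-point index uses floor
  w <- window_over(vp, 2, 7)
  expect_equal(unname(dipole_extrema(vp, w)$dipole_at_mid),
               unname(vp$xyz[floor((w$start_index + w$end_index) / 2), ]))
})

test_that("angular differences hit the boundary cases exactly", {
  v <- c(0.3, -0.2, 0.9)
  expect_identical(angular_difference(v, v), 0)
  expect_identical(angular_difference(v, -v), 180)
  expect_equal(angular_difference(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angular_difference(c(1, 0, 0), c(1, 1, 0)), 45)
  expect_error(angular_difference(c(0, 0, 0), v), "undefined angle")
})

test_that("metrics are rotation-equivariant", {
  e <- simulate_ecg(build_patch_model(300, seed = 9),
                    simulation_scenario(600, scar_definition("none"),
                                        seed = 9, n_patches = 300))
  v <- kors_transform(e)
  R <- rotation_matrix(c(1, 2, 3), 0.7)
  vr <- vcg_trace(v$xyz %*% t(R), v$sampling_rate)

  m <- vcg_metrics(v)
  mr <- vcg_metrics(vr)
  expect_equal(mr$window$start_index, m$window$start_index)
  expect_equal(mr$window$end_index, m$window$end_index)
  expect_equal(mr$qrsd, m$qrsd)
  expect_equal(mr$qrs_area, m$qrs_area, tolerance = 1e-9)
  expect_equal(mr$vcg_mean_mag, m$vcg_mean_mag, tolerance = 1e-9)
  expect_equal(mr$vcg_max_mag, m$vcg_max_mag, tolerance = 1e-9)
  expect_equal(mr$t_vcg_max, m$t_vcg_max)
  for (f in c("max_dipole", "mean_weighted_dipole", "dipole_at_start",
              "dipole_at_mid", "dipole_at_end")) {
    expect_equal(unname(mr[[f]]), unname(as.numeric(R %*% m[[f]])),
                 tolerance = 1e-9)
  }
  # pairwise angular differences are rotation-invariant
  expect_equal(angular_difference(mr$dipole_at_start, mr$dipole_at_end),
               angular_difference(m$dipole_at_start, m$dipole_at_end),
               tolerance = 1e-9)
})

test_that("metrics are scale-equivariant", {
  e <- simulate_ecg(build_patch_model(300, seed = 10),
                    simulation_scenario(600, scar_definition("none"),
                                        seed = 10, n_patches = 300))
  v <- kors_transform(e)
  vs <- vcg_trace(2.5 * v$xyz, v$sampling_rate)
  m <- vcg_metrics(v)
  ms <- vcg_metrics(vs)
  expect_equal(ms$qrsd, m$qrsd)
  expect_equal(ms$qrs_area, 2.5 * m$qrs_area, tolerance = 1e-12)
  expect_equal(ms$vcg_max_mag, 2.5 * m$vcg_max_mag, tolerance = 1e-12)
  expect_equal(ms$vcg_mean_mag, 2.5 * m$vcg_mean_mag, tolerance = 1e-12)
  expect_equal(ms$waa, m$waa, tolerance = 1e-9)
  expect_equal(ms$wae, m$wae, tolerance = 1e-9)
  expect_equal(unname(ms$mean_weighted_dipole),
               unname(m$mean_weighted_dipole), tolerance = 1e-12)
})
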