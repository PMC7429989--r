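nofilt <- filter_config(enabled = FALSE)

test_that("kors_transform is the documented linear map", {
  n <- 50
  zero <- matrix(0, n, 12, dimnames = list(NULL, NULL))
  colnames(zero) <- c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6))
  e0 <- ecg_recording(zero, 1000)
  expect_true(all(kors_transform(e0)$xyz == 0))

  # unit step on lead I only: the VCG is constant and equals the lead-I
  # column of the Kors matrix
  s <- zero; s[, "I"] <- 1
  # keep limb leads consistent with I = 1, II = 0
  s[, "III"] <- -1; s[, "aVR"] <- -0.5; s[, "aVL"] <- 1; s[, "aVF"] <- -0.5
  v <- kors_transform(ecg_recording(s, 1000))
  K <- kors_matrix()
  for (i in seq_len(n)) expect_equal(unname(v$xyz[i, ]), unname(K[, "I"]))

  # linearity
  set.seed(9)
  a <- ecg_recording(matrix(rnorm(12 * n), n, 12), 1000)
  b <- ecg_recording(matrix(rnorm(12 * n), n, 12), 1000)
  ab <- ecg_recording(a$samples + b$samples, 1000)
  expect_equal(kors_transform(ab)$xyz,
               kors_transform(a)$xyz + kors_transform(b)$xyz)
})

test_that("kors matrix and lead field are mutual pseudo-inverses", {
  K <- unclass(kors_matrix())
  L <- lead_field_matrix()
  expect_equal(unname(K %*% L), diag(3), tolerance = 1e-12)
})

test_that("spatial velocity matches analytic derivatives", {
  fs <- 1000
  t <- seq(0, 500, by = 1000 / fs)
  # constant trace
  v0 <- vcg_trace(cbind(rep(2, length(t)), 1, -1), fs)
  expect_true(all(spatial_velocity(v0, nofilt) == 0))
  # linear ramp: sv = |slope| exactly (central and one-sided differences)
  c_slope <- 0.02
  vl <- vcg_trace(cbind(c_slope * t, 0, 0), fs)
  expect_equal(spatial_velocity(vl, nofilt), rep(abs(c_slope), length(t)))
  # sinusoid: max sv = 2*pi*f within central-difference truncation error
  f <- 5
  vs <- vcg_trace(cbind(sin(2 * pi * f * t / 1000), 0, 0), fs)
  expect_equal(max(spatial_velocity(vs, nofilt)), 2 * pi * f / 1000,
               tolerance = 1e-3)
  expect_error(spatial_velocity(vcg_trace(cbind(1:2, 0, 0), fs), nofilt),
               "3 samples")
})

test_that("QRS delimitation finds the analytically forced window", {
  v <- trapezoid_vcg()
  w <- detect_qrs(v, filter = nofilt)
  expect_equal(w$start_time, 40)
  expect_equal(w$end_time, 140)
  expect_equal(qrs_duration(w), 100)

  # forced rectangular spatial-velocity support
  x <- cumsum(c(rep(0, 50), rep(0.1, 51), rep(0, 100)))
  vr <- vcg_trace(cbind(x, 0, 0), 1000)
  wr <- detect_qrs(vr, filter = nofilt)
  expect_equal(wr$start_index, 50)
  expect_equal(wr$end_index, 101)
})

test_that("threshold zero with strictly positive sv spans the full trace", {
  t <- seq(0, 300, 1)
  # derivative 0.1 + 0.005 cos(t/10) is bounded away from zero, so the
  # spatial velocity is strictly positive everywhere
  v <- vcg_trace(cbind(0.1 * t + 0.05 * sin(t / 10), 0, 0), 1000)
  w <- detect_qrs(v, threshold_fraction = 0, filter = nofilt)
  expect_equal(w$start_index, 1)
  expect_equal(w$end_index, length(t))
})

test_that("delimitation is scale-invariant and monotone in threshold", {
  e <- simulate_ecg(build_patch_model(300, seed = 6),
                    simulation_scenario(600, scar_definition("none"),
                                        seed = 6, n_patches = 300))
  v <- kors_transform(e)
  w1 <- detect_qrs(v)
  v10 <- vcg_trace(10 * v$xyz, v$sampling_rate)
  w10 <- detect_qrs(v10)
  expect_equal(w10$start_index, w1$start_index)
  expect_equal(w10$end_index, w1$end_index)

  fracs <- seq(0.02, 0.9, length.out = 50)
  wins <- lapply(fracs, function(f) detect_qrs(v, threshold_fraction = f))
  starts <- vapply(wins, `[[`, integer(1), "start_index")
  ends <- vapply(wins, `[[`, integer(1), "end_index")
  expect_true(all(diff(starts) >= 0))
  expect_true(all(diff(ends) <= 0))
})

test_that("QRS window brackets the generator's activation span", {
  for (s in c(2, 8)) {
    scenario <- simulation_scenario(600, scar_definition("none"), seed = s,
                                    n_patches = 500)
    e <- simulate_scenario(scenario)
    act <- attr(e, "activation")
    w <- detect_qrs(kors_transform(e))
    span <- 3 * scenario$waveform_sd
    expect_lt(abs(w$start_time - min(act, na.rm = TRUE)), span)
    expect_lt(abs(w$end_time - max(act, na.rm = TRUE)), span)
  }
})
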