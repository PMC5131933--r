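test_that("compare_methods pools both detectors and reports the distance", {
  m <- fixture_surrogate_late()
  r <- compare_methods(m, tau_ms = 30, M = -pi, resolution_mm = 0.5,
                       keep_points = TRUE)
  expect_s3_class(r, "hausdorff_report")
  expect_gt(r$n_a_raw, 0)
  expect_gt(r$n_b_raw, 0)
  expect_equal(r$H_mm, max(r$h_ab_mm, r$h_ba_mm))
  # the two methods pin the same rotor: agreement within a few mm on 3x3 cm
  expect_lt(r$H_mm, 5)
  # identical method against itself is exactly zero
  self <- hausdorff(r$ps_ig, r$ps_ig, 0.5)
  expect_equal(self$H_mm, 0)
})

test_that("chunked detection is invariant to the chunk size", {
  m <- fixture_surrogate_late()
  r1 <- compare_methods(m, chunk_frames = 1000L, keep_points = TRUE)
  r2 <- compare_methods(m, chunk_frames = 37L, keep_points = TRUE)
  expect_equal(r1$H_mm, r2$H_mm)
  expect_equal(as.data.frame(r1$ps_ig), as.data.frame(r2$ps_ig))
  expect_equal(as.data.frame(r1$ps_lc), as.data.frame(r2$ps_lc))
})

test_that("a single-value sweep reproduces compare_methods", {
  m <- fixture_surrogate_late()
  sw <- sweep_compare(m, "tau_ms", 30)
  r <- compare_methods(m, tau_ms = 30)
  expect_equal(sw$hd_mm, r$H_mm)
  sw2 <- sweep_compare(m, "M", -pi)
  expect_equal(sw2$hd_mm, r$H_mm)
})

test_that("tau sweep runs the valid values and skips misaligned ones with a warning", {
  m <- fixture_surrogate_late()
  expect_warning(
    sw <- sweep_compare(m, "tau_ms", c(10, 20, 30, 40, 15.5)),
    "skipped")
  expect_equal(sw$values, c(10, 20, 30, 40, 15.5))
  expect_true(all(is.finite(sw$hd_mm[1:4])))
  expect_true(is.na(sw$hd_mm[5]))
})

test_that("sample-interval sweep decimates from the finest stored movie", {
  m <- fixture_surrogate_late()
  sw <- sweep_compare(m, "sample_interval_ms", c(1, 2, 5))
  expect_true(all(is.finite(sw$hd_mm)))
  # robustness: distances stay on the same few-mm scale across cadences
  expect_lt(max(sw$hd_mm) - min(sw$hd_mm), 3)
})

test_that("the M threshold sweep reuses one phase computation and matches per-M runs", {
  m <- fixture_surrogate_late()
  Ms <- -pi * c(1.4, 1.0, 0.6)
  sw <- sweep_compare(m, "M", Ms)
  for (i in seq_along(Ms)) {
    ri <- compare_methods(m, M = Ms[i])
    expect_equal(sw$hd_mm[i], ri$H_mm)
  }
})

test_that("benchmark reports a speed ratio above one for the local criterion", {
  m <- fixture_surrogate_late()
  b <- benchmark_detectors(m, repeats = 3)
  expect_gt(b$ratio, 1)
  expect_gt(b$ig_ms, 0)
  expect_true(is.finite(b$ratio))  # guarded against division by zero
})

test_that("benchmark scales roughly linearly in pixel count", {
  m <- fixture_surrogate_late()
  sub <- voltage_movie(m$frames[1:60, , ], m$dx_mm, m$frame_interval_ms)
  b_full <- benchmark_detectors(m, repeats = 3)
  b_half <- benchmark_detectors(sub, repeats = 3)
  ratio <- b_full$ig_ms / b_half$ig_ms
  expect_gt(ratio, 1.0)
  expect_lt(ratio, 4.5)
})
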