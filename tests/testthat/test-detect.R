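test_that("wrapped_diff wraps into (-pi, pi]", {
  expect_equal(wrapped_diff(0.9 * pi, -0.9 * pi), -0.2 * pi)
  expect_equal(wrapped_diff(1.2, 1.2), 0)
  expect_equal(wrapped_diff(pi, 0), pi)       # +pi stays +pi
  expect_equal(wrapped_diff(0, pi), pi)       # -pi folds onto +pi
  # brute force over candidate unwrappings k in {-1, 0, 1}
  set.seed(42)
  a <- runif(500, -pi, pi); b <- runif(500, -pi, pi)
  got <- wrapped_diff(a, b)
  brute <- vapply(seq_along(a), function(i) {
    cand <- (a[i] - b[i]) - 2 * pi * (-1:1)
    cand[which.min(abs(cand))]
  }, numeric(1))
  # the minimiser convention differs only at exactly +/- pi, excluded a.s.
  expect_equal(got, brute, tolerance = 1e-12)
  expect_true(all(got > -pi & got <= pi))
})

test_that("winding number is +1 around an analytic vortex and 0 on smooth fields", {
  n <- 21
  r0 <- 11.3; c0 <- 10.6
  ph <- outer(1:n, 1:n, function(r, c) atan2(r - r0, c - c0))
  expect_equal(winding_number(ph, 11, 11), 1L)
  expect_equal(winding_number(ph, 12, 11), 1L)
  expect_equal(winding_number(ph, 3, 3), 0L)   # far from the core
  expect_equal(winding_number(ph * 0 + 1.2, 5, 5), 0L)
  expect_error(winding_number(ph, 1, 5), "interior")
  # reversed field gives -1
  ph2 <- outer(1:n, 1:n, function(r, c) atan2(-(r - r0), c - c0))
  expect_equal(winding_number(ph2, 11, 11), -1L)
})

test_that("winding numbers match the loop-unwrapping oracle on 50 random smooth frames", {
  set.seed(11)
  for (k in 1:50) {
    ph <- random_smooth_phase(n = 16)
    r <- sample(2:15, 1); c <- sample(2:15, 1)
    expect_identical(winding_number(ph, r, c), winding_oracle(ph, r, c))
  }
})

test_that("the compiled winding field agrees with the R reference and per-pixel values", {
  set.seed(12)
  for (k in 1:5) {
    ph <- random_smooth_phase(n = 14)
    wf <- spiralps:::winding_field(ph, margin = 1L)
    expect_identical(wf, spiralps:::winding_field_r(ph, margin = 1L))
    for (r in 2:13) for (c in 2:13)
      expect_identical(wf[r - 1, c - 1], winding_number(ph, r, c))
  }
})

test_that("Iyer-Gray flags a single tight cluster at the analytic core and nothing on planar waves", {
  fx <- fixture_analytic_static()
  pm <- compute_phase(fx$movie, tau_ms = 15)  # omega*tau = pi/2
  truth <- fx$truth
  for (fr in c(30, 100, 180)) {
    ps <- detect_iyer_gray(pm, frame = fr)
    expect_gt(nrow(ps), 0)
    expect_lte(nrow(ps), 8)  # small cluster, not a blob
    # every flagged pixel within 1 (Chebyshev) of the true core
    expect_true(all(pmax(abs(ps$row - truth$row[fr]),
                         abs(ps$col - truth$col[fr])) <= 1))
  }
  # planar wave: phase varies along one axis only
  plane <- array(rep(seq(-3, 3, length.out = 30), each = 400), c(20, 20, 30))
  plane <- plane - 2 * pi * floor((plane + pi) / (2 * pi))
  pmov <- structure(list(frames = plane, tau_ms = 1, frame_interval_ms = 1,
                         dx_mm = 0.25, t0_ms = 0,
                         degenerate = matrix(FALSE, 20, 20)),
                    class = "phase_movie")
  expect_equal(nrow(detect_iyer_gray(pmov, frame = 3)), 0)
})

test_that("location-centric flags exactly the below-threshold negative jumps", {
  # two-frame phase movie built by hand
  th <- array(0, c(3, 3, 2))
  th[2, 2, ] <- c(0.9 * pi, -0.9 * pi)   # raw jump -1.8 pi < -pi -> flagged
  th[1, 1, ] <- c(-0.9 * pi, 0.9 * pi)   # +1.8 pi -> not flagged
  th[3, 3, ] <- c(0.5, 0.4)              # small change -> not flagged
  pmov <- structure(list(frames = th, tau_ms = 1, frame_interval_ms = 1,
                         dx_mm = 0.25, t0_ms = 0,
                         degenerate = matrix(FALSE, 3, 3)),
                    class = "phase_movie")
  ps <- detect_location_centric(pmov, 1)
  expect_equal(nrow(ps), 1)
  expect_equal(c(ps$row, ps$col), c(2, 2))
  expect_equal(ps$frame, 2L)  # reported at frame n+1 by default
  expect_true(is.na(ps$chirality))
  ps0 <- detect_location_centric(
    pmov, 1, detector_config("location_centric", frame_assign = "current"))
  expect_equal(ps0$frame, 1L)
  expect_error(detect_location_centric(pmov, 2), "last frame")
})

test_that("location-centric never fires on the static analytic spiral (its stated blind spot)", {
  # at a motionless core the embedded phase advances smoothly everywhere,
  # so the temporal-discontinuity criterion has nothing to latch onto
  fx <- fixture_analytic_static()
  pm <- compute_phase(fx$movie, tau_ms = 15)
  ps <- detect_movie(pm, detector_config("location_centric"))
  expect_equal(nrow(ps), 0)
})

test_that("location-centric output at a pixel depends only on that pixel's series", {
  m <- fixture_surrogate()
  pm <- compute_phase(m, tau_ms = 30)
  cfg <- detector_config("location_centric")
  ps_full <- detect_movie(pm, cfg)
  px <- c(61, 55)
  # scramble every other pixel's series
  set.seed(99)
  d <- dim(pm$frames)
  scr <- pm$frames
  for (r in 1:d[1]) for (c in 1:d[2]) {
    if (r == px[1] && c == px[2]) next
    scr[r, c, ] <- scr[r, c, sample(d[3])]
  }
  pm2 <- pm; pm2$frames <- scr
  ps_scr <- detect_movie(pm2, cfg)
  sel <- function(ps) ps[ps$row == px[1] & ps$col == px[2],
                         c("frame", "row", "col")]
  expect_equal(sel(ps_full), sel(ps_scr), ignore_attr = TRUE)
})

test_that("both detectors track the surrogate rotor and windings stay in {-1,0,1}", {
  m <- fixture_surrogate()
  pm <- compute_phase(m, tau_ms = 30)
  d <- dim(pm$frames)
  ig <- detect_movie(pm, detector_config("iyer_gray"))
  lc <- detect_movie(pm, detector_config("location_centric"))
  # after the initiation transient there is at least one PS per frame
  late <- 200:d[3]
  expect_gte(mean(late %in% ig$frame), 0.98)
  expect_gt(nrow(lc), 50)
  # winding quantization on a sample of frames
  for (fr in seq(150, d[3], by = 100)) {
    wf <- spiralps:::winding_field(pm$frames[, , fr], 1L)
    expect_true(all(wf %in% -1:1))
  }
})

test_that("detections map consistently onto the display grid after 2x decimation", {
  m <- fixture_surrogate()
  pm <- compute_phase(m, tau_ms = 30)
  ig <- detect_movie(pm, detector_config("iyer_gray"))
  md <- decimate_movie(m, space_factor = 2)
  pmd <- compute_phase(md, tau_ms = 30)
  igd <- detect_movie(pmd, detector_config("iyer_gray"))
  expect_gt(nrow(igd), 0)
  # pooled point clouds agree within one display pixel
  h <- hausdorff(ig, igd, resolution_mm = 0.5)
  expect_lte(h$H_mm, sqrt(2) * 0.5 + 1e-9)
})

test_that("empty-activity movies yield empty point sets", {
  fr <- array(-80, c(10, 10, 50))
  fr[5, 5, ] <- -80 + 1e-3 * sin(1:50)  # negligible ripple
  m <- voltage_movie(fr, 0.25, 1)
  pm <- compute_phase(m, tau_ms = 5)
  expect_equal(nrow(detect_movie(pm, detector_config("iyer_gray"))), 0)
})

test_that("cluster reduction collapses an Iyer-Gray cluster to one centroid", {
  fx <- fixture_analytic_static()
  pm <- compute_phase(fx$movie, tau_ms = 15)
  ps <- detect_iyer_gray(pm, frame = 50)
  red <- reduce_clusters(ps)
  expect_equal(nrow(red), 1)
  expect_lte(max(abs(red$row - fx$truth$row[50])), 1)
})
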