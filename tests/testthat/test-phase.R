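make_movie <- function(frames, dt = 1, dx = 0.25) {
  voltage_movie(frames, dx_mm = dx, frame_interval_ms = dt)
}

test_that("vmean of a constant movie is that constant", {
  fr <- array(-80, c(4, 5, 10))
  vm <- compute_vmean(make_movie(fr))
  expect_true(all(vm == -80))
  expect_equal(dim(vm), c(4, 5))
})

test_that("vmean of an offset sinusoid over whole periods is the offset", {
  tt <- 0:59
  fr <- array(0, c(3, 3, 60))
  offs <- matrix(seq(-80, -40, length.out = 9), 3, 3)
  for (i in 1:3) for (j in 1:3)
    fr[i, j, ] <- offs[i, j] + 7 * cos(2 * pi * tt / 30)  # 2 full periods
  vm <- compute_vmean(make_movie(fr))
  expect_equal(unclass(vm), offs, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("vmean equals a brute-force re-summation and honours windows", {
  set.seed(1)
  fr <- array(rnorm(4 * 4 * 30, -60, 20), c(4, 4, 30))
  m <- make_movie(fr)
  vm <- compute_vmean(m)
  brute <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) brute[i, j] <- mean(fr[i, j, ])
  expect_equal(unclass(vm), brute, ignore_attr = TRUE)
  vmw <- compute_vmean(m, window = c(10, 19))
  brute2 <- apply(fr[, , 11:20], c(1, 2), mean)
  expect_equal(unclass(vmw), brute2, ignore_attr = TRUE)
  expect_error(compute_vmean(m, window = c(100, 200)), "empty")
})

test_that("phase of a cosine with omega*tau = pi/2 is the negated angle", {
  # V - Vmean = cos(omega t), omega = pi/30 per ms, tau = 15 ms
  omega <- pi / 30
  tt <- 0:120
  fr <- array(rep(-60 + cos(omega * tt), each = 9), c(3, 3, 121))
  m <- make_movie(fr)
  pm <- compute_phase(m, vmean = matrix(-60, 3, 3), tau_ms = 15)
  # theta(t) = atan2(cos(w(t+tau)), cos(wt)) = atan2(-sin wt, cos wt) = -wt
  got <- pm$frames[2, 2, ]
  want <- -omega * (0:(length(got) - 1))
  want <- want - 2 * pi * floor((want + pi) / (2 * pi))
  want[want == -pi] <- pi
  expect_equal(got, want, tolerance = 1e-10)
  expect_equal(got[1], 0)
})

test_that("phase range is (-pi, pi] and flat-at-vmean pixels are degenerate with phase 0", {
  set.seed(2)
  fr <- array(rnorm(3 * 3 * 40, -60, 25), c(3, 3, 40))
  fr[1, 1, ] <- -55  # exactly flat
  m <- make_movie(fr)
  pm <- compute_phase(m, vmean = matrix(-55, 3, 3), tau_ms = 5)
  expect_true(all(pm$frames > -pi & pm$frames <= pi))
  expect_true(all(pm$frames[1, 1, ] == 0))
  expect_true(pm$degenerate[1, 1])
  expect_false(any(pm$degenerate[-1]))
})

test_that("phase is invariant to a common shift of V and Vmean", {
  set.seed(3)
  fr <- array(rnorm(4 * 4 * 50, -60, 25), c(4, 4, 50))
  m1 <- make_movie(fr)
  m2 <- make_movie(fr + 17.3)
  vm <- compute_vmean(m1)
  p1 <- compute_phase(m1, vm, tau_ms = 10)
  p2 <- compute_phase(m2, vm + 17.3, tau_ms = 10)
  expect_equal(p1$frames, p2$frames)
})

test_that("tau must align with the sampling grid and fit in the movie", {
  fr <- array(rnorm(3 * 3 * 40), c(3, 3, 40))
  m <- make_movie(fr, dt = 2)
  expect_error(compute_phase(m, tau_ms = 5), "integer multiple")
  expect_error(compute_phase(m, tau_ms = 100), "shorter")
  pm <- compute_phase(m, tau_ms = 10)  # 5 frames
  expect_equal(dim(pm$frames)[3], 35)
})

test_that("argument order switch flips the rotation sense", {
  omega <- pi / 30
  tt <- 0:120
  fr <- array(rep(cos(omega * tt), each = 4), c(2, 2, 121))
  m <- make_movie(fr)
  vm <- matrix(0, 2, 2)
  pa <- compute_phase(m, vm, tau_ms = 15, delayed_first = TRUE)
  pb <- compute_phase(m, vm, tau_ms = 15, delayed_first = FALSE)
  # one runs clockwise, the other counter-clockwise
  da <- wrapped_diff(pa$frames[1, 1, 3:20], pa$frames[1, 1, 2:19])
  db <- wrapped_diff(pb$frames[1, 1, 3:20], pb$frames[1, 1, 2:19])
  expect_true(all(da < 0))
  expect_true(all(db > 0))
})

test_that("phase trace matches an element-wise oracle recomputation on a rotor movie", {
  m <- fixture_surrogate()
  vm <- compute_vmean(m)
  pm <- compute_phase(m, vm, tau_ms = 30)
  r <- 60; c <- 40
  v <- m$frames[r, c, ]
  want <- atan2(v[31:length(v)] - vm[r, c],
                v[1:(length(v) - 30)] - vm[r, c])
  want[want == -pi] <- pi
  expect_equal(pm$frames[r, c, ], want)
})
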