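# Shared fixtures, generated in code and cached for the test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# surrogate rotor movie: the standard non-analytic spiral input
fixture_surrogate <- function() {
  cached("surrogate", {
    surrogate_spiral(sim_grid(120, 120), duration_ms = 700)
  })
}

# the same rotor restricted to the settled window after the initiation
# transient (the wave-break protocol briefly litters the phase field)
fixture_surrogate_late <- function() {
  cached("surrogate_late", subset_movie(fixture_surrogate(), 250, 700))
}

# analytic spiral with a static core on a grid pixel
fixture_analytic_static <- function() {
  cached("analytic_static", {
    g <- sim_grid(81, 81)
    spec <- analytic_spiral_spec(core_path = c(10, 10),
                                 omega_rad_per_ms = pi / 30,
                                 k_rad_per_mm = 0.5)
    analytic_spiral_movie(spec, g, duration_ms = 240)
  })
}

# analytic spiral with a circularly orbiting core
fixture_analytic_orbit <- function() {
  cached("analytic_orbit", {
    g <- sim_grid(81, 81)
    spec <- analytic_spiral_spec(
      core_path = function(t) c(10 + 3 * cos(2 * pi * t / 240),
                                10 + 3 * sin(2 * pi * t / 240)),
      omega_rad_per_ms = pi / 30, k_rad_per_mm = 0.5)
    analytic_spiral_movie(spec, g, duration_ms = 240)
  })
}

# smooth random phase frame: band-limited random field mapped to (-pi, pi]
# via a small-amplitude wrap so winding numbers stay well defined
random_smooth_phase <- function(n = 24, amp = 2.5) {
  base <- matrix(rnorm(9), 3, 3)
  big <- matrix(NA_real_, n, n)
  xs <- seq(1, 3, length.out = n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      x <- xs[i]; y <- xs[j]
      i0 <- floor(x); j0 <- floor(y)
      i1 <- min(i0 + 1, 3); j1 <- min(j0 + 1, 3)
      fx <- x - i0; fy <- y - j0
      big[i, j] <- (1 - fx) * (1 - fy) * base[i0, j0] +
        fx * (1 - fy) * base[i1, j0] +
        (1 - fx) * fy * base[i0, j1] + fx * fy * base[i1, j1]
    }
  }
  ph <- amp * big
  ph <- ph - 2 * pi * floor((ph + pi) / (2 * pi))
  ph[ph == -pi] <- pi
  ph
}

# random point sets in mm for Hausdorff property tests
random_point_set <- function(n, extent_mm = 20) {
  cbind(x = runif(n, 0, extent_mm), y = runif(n, 0, extent_mm))
}

# brute-force directed Hausdorff oracle: literal double loop
hausdorff_oracle <- function(A, B) {
  h_dir <- function(P, Q) {
    worst <- 0
    for (i in seq_len(nrow(P))) {
      best <- Inf
      for (j in seq_len(nrow(Q))) {
        d <- sqrt((P[i, 1] - Q[j, 1])^2 + (P[i, 2] - Q[j, 2])^2)
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(h_dir(A, B), h_dir(B, A))
}

# winding oracle: accumulate unwrapped differences along the same
# 8-neighbor loop used by the detector
winding_oracle <- function(ph, r, c) {
  off <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
              c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
  vals <- vapply(off, function(o) ph[r + o[1], c + o[2]], numeric(1))
  vals <- c(vals, vals[1])
  tot <- 0
  for (k in 1:8) {
    d <- vals[k + 1] - vals[k]
    while (d > pi) d <- d - 2 * pi
    while (d <= -pi) d <- d + 2 * pi
    tot <- tot + d
  }
  as.integer(round(tot / (2 * pi)))
}
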