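test_that("single-triplet motion variance matches the closed-form ML solution", {
  tr <- toy_fixes(c(0, 120, 100), c(0, -50, 200))
  a <- 0.5; Tt <- 2
  mx <- a * 100; my <- a * 200
  r2 <- ((120 - mx)^2 + (-50 - my)^2) / 2      # per-coordinate mean squared residual
  closed <- r2 / (a * (1 - a) * Tt)
  est <- fit_motion_variance(tr, delta = 0)
  expect_equal(est, closed, tolerance = 1e-6)

  # uneven spacing: alpha != 1/2
  tr2 <- toy_fixes(c(0, 200, 300), c(0, 80, 0))
  tr2$timestamp <- tr2$timestamp[1] + c(0, 3600, 3 * 3600)
  a2 <- 1 / 3; T2 <- 3
  mx2 <- a2 * 300; my2 <- 0
  r22 <- ((200 - mx2)^2 + (80 - my2)^2) / 2
  expect_equal(fit_motion_variance(tr2, delta = 0), r22 / (a2 * (1 - a2) * T2),
               tolerance = 1e-6)
})

test_that("an exactly interpolated midpoint drives the estimate to the lower bound", {
  tr <- toy_fixes(c(0, 500, 1000), c(0, 250, 500))
  est <- fit_motion_variance(tr, delta = 10, bounds = c(1e-6, 1e7))
  expect_lt(est, 1e-4)
})

test_that("motion variance is recovered from simulated Brownian paths", {
  # 10^4 m^2/h matches the hourly displacement scale of the synthetic deer
  for (delta in c(0, 10)) {
    est <- vapply(1:5, function(s) {
      fit_motion_variance(sim_brownian_track(500, 1e4, delta, seed = s), delta = delta)
    }, numeric(1))
    expect_lt(mean(abs(est - 1e4) / 1e4), 0.15)
  }
})

test_that("fit_motion_variance rejects degenerate inputs", {
  expect_error(fit_motion_variance(toy_fixes(c(0, 1), c(0, 1))),
               class = "tendr_validation_error")
  tr <- toy_fixes(c(0, 1, 2), c(0, 1, 2))
  expect_error(fit_motion_variance(tr, max_lag = 1), class = "tendr_validation_error")
})

test_that("a single-bridge UD is symmetric and mass-normalized", {
  tr <- toy_fixes(c(0, 990), c(0, 0))
  ud <- compute_ud(tr, sigma2_m = 2500, delta = 10, buffer = 300)
  expect_equal(sum(ud$mass), 1, tolerance = 1e-6)
  # reflection x -> 990 - x maps cell centers onto cell centers here
  for (j in seq_len(ud$ny)) {
    expect_equal(ud$mass[, j], rev(ud$mass[, j]), tolerance = 1e-9)
  }
})

test_that("the bridge integrand matches the analytic midpoint law", {
  tr <- toy_fixes(c(0, 990), c(0, 0))
  tr$timestamp <- tr$timestamp[1] + c(0, 4 * 3600)   # T = 4 h
  s2 <- 3000; delta <- 10
  ud <- compute_ud(tr, s2, delta = delta, buffer = 400, n_integration = 1)
  v <- 0.25 * 4 * s2 + 0.5 * delta^2
  xc <- ud$origin[["x"]] + (seq_len(ud$nx) - 0.5) * ud$cell_size
  yc <- ud$origin[["y"]] + (seq_len(ud$ny) - 0.5) * ud$cell_size
  analytic <- dnorm(xc, 495, sqrt(v)) %o% dnorm(yc, 0, sqrt(v))
  analytic <- analytic / sum(analytic)
  expect_equal(ud$mass, analytic, tolerance = 1e-9)
})

test_that("UD is invariant to reversing the track", {
  tr <- sim_brownian_track(40, 5000, 10, seed = 9)
  rev_tr <- tr[nrow(tr):1, ]
  rev_tr$timestamp <- tr$timestamp   # same clock, path walked backwards
  ud1 <- compute_ud(tr, 5000, delta = 10, buffer = 300)
  ud2 <- compute_ud(rev_tr, 5000, delta = 10, buffer = 300)
  expect_equal(ud1$mass, ud2$mass, tolerance = 1e-12)
})

test_that("ud_volume computes inclusive cumulative volumes", {
  ud <- structure(list(origin = c(x = 0, y = 0), cell_size = 30,
                       nx = 3, ny = 1, mass = matrix(c(0.5, 0.3, 0.2), 3, 1)),
                  class = "tendr_ud")
  vol <- ud_volume(ud)
  expect_equal(as.vector(vol$volume), c(50, 80, 100))

  single <- structure(list(origin = c(x = 0, y = 0), cell_size = 30,
                           nx = 2, ny = 2, mass = matrix(c(1, 0, 0, 0), 2, 2)),
                      class = "tendr_ud")
  expect_equal(ud_volume(single)$volume[1, 1], 100)

  # ties share the inclusive value
  tied <- structure(list(origin = c(x = 0, y = 0), cell_size = 30,
                         nx = 4, ny = 1, mass = matrix(c(0.4, 0.2, 0.2, 0.2), 4, 1)),
                    class = "tendr_ud")
  expect_equal(as.vector(ud_volume(tied)$volume), c(40, 100, 100, 100))
})

test_that("ud_volume agrees exactly with the direct-definition oracle", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      m <- matrix(rgamma(400, shape = 0.5), 20, 20)
      m <- m / sum(m)
      ud <- structure(list(origin = c(x = 0, y = 0), cell_size = 30,
                           nx = 20, ny = 20, mass = m), class = "tendr_ud")
      expect_equal(ud_volume(ud)$volume, oracle_volume(m))
    }
  })
})

test_that("volume lookups use half-open cells and find the mode", {
  ud <- structure(list(origin = c(x = 0, y = 0), cell_size = 30,
                       nx = 2, ny = 1, mass = matrix(c(0.7, 0.3), 2, 1)),
                  class = "tendr_ud")
  vol <- ud_volume(ud)
  expect_equal(volume_at(vol, 15, 15), 70)    # cell center
  expect_equal(volume_at(vol, 30, 15), 100)   # shared edge belongs to the right cell
  expect_warning(out <- volume_at(vol, -5, 15), "outside")
  expect_true(is.na(out))

  # mode of a discretized Gaussian has the minimum volume on the grid
  tr <- toy_fixes(c(0, 300), c(0, 0))
  g <- ud_volume(compute_ud(tr, 2000, delta = 10, buffer = 300))
  mode_idx <- which(g$mass == max(g$mass), arr.ind = TRUE)[1, ]
  mode_xy <- g$origin + (mode_idx - 0.5) * g$cell_size
  expect_equal(volume_at(g, mode_xy[1], mode_xy[2]), min(g$volume))
})

test_that("volume values are monotone nonincreasing in density", {
  tr <- sim_brownian_track(60, 8000, 10, seed = 2)
  ud <- compute_ud(tr, 8000, delta = 10)
  vol <- ud_volume(ud)
  expect_true(all(vol$volume > 0 & vol$volume <= 100))
  ord <- order(as.vector(ud$mass), decreasing = TRUE)
  expect_false(is.unsorted(as.vector(vol$volume)[ord]))
  # the minimal whole-cell p% contour encloses at least p/100 of the mass
  for (p in c(30, 50, 95)) {
    vstar <- min(vol$volume[vol$volume >= p])
    expect_gte(sum(ud$mass[vol$volume <= vstar]), p / 100 - 1e-9)
  }
})

test_that("grid export formats are readable", {
  tr <- toy_fixes(c(0, 300), c(0, 100))
  ud <- compute_ud(tr, 2000, delta = 10, buffer = 300)
  tb <- ud_to_tibble(ud_volume(ud))
  expect_equal(nrow(tb), ud$nx * ud$ny)
  expect_equal(sum(tb$mass), 1, tolerance = 1e-9)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(ud, path)
  hdr <- readLines(path, n = 6)
  expect_match(hdr[1], "^ncols")
  expect_equal(length(readLines(path)), 6 + ud$ny)
})
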