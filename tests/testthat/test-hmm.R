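true_par_2 <- list(
  mu = c(50, 300), sigma = c(25, 150), zero_mass = c(0.05, 0.01),
  angle_mean = c(0, 0), kappa = c(0.5, 2),
  gamma = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
)

test_that("step/turn construction follows the sign convention", {
  reg <- tibble::tibble(animal_id = "A", timestamp = Sys.time() + 0:3 * 3600,
                        x = c(0, 10, 20, 30), y = c(0, 0, 0, 0))
  s <- make_series(reg)
  expect_equal(s$step, rep(10, 3))
  expect_equal(s$angle, c(NA, 0, 0))

  # right-angle left turn: +pi/2
  reg2 <- tibble::tibble(animal_id = "A", timestamp = Sys.time() + 0:2 * 3600,
                         x = c(0, 10, 10), y = c(0, 0, 10))
  expect_equal(make_series(reg2)$angle[2], pi / 2)
  # right turn: -pi/2
  reg3 <- tibble::tibble(animal_id = "A", timestamp = Sys.time() + 0:2 * 3600,
                         x = c(0, 10, 10), y = c(0, 0, -10))
  expect_equal(make_series(reg3)$angle[2], -pi / 2)
  expect_error(make_series(reg2[1:2, ]), class = "tendr_validation_error")
})

test_that("angles match an independent azimuth-difference oracle", {
  withr::with_seed(8, {
    reg <- tibble::tibble(animal_id = "A", timestamp = Sys.time() + 0:9 * 3600,
                          x = cumsum(rnorm(10)), y = cumsum(rnorm(10)))
  })
  s <- make_series(reg)
  for (t in 2:9) {
    az1 <- atan2(reg$y[t] - reg$y[t - 1], reg$x[t] - reg$x[t - 1])
    az2 <- atan2(reg$y[t + 1] - reg$y[t], reg$x[t + 1] - reg$x[t])
    d <- az2 - az1
    while (d <= -pi) d <- d + 2 * pi
    while (d > pi) d <- d - 2 * pi
    expect_equal(s$angle[t], d)
  }
})

test_that("emission densities integrate to one", {
  par <- true_par_2
  for (s in 1:2) {
    gamma_part <- integrate(function(x) dgamma(x, shape = par$mu[s]^2 / par$sigma[s]^2,
                                               rate = par$mu[s] / par$sigma[s]^2),
                            0, Inf)$value
    expect_equal(par$zero_mass[s] + (1 - par$zero_mass[s]) * gamma_part, 1,
                 tolerance = 1e-6)
    vm <- integrate(function(x) dvonmises(x, par$angle_mean[s], par$kappa[s]),
                    -pi, pi)$value
    expect_equal(vm, 1, tolerance = 1e-6)
  }
})

test_that("forward likelihood equals the exhaustive-path sum at T = 6", {
  sim <- simulate_hmm_series(true_par_2, 6, seed = 2)
  expect_equal(forward_loglik(sim, true_par_2),
               oracle_forward(sim$step, sim$angle, true_par_2),
               tolerance = 1e-10)
  # with a zero step present
  sim2 <- simulate_hmm_series(
    modifyList(true_par_2, list(zero_mass = c(0.6, 0.3))), 6, seed = 5)
  expect_true(any(sim2$step == 0))
  expect_equal(forward_loglik(sim2, true_par_2),
               oracle_forward(sim2$step, sim2$angle, true_par_2),
               tolerance = 1e-10)
})

test_that("forward likelihood is invariant to state relabelling", {
  sim <- simulate_hmm_series(true_par_2, 50, seed = 3)
  swapped <- list(mu = rev(true_par_2$mu), sigma = rev(true_par_2$sigma),
                  zero_mass = rev(true_par_2$zero_mass),
                  angle_mean = rev(true_par_2$angle_mean),
                  kappa = rev(true_par_2$kappa),
                  gamma = true_par_2$gamma[2:1, 2:1])
  expect_equal(forward_loglik(sim, true_par_2), forward_loglik(sim, swapped),
               tolerance = 1e-10)
})

test_that("viterbi decoding equals exhaustive-path argmax on an 8-step toy", {
  fit <- c(true_par_2, list(n_states = 2, delta = hmm_stationary_for_test(true_par_2$gamma)))
  class(fit) <- "tendr_hmm"
  withr::with_seed(17, {
    for (rep in 1:5) {
      sim <- simulate_hmm_series(true_par_2, 8, seed = sample(1e4, 1))
      expect_equal(viterbi_decode(fit, sim), oracle_viterbi(sim$step, sim$angle, true_par_2))
    }
  })
})

test_that("viterbi ties break toward the lower state index", {
  par_tied <- list(mu = c(100, 100), sigma = c(50, 50), zero_mass = c(0.02, 0.02),
                   angle_mean = c(0, 0), kappa = c(1, 1),
                   gamma = matrix(0.5, 2, 2))
  fit <- c(par_tied, list(n_states = 2, delta = c(0.5, 0.5)))
  class(fit) <- "tendr_hmm"
  sim <- simulate_hmm_series(true_par_2, 10, seed = 4)
  expect_equal(viterbi_decode(fit, sim), rep(1L, 10))
})

test_that("the stationary distribution satisfies its defining equation", {
  g <- matrix(c(0.8, 0.15, 0.3, 0.6, 0.25, 0.3, 0.05, 0.6, 0.4), 3, 3)
  g <- g / rowSums(g)
  d <- tendr:::hmm_stationary(g)
  expect_equal(as.numeric(d %*% g), d, tolerance = 1e-10)
  expect_equal(sum(d), 1, tolerance = 1e-12)
  expect_equal(d, hmm_stationary_for_test(g), tolerance = 1e-10)
})

test_that("fitting recovers parameters and beats every tried start", {
  sim <- simulate_hmm_series(true_par_2, 2000, seed = 1)
  fit <- fit_hmm(sim, 2, n_restarts = 2, seed = 1, maxit = 300)
  expect_true(all(abs(fit$mu - true_par_2$mu) / true_par_2$mu < 0.15))
  expect_true(all(abs(fit$sigma - true_par_2$sigma) / true_par_2$sigma < 0.15))
  expect_true(all(abs(diag(fit$gamma) - 0.9) < 0.05))
  expect_false(is.unsorted(fit$mu))                    # canonical ordering
  expect_equal(rowSums(fit$gamma), c(1, 1), tolerance = 1e-10)
  expect_equal(as.numeric(fit$delta %*% fit$gamma), fit$delta, tolerance = 1e-10)
  # optimization contract: best optimum at least as good as every start
  expect_true(all(-fit$loglik <= fit$restarts$start_nll + 1e-8))
  # starting from the truth cannot beat the multi-start optimum materially
  refit <- fit_hmm(sim, 2, n_restarts = 0, seed = 1, init = true_par_2, maxit = 300)
  expect_gte(fit$loglik, refit$loglik - 1e-4)
  # decoding accuracy on well-separated states
  expect_gte(mean(viterbi_decode(fit, sim) == sim$state), 0.9)
})

test_that("fitting warns on tiny samples and errors with no data", {
  small <- simulate_hmm_series(true_par_2, 30, seed = 9)
  expect_warning(fit_hmm(small, 2, n_restarts = 1, seed = 1, maxit = 50), "unstable")
  expect_error(fit_hmm(list(), 2), class = "tendr_validation_error")
})
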