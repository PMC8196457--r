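#' Build a step-length / turning-angle series from hourly locations
#'
#' Steps are Euclidean displacements between consecutive hourly locations;
#' turning angles are signed differences of successive movement azimuths
#' wrapped to \eqn{(-\pi, \pi]} (positive = left turn).  The angle is
#' missing at the first step and whenever either adjacent step has zero
#' length (no azimuth is defined for a zero displacement).
#'
#' @param reg A regular hourly track (e.g. from [interpolate_hourly()]),
#'   with columns `animal_id`, `timestamp`, `x`, `y`; at least 3 locations.
#' @return A tibble (class `tendr_steps`): `animal_id`, `timestamp` (of the
#'   step start), `step` (m), `angle` (radians, `NA` where undefined).
#' @export
make_series <- function(reg) {
  n <- nrow(reg)
  if (n < 3) abort("need at least 3 hourly locations", class = "tendr_validation_error")
  dx <- diff(reg$x)
  dy <- diff(reg$y)
  step <- sqrt(dx^2 + dy^2)
  az <- atan2(dy, dx)
  angle <- c(NA_real_, wrap_angle(diff(az)))
  prev_zero <- c(TRUE, step[-length(step)] == 0)
  angle[prev_zero | step == 0] <- NA_real_
  out <- tibble::tibble(
    animal_id = reg$animal_id[1],
    timestamp = reg$timestamp[-n],
    step = step,
    angle = angle
  )
  class(out) <- c("tendr_steps", class(out))
  out
}

# wrap radians to (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' von Mises density
#'
#' Density on \eqn{(-\pi, \pi]} with mean direction `mu` and concentration
#' `kappa` (`kappa = 0` is the circular uniform).
#'
#' @param x Angles, radians.
#' @param mu Mean direction, radians.
#' @param kappa Concentration, \eqn{\ge 0}.
#' @param log Return log density?
#' @return Density values.
#' @export
dvonmises <- function(x, mu = 0, kappa = 1, log = FALSE) {
  stopifnot(all(kappa >= 0))
  ld <- kappa * cos(x - mu) - log(2 * pi) - log(besselI(kappa, 0, expon.scaled = TRUE)) - kappa
  if (log) ld else exp(ld)
}

# ---- working-scale parameter transforms -------------------------------------

hmm_n_par <- function(N) 4L * N + N * (N - 1L)

# pack natural parameters into an unconstrained working vector
hmm_pack <- function(par) {
  N <- length(par$mu)
  c(
    log(par$mu), log(par$sigma),
    stats::qlogis(pmin(pmax(par$zero_mass, 1e-8), 1 - 1e-8)),
    par$kappa * cos(par$angle_mean), par$kappa * sin(par$angle_mean),
    as.vector(t(log(par$gamma / diag(par$gamma))))[
      as.vector(t(diag(N) == 0))
    ]
  )
}

# unpack a working vector into natural parameters; angle mean recovered with
# atan2 and concentration as the length of the (cos, sin) working pair
hmm_unpack <- function(w, N) {
  mu <- exp(w[1:N])
  sigma <- exp(w[N + 1:N])
  zero_mass <- stats::plogis(w[2 * N + 1:N])
  a <- w[3 * N + 1:N]
  b <- w[4 * N + 1:N]
  angle_mean <- atan2(b, a)
  kappa <- sqrt(a^2 + b^2)
  gamma <- diag(N)
  if (N > 1) {
    eta <- w[4 * N + N + seq_len(N * (N - 1))]
    g <- matrix(0, N, N)
    g[t(diag(N) == 0)] <- eta        # fill off-diagonals row-wise
    g <- t(g)
    gamma <- exp(g)
    gamma <- gamma / rowSums(gamma)
  }
  list(
    mu = mu, sigma = sigma, zero_mass = zero_mass,
    angle_mean = angle_mean, kappa = kappa, gamma = gamma
  )
}

# stationary distribution of a transition matrix
hmm_stationary <- function(gamma) {
  N <- nrow(gamma)
  delta <- try(solve(t(diag(N) - gamma + 1), rep(1, N)), silent = TRUE)
  if (inherits(delta, "try-error") || any(!is.finite(delta)) || any(delta < 0)) {
    delta <- rep(1 / N, N)
  }
  delta / sum(delta)
}

# T x N matrix of per-observation emission densities
hmm_emissions <- function(step, angle, par) {
  N <- length(par$mu)
  Tn <- length(step)
  P <- matrix(1, Tn, N)
  shape <- par$mu^2 / par$sigma^2
  rate <- par$mu / par$sigma^2
  zero <- !is.na(step) & step == 0
  pos <- !is.na(step) & step > 0
  has_angle <- !is.na(angle)
  for (s in seq_len(N)) {
    col <- rep(1, Tn)
    col[zero] <- par$zero_mass[s]
    dg <- suppressWarnings(dgamma(step[pos], shape = shape[s], rate = rate[s]))
    dg[!is.finite(dg)] <- 0
    col[pos] <- (1 - par$zero_mass[s]) * dg
    if (any(has_angle)) {
      col[has_angle] <- col[has_angle] *
        dvonmises(angle[has_angle], par$angle_mean[s], par$kappa[s])
    }
    P[, s] <- col
  }
  P
}

#' Forward log-likelihood of a gamma/von Mises HMM
#'
#' Scaled forward recursion (log-space accumulation) for one step/turn
#' series under state-dependent zero-inflated gamma step lengths and von
#' Mises turning angles, with the stationary distribution of the transition
#' matrix as the initial state distribution.  Missing angles contribute no
#' angle factor.
#'
#' @param series A `tendr_steps` tibble (columns `step`, `angle`).
#' @param par Natural parameter list: `mu`, `sigma`, `zero_mass`,
#'   `angle_mean`, `kappa` (length-N vectors) and `gamma` (N x N).
#' @return Scalar log-likelihood.
#' @export
forward_loglik <- function(series, par) {
  P <- hmm_emissions(series$step, series$angle, par)
  delta <- hmm_stationary(par$gamma)
  Tn <- nrow(P)
  phi <- delta * P[1, ]
  s <- sum(phi)
  if (s <= 0 || !is.finite(s)) return(-Inf)
  ll <- log(s)
  phi <- phi / s
  if (Tn > 1) {
    for (t in 2:Tn) {
      phi <- (phi %*% par$gamma)[1, ] * P[t, ]
      s <- sum(phi)
      if (s <= 0 || !is.finite(s)) return(-Inf)
      ll <- ll + log(s)
      phi <- phi / s
    }
  }
  ll
}

# joint negative log-likelihood over a list of series, working scale
hmm_nll <- function(w, series_list, N) {
  par <- hmm_unpack(w, N)
  if (any(!is.finite(unlist(par[c("mu", "sigma", "kappa")])))) return(1e10)
  ll <- sum(vapply(series_list, forward_loglik, numeric(1), par = par))
  if (!is.finite(ll)) return(1e10)
  -ll
}

# data-driven starting values: state means at spread quantiles of positive steps
hmm_start <- function(series_list, N, jitter = 0) {
  steps <- unlist(lapply(series_list, function(s) s$step))
  steps <- steps[!is.na(steps)]
  pos <- steps[steps > 0]
  qs <- quantile(pos, probs = (seq_len(N) * 2 - 1) / (2 * N), names = FALSE)
  mu <- qs * exp(rnorm(N, 0, jitter))
  sigma <- pmax(qs * 0.75, 1e-3) * exp(rnorm(N, 0, jitter))
  zero_mass <- rep(pmin(pmax(mean(steps == 0), 1e-4), 0.5), N) *
    exp(rnorm(N, 0, jitter / 2))
  angle_mean <- if (jitter > 0) runif(N, -pi / 4, pi / 4) else rep(0, N)
  kappa <- pmax(rep(1, N) * exp(rnorm(N, 0, jitter)), 1e-3)
  gamma <- matrix(0.1 / max(N - 1, 1), N, N)
  diag(gamma) <- 0.9
  list(
    mu = mu, sigma = sigma, zero_mass = pmin(zero_mass, 0.9),
    angle_mean = angle_mean, kappa = kappa, gamma = gamma
  )
}

#' Fit a hidden Markov model to step/turn series
#'
#' Maximizes the joint forward log-likelihood (sum over individuals; all
#' state-dependent and transition parameters shared across individuals,
#' each series entering with the stationary initial distribution) by direct
#' numerical optimization on an unconstrained working scale, with seeded
#' multi-start from perturbed data-driven initial values.  States are
#' relabelled in ascending order of step-length mean so reports are free of
#' label switching.
#'
#' @param series One `tendr_steps` tibble or a list of them (one per
#'   individual).
#' @param n_states Number of states (2 or 3 in typical use).
#' @param n_restarts Number of optimization starts (default 25).
#' @param seed Integer seed for the start perturbations.
#' @param init Optional natural parameter list used as the first start.
#' @param maxit Iteration cap per start passed to [stats::optim()].
#' @return A `tendr_hmm` object: the natural parameters (canonically
#'   ordered), `loglik`, `n_states`, `delta` (stationary initial
#'   distribution), `n_obs`, and a `restarts` tibble of per-start results.
#' @export
fit_hmm <- function(series, n_states, n_restarts = 25, seed = 1,
                    init = NULL, maxit = 500) {
  if (inherits(series, "data.frame")) series <- list(series)
  series <- purrr::keep(series, ~ nrow(.x) > 0)
  if (length(series) == 0) abort("no non-empty series", class = "tendr_validation_error")
  n_obs <- sum(vapply(series, nrow, integer(1)))
  if (n_obs < 50 * n_states) {
    warn(sprintf(
      "only %d pooled steps for %d states; fit may be unstable", n_obs, n_states
    ))
  }
  starts <- withr::with_seed(seed, {
    lapply(seq_len(n_restarts), function(r) {
      hmm_start(series, n_states, jitter = if (r == 1) 0 else 0.4)
    })
  })
  if (!is.null(init)) starts <- c(list(init), starts)

  runs <- lapply(seq_along(starts), function(r) {
    w0 <- hmm_pack(starts[[r]])
    fit <- try(
      optim(w0, hmm_nll,
        series_list = series, N = n_states,
        method = "BFGS", control = list(maxit = maxit, reltol = 1e-10)
      ),
      silent = TRUE
    )
    if (inherits(fit, "try-error")) {
      return(list(ok = FALSE, value = Inf, start_value = hmm_nll(w0, series, n_states)))
    }
    list(
      ok = TRUE, value = fit$value, par = fit$par,
      convergence = fit$convergence,
      start_value = hmm_nll(w0, series, n_states)
    )
  })
  values <- vapply(runs, function(r) r$value, numeric(1))
  if (all(!is.finite(values))) {
    abort(
      paste0("all ", length(runs), " starts failed to produce a finite likelihood"),
      class = "tendr_fit_error"
    )
  }
  best <- runs[[which.min(values)]]
  par <- hmm_unpack(best$par, n_states)

  # canonical labelling: ascending step-length mean
  ord <- order(par$mu)
  par <- list(
    mu = par$mu[ord], sigma = par$sigma[ord], zero_mass = par$zero_mass[ord],
    angle_mean = par$angle_mean[ord], kappa = par$kappa[ord],
    gamma = par$gamma[ord, ord, drop = FALSE]
  )
  out <- list(
    n_states = n_states,
    mu = par$mu, sigma = par$sigma, zero_mass = par$zero_mass,
    angle_mean = par$angle_mean, kappa = par$kappa, gamma = par$gamma,
    delta = hmm_stationary(par$gamma),
    loglik = -best$value,
    convergence = best$convergence,
    n_obs = n_obs,
    n_series = length(series),
    restarts = tibble::tibble(
      start = seq_along(runs),
      start_nll = vapply(runs, function(r) r$start_value, numeric(1)),
      final_nll = values,
      converged = vapply(runs, function(r) isTRUE(r$ok) && r$convergence == 0, logical(1))
    )
  )
  class(out) <- "tendr_hmm"
  out
}

#' Viterbi decoding of the most likely state sequence
#'
#' Exact joint-MAP path under a fitted HMM, computed in log space.  Ties are
#' broken toward the lower state index.  Missing angles drop the angle
#' emission factor at those steps.
#'
#' @param fit A `tendr_hmm` from [fit_hmm()].
#' @param series A `tendr_steps` tibble.
#' @return Integer vector of decoded states (length `nrow(series)`).
#' @export
viterbi_decode <- function(fit, series) {
  par <- fit[c("mu", "sigma", "zero_mass", "angle_mean", "kappa", "gamma")]
  P <- log(hmm_emissions(series$step, series$angle, par))
  lG <- log(par$gamma)
  Tn <- nrow(P)
  N <- fit$n_states
  v <- log(fit$delta) + P[1, ]
  back <- matrix(1L, Tn, N)
  if (Tn > 1) {
    for (t in 2:Tn) {
      cand <- v + lG                      # cand[i, j]: from i to j
      back[t, ] <- apply(cand, 2, which.max)
      v <- cand[cbind(back[t, ], seq_len(N))] + P[t, ]
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(v)
  if (Tn > 1) {
    for (t in (Tn - 1):1) path[t] <- back[t + 1, path[t + 1]]
  }
  path
}

#' @export
print.tendr_hmm <- function(x, ...) {
  cat(sprintf(
    "<tendr_hmm> %d states, %d obs in %d series, logLik %.2f\n",
    x$n_states, x$n_obs, x$n_series, x$loglik
  ))
  print(tidy(x))
  invisible(x)
}

#' Tidy a fitted HMM's state parameters
#'
#' @param x A `tendr_hmm`.
#' @param ... Unused.
#' @return One row per state: step gamma mean/SD, zero-step mass, angle
#'   mean/concentration, self-transition probability, stationary weight.
#' @exportS3Method generics::tidy
tidy.tendr_hmm <- function(x, ...) {
  tibble::tibble(
    state = seq_len(x$n_states),
    step_mean = x$mu,
    step_sd = x$sigma,
    zero_mass = x$zero_mass,
    angle_mean = x$angle_mean,
    angle_concentration = x$kappa,
    self_transition = diag(x$gamma),
    stationary = x$delta
  )
}

#' One-line fit summary of an HMM
#'
#' @param x A `tendr_hmm`.
#' @param ... Unused.
#' @return Tibble with log-likelihood, parameter count, AIC, sample size.
#' @exportS3Method generics::glance
glance.tendr_hmm <- function(x, ...) {
  k <- hmm_n_par(x$n_states)
  tibble::tibble(
    n_states = x$n_states,
    logLik = x$loglik,
    df = k,
    AIC = 2 * k - 2 * x$loglik,
    nobs = x$n_obs,
    n_series = x$n_series
  )
}

#' Export an HMM fit report as JSON
#'
#' @param fit A `tendr_hmm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hmm_report <- function(fit, path) {
  jsonlite::write_json(
    list(
      n_states = fit$n_states,
      parameters = as.list(tidy(fit)),
      gamma = fit$gamma,
      loglik = fit$loglik,
      n_obs = fit$n_obs,
      restarts = as.list(fit$restarts)
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
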