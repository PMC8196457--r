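#' Define a paired-trajectory simulation scenario
#'
#' Describes one male-female dyad over a breeding season: home-range
#' anchored movement for each animal, GPS error, and a schedule of
#' ground-truth interaction events during which the male tends the female.
#' Defaults emulate hourly deer telemetry: a 9-week season, 10 m GPS error
#' SD, home ranges of roughly 1-3 km\eqn{^2} (OU attraction 0.05/h,
#' diffusion SD 100 m/h), and event durations log-normal with median 7 h
#' truncated to 1-79 h.
#'
#' Event modes:
#' \describe{
#'   \item{`cohesive-distinct`}{male tethered to the female (AR(1) offset,
#'     stationary SD 25 m, coefficient 0.95 so the tether drifts slowly and
#'     the pair's displacements stay aligned) while the pair's step-length scale drops
#'     (`event_step_frac`): proximity *and* changed movement statistics.}
#'   \item{`cohesive-null`}{male tethered the same way but the female keeps
#'     her usual movement, so the male's marginal step/turn distributions
#'     match non-event hours: proximity *without* a movement signature.}
#'   \item{`stationary-female`}{female holds position; the male orbits
#'     within 50 m of her.}
#' }
#'
#' @param season_days Season length in days (default 63).
#' @param start Season start timestamp (UTC).
#' @param study_area Study-area code stamped on both tracks.
#' @param female_center,male_center Home-range centers, meters.
#' @param beta_f,beta_m Attraction strength toward the center per hour.
#' @param sigma_f,sigma_m Per-hour diffusion SD, meters.
#' @param delta GPS measurement-error SD, meters (default 10).
#' @param mode Event mode (see above).
#' @param n_events Number of scheduled events (default 10); ignored when
#'   `events` is supplied.
#' @param events Optional tibble `start_hour`, `duration_h` overriding the
#'   seeded schedule.
#' @param event_step_frac Step-scale multiplier during `cohesive-distinct`
#'   events (default 0.5).
#' @param tether_sd,tether_phi Stationary SD (m) and AR(1) coefficient of
#'   the male-female offset during cohesive events.
#' @param duration_meanlog,duration_sdlog Log-normal event-duration
#'   parameters (defaults give median 7 h).
#' @param duration_range Truncation bounds for durations, hours.
#' @param seed Scenario seed; all randomness flows from it.
#' @return A `tendr_scenario` list.
#' @export
scenario <- function(season_days = 63,
                     start = as.POSIXct("2015-10-18 00:00:00", tz = "UTC"),
                     study_area = "SN",
                     female_center = c(0, 0), male_center = c(400, 0),
                     beta_f = 0.05, beta_m = 0.05,
                     sigma_f = 100, sigma_m = 100,
                     delta = 10,
                     mode = c("cohesive-distinct", "cohesive-null", "stationary-female"),
                     n_events = 10, events = NULL,
                     event_step_frac = 0.5,
                     tether_sd = 25, tether_phi = 0.95,
                     duration_meanlog = log(7), duration_sdlog = 0.9,
                     duration_range = c(1, 79),
                     seed = 1) {
  mode <- match.arg(mode)
  stopifnot(
    season_days > 0, sigma_f >= 0, sigma_m >= 0, delta >= 0,
    tether_sd >= 0, tether_phi >= 0, tether_phi < 1,
    event_step_frac > 0, event_step_frac <= 1
  )
  if (!is.null(events)) {
    events <- dplyr::arrange(tibble::as_tibble(events), .data$start_hour)
    if (nrow(events) > 1) {
      ends <- events$start_hour + events$duration_h
      if (any(events$start_hour[-1] <= ends[-nrow(events)])) {
        abort("scheduled events overlap", class = "tendr_validation_error")
      }
    }
  }
  out <- list(
    season_days = season_days, start = as_utc(start), study_area = study_area,
    female_center = female_center, male_center = male_center,
    beta_f = beta_f, beta_m = beta_m, sigma_f = sigma_f, sigma_m = sigma_m,
    delta = delta, mode = mode, n_events = n_events, events = events,
    event_step_frac = event_step_frac,
    tether_sd = tether_sd, tether_phi = tether_phi,
    duration_meanlog = duration_meanlog, duration_sdlog = duration_sdlog,
    duration_range = duration_range, seed = seed
  )
  class(out) <- "tendr_scenario"
  out
}

# deterministic sub-seed for a named stage, all derived from the scenario seed
sub_seed <- function(seed, stage) {
  offsets <- c(schedule = 1L, female = 2L, male = 3L, error = 4L)
  (as.integer(seed) * 7919L + offsets[[stage]]) %% .Machine$integer.max
}

# seeded event schedule: one event per equal block of the season, log-normal
# durations truncated by resampling, >= 6 h clearance inside each block
schedule_events <- function(sc, n_hours) {
  if (!is.null(sc$events)) return(sc$events)
  if (sc$n_events == 0) {
    return(tibble::tibble(start_hour = numeric(), duration_h = numeric()))
  }
  withr::with_seed(sub_seed(sc$seed, "schedule"), {
    block <- n_hours / sc$n_events
    durs <- vapply(seq_len(sc$n_events), function(i) {
      for (draw in 1:100) {
        d <- rlnorm(1, sc$duration_meanlog, sc$duration_sdlog)
        if (d >= sc$duration_range[1] && d <= sc$duration_range[2]) return(d)
      }
      median(sc$duration_range)
    }, numeric(1))
    durs <- pmin(durs, block - 13)   # an event must fit its block with clearance
    starts <- (seq_len(sc$n_events) - 1) * block + 6 +
      runif(sc$n_events) * pmax(block - durs - 12, 0)
    tibble::tibble(start_hour = floor(starts), duration_h = floor(durs))
  })
}

#' Simulate a male-female pair with known interaction events
#'
#' Hourly true positions follow discrete-time Ornstein-Uhlenbeck home-range
#' dynamics, \eqn{x_{t+1} = x_t + \beta (c - x_t) + N(0, \sigma^2 I)};
#' during scheduled events the male is tethered to the female according to
#' the scenario's mode, and observed fixes add isotropic
#' \eqn{N(0, \delta^2)} GPS error.  The same seed always reproduces the
#' same output bit for bit.
#'
#' @param sc A [scenario()].
#' @param male_id,female_id Animal ids for the output tracks.
#' @return List with `tracks` (canonical fix tibble for both animals) and
#'   `truth` (tibble `male_id`, `female_id`, `start`, `end`, `mode` of
#'   ground-truth events).
#' @export
simulate_pair <- function(sc, male_id = "M1", female_id = "F1") {
  stopifnot(inherits(sc, "tendr_scenario"))
  n_hours <- sc$season_days * 24L
  sched <- schedule_events(sc, n_hours)
  in_event <- rep(FALSE, n_hours)
  for (i in seq_len(nrow(sched))) {
    hrs <- seq(sched$start_hour[i], min(sched$start_hour[i] + sched$duration_h[i], n_hours - 1))
    in_event[hrs + 1] <- TRUE
  }

  # female true path
  fx <- matrix(0, n_hours, 2)
  withr::with_seed(sub_seed(sc$seed, "female"), {
    fx[1, ] <- sc$female_center + rnorm(2, 0, sc$sigma_f)
    eps <- matrix(rnorm(2 * (n_hours - 1)), n_hours - 1, 2)
    for (t in 2:n_hours) {
      s <- sc$sigma_f
      if (in_event[t]) {
        if (sc$mode == "stationary-female") s <- 0
        if (sc$mode == "cohesive-distinct") s <- sc$sigma_f * sc$event_step_frac
      }
      fx[t, ] <- fx[t - 1, ] + sc$beta_f * (sc$female_center - fx[t - 1, ]) +
        s * eps[t - 1, ]
    }
  })

  # male true path: OU outside events, tethered to the female inside
  mx <- matrix(0, n_hours, 2)
  withr::with_seed(sub_seed(sc$seed, "male"), {
    tether_sd <- if (sc$mode == "stationary-female") 20 else sc$tether_sd
    innov_sd <- tether_sd * sqrt(1 - sc$tether_phi^2)
    offset <- rnorm(2, 0, tether_sd)
    mx[1, ] <- sc$male_center + rnorm(2, 0, sc$sigma_m)
    for (t in 2:n_hours) {
      if (in_event[t]) {
        if (!in_event[t - 1]) offset <- rnorm(2, 0, tether_sd)  # tether engages
        offset <- sc$tether_phi * offset + rnorm(2, 0, innov_sd)
        if (sc$mode == "stationary-female") {
          r <- sqrt(sum(offset^2))
          if (r > 50) offset <- offset * 50 / r   # orbit stays within 50 m
        }
        mx[t, ] <- fx[t, ] + offset
      } else {
        mx[t, ] <- mx[t - 1, ] + sc$beta_m * (sc$male_center - mx[t - 1, ]) +
          rnorm(2, 0, sc$sigma_m)
      }
    }
  })

  # observed fixes: truth + GPS error
  withr::with_seed(sub_seed(sc$seed, "error"), {
    obs_f <- fx + matrix(rnorm(2 * n_hours, 0, sc$delta), n_hours, 2)
    obs_m <- mx + matrix(rnorm(2 * n_hours, 0, sc$delta), n_hours, 2)
  })

  times <- sc$start + (seq_len(n_hours) - 1) * 3600
  tracks <- dplyr::bind_rows(
    tibble::tibble(
      animal_id = male_id, sex = "male", study_area = sc$study_area,
      timestamp = times, x = obs_m[, 1], y = obs_m[, 2]
    ),
    tibble::tibble(
      animal_id = female_id, sex = "female", study_area = sc$study_area,
      timestamp = times, x = obs_f[, 1], y = obs_f[, 2]
    )
  )
  truth <- tibble::tibble(
    male_id = male_id, female_id = female_id,
    start = sc$start + sched$start_hour * 3600,
    end = sc$start + pmin(sched$start_hour + sched$duration_h, n_hours - 1) * 3600,
    mode = sc$mode
  )
  list(tracks = validate_tracks(tracks), truth = truth)
}

#' Write a simulated dyad's ground-truth events to CSV
#'
#' @param truth The `truth` tibble from [simulate_pair()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- dplyr::mutate(truth, dplyr::across(
    dplyr::where(~ inherits(.x, "POSIXct")),
    ~ format(.x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  ))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler.
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration, \eqn{\ge 0} (0 = circular uniform).
#' @return Angles in \eqn{(-\pi, \pi]}.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (kappa < 1e-8) return(wrap_angle(runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      z <- cos(pi * runif(1))
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      u2 <- runif(1)
      if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) break
    }
    out[i] <- sign(runif(1) - 0.5) * acos(pmin(pmax(f, -1), 1)) + mu
  }
  wrap_angle(out)
}

#' Simulate a step/turn series from known HMM parameters
#'
#' Test harness for the HMM module: draws a Markov state path from the
#' transition matrix (stationary start), then per-state zero-inflated gamma
#' step lengths and von Mises turning angles.  Angles are set missing at
#' the first step and wherever the emission model defines no angle (zero
#' adjacent steps), matching [make_series()] output.
#'
#' @param par Natural parameter list as in [forward_loglik()].
#' @param n_steps Number of steps.
#' @param seed Integer seed.
#' @param animal_id Id stamped on the series.
#' @return A `tendr_steps` tibble with an extra `state` column (the true
#'   path).
#' @export
simulate_hmm_series <- function(par, n_steps, seed = 1, animal_id = "sim") {
  N <- length(par$mu)
  g <- par$gamma
  if (!is.matrix(g) || nrow(g) != N || ncol(g) != N ||
      any(g < 0) || any(abs(rowSums(g) - 1) > 1e-8)) {
    abort("invalid transition matrix", class = "tendr_validation_error")
  }
  withr::with_seed(seed, {
    delta <- hmm_stationary(g)
    states <- integer(n_steps)
    states[1] <- sample.int(N, 1, prob = delta)
    for (t in seq_len(n_steps - 1)) {
      states[t + 1] <- sample.int(N, 1, prob = g[states[t], ])
    }
    shape <- par$mu^2 / par$sigma^2
    rate <- par$mu / par$sigma^2
    step <- vapply(states, function(s) {
      if (runif(1) < par$zero_mass[s]) 0 else rgamma(1, shape[s], rate[s])
    }, numeric(1))
    angle <- vapply(states, function(s) {
      rvonmises(1, par$angle_mean[s], par$kappa[s])
    }, numeric(1))
  })
  prev_zero <- c(TRUE, step[-n_steps] == 0)
  angle[prev_zero | step == 0] <- NA_real_
  out <- tibble::tibble(
    animal_id = animal_id,
    timestamp = as.POSIXct("2015-10-18", tz = "UTC") + (seq_len(n_steps) - 1) * 3600,
    step = step, angle = angle, state = states
  )
  class(out) <- c("tendr_steps", class(out))
  out
}
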