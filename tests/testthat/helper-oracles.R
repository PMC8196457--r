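# Independent brute-force oracles and small fixture builders.
# These deliberately use different algorithms from the package internals.

toy_fixes <- function(x, y, t0 = "2015-11-01 00:00:00", dt_h = 1,
                      animal_id = "A1", sex = "female", study_area = "SN") {
  tibble::tibble(
    animal_id = animal_id, sex = sex, study_area = study_area,
    timestamp = as.POSIXct(t0, tz = "UTC") + (seq_along(x) - 1) * dt_h * 3600,
    x = x, y = y
  )
}

toy_dyad <- function(dist, t0 = "2015-11-01 00:00:00") {
  # paired-fix series with prescribed distances; A at origin line, B offset in y
  n <- length(dist)
  ts <- as.POSIXct(t0, tz = "UTC") + (seq_len(n) - 1) * 3600
  out <- tibble::tibble(
    timestamp = ts, t_a = ts, t_b = ts,
    x_a = seq_len(n) * 10, y_a = 0,
    x_b = seq_len(n) * 10, y_b = dist,
    distance = dist
  )
  attr(out, "id_a") <- "M1"
  attr(out, "id_b") <- "F1"
  class(out) <- c("tendr_dyad", class(out))
  out
}

# Event-detection oracle: graph transitive closure over close fixes plus an
# exhaustive window scan for the min-run condition.
oracle_detect <- function(times_h, dist, thr = 100, min_run = 2, gap_h = 2) {
  close_idx <- which(dist <= thr)
  if (length(close_idx) == 0) return(list())
  k <- length(close_idx)
  # adjacency: two close fixes linked if their times differ by <= gap_h
  adj <- outer(times_h[close_idx], times_h[close_idx],
               function(a, b) abs(a - b) <= gap_h)
  reach <- adj
  for (r in seq_len(k)) reach <- (reach %*% adj > 0) | reach  # transitive closure
  comp <- rep(NA_integer_, k)
  cid <- 0
  for (i in seq_len(k)) {
    if (is.na(comp[i])) {
      cid <- cid + 1
      comp[reach[i, ]] <- cid
    }
  }
  events <- list()
  for (g in seq_len(cid)) {
    members <- close_idx[comp == g]
    span <- seq(min(members), max(members))
    # exhaustive scan: longest window of consecutive fixes all close
    best <- 0
    for (s in span) for (e in span[span >= s]) {
      if (all(dist[s:e] <= thr)) best <- max(best, e - s + 1)
    }
    if (best < min_run) next
    if (mean(dist[span]) > thr) next
    events[[length(events) + 1]] <- list(
      start = min(span), end = max(span),
      n_fixes = length(span), mean_distance = mean(dist[span])
    )
  }
  events
}

# Nearest-time matching oracle: maximum-cardinality, minimum total |dt|
# matching by explicit enumeration over all injective pairings (tiny inputs).
oracle_match <- function(ta, tb, tol) {
  best <- list(n = -1, cost = Inf)
  recurse <- function(i, used_b, n, cost) {
    if (i > length(ta)) {
      if (n > best$n || (n == best$n && cost < best$cost)) {
        best <<- list(n = n, cost = cost)
      }
      return(invisible())
    }
    recurse(i + 1, used_b, n, cost)                 # leave a_i unmatched
    for (j in seq_along(tb)) {
      if (!used_b[j] && abs(tb[j] - ta[i]) <= tol) {
        used_b[j] <- TRUE
        recurse(i + 1, used_b, n + 1, cost + abs(tb[j] - ta[i]))
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, length(tb)), 0, 0)
  best
}

# UD volume oracle: direct definition, one pass per cell
oracle_volume <- function(mass) {
  v <- vapply(as.vector(mass), function(mi) 100 * sum(mass[mass >= mi]), numeric(1))
  matrix(v, nrow(mass), ncol(mass))
}

# Exhaustive-path HMM log-likelihood (sums over all N^T state paths)
oracle_forward <- function(step, angle, par) {
  N <- length(par$mu)
  Tn <- length(step)
  delta <- solve(t(diag(N) - par$gamma + 1), rep(1, N))
  delta <- delta / sum(delta)
  emis <- function(t, s) {
    p <- if (step[t] == 0) par$zero_mass[s] else {
      (1 - par$zero_mass[s]) *
        dgamma(step[t], shape = par$mu[s]^2 / par$sigma[s]^2,
               rate = par$mu[s] / par$sigma[s]^2)
    }
    if (!is.na(angle[t])) {
      p <- p * exp(par$kappa[s] * cos(angle[t] - par$angle_mean[s])) /
        (2 * pi * besselI(par$kappa[s], 0))
    }
    p
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), Tn)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    p <- delta[paths[r, 1]] * emis(1, paths[r, 1])
    for (t in seq_len(Tn - 1)) {
      p <- p * par$gamma[paths[r, t], paths[r, t + 1]] * emis(t + 1, paths[r, t + 1])
    }
    total <- total + p
  }
  log(total)
}

# Exhaustive-path Viterbi (argmax over all paths, first maximum wins)
oracle_viterbi <- function(step, angle, par) {
  N <- length(par$mu)
  Tn <- length(step)
  delta <- solve(t(diag(N) - par$gamma + 1), rep(1, N))
  delta <- delta / sum(delta)
  emis <- function(t, s) {
    p <- if (step[t] == 0) par$zero_mass[s] else {
      (1 - par$zero_mass[s]) *
        dgamma(step[t], shape = par$mu[s]^2 / par$sigma[s]^2,
               rate = par$mu[s] / par$sigma[s]^2)
    }
    if (!is.na(angle[t])) {
      p <- p * exp(par$kappa[s] * cos(angle[t] - par$angle_mean[s])) /
        (2 * pi * besselI(par$kappa[s], 0))
    }
    p
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), Tn)))
  # expand.grid varies the first column fastest; reorder rows so that paths
  # are in lexicographic order and the first maximum is the lowest-index path
  paths <- paths[do.call(order, as.data.frame(paths)), , drop = FALSE]
  best_p <- -Inf
  best <- NULL
  for (r in seq_len(nrow(paths))) {
    p <- log(delta[paths[r, 1]]) + log(emis(1, paths[r, 1]))
    for (t in seq_len(Tn - 1)) {
      p <- p + log(par$gamma[paths[r, t], paths[r, t + 1]]) +
        log(emis(t + 1, paths[r, t + 1]))
    }
    if (p > best_p) {
      best_p <- p
      best <- paths[r, ]
    }
  }
  unname(best)
}

# Brownian path with GPS error, hourly fixes
sim_brownian_track <- function(n, sigma2_m, delta, seed,
                               t0 = "2015-11-01 00:00:00") {
  withr::with_seed(seed, {
    x <- cumsum(rnorm(n, 0, sqrt(sigma2_m)))
    y <- cumsum(rnorm(n, 0, sqrt(sigma2_m)))
    tibble::tibble(
      animal_id = "B1",
      timestamp = as.POSIXct(t0, tz = "UTC") + (seq_len(n) - 1) * 3600,
      x = x + rnorm(n, 0, delta),
      y = y + rnorm(n, 0, delta)
    )
  })
}

# match ground-truth events to detected events by >= 50% interval overlap
match_truth <- function(truth, events) {
  vapply(seq_len(nrow(truth)), function(i) {
    if (nrow(events) == 0) return(NA_integer_)
    o <- pmax(0, as.numeric(pmin(events$end, truth$end[i])) -
                 as.numeric(pmax(events$start, truth$start[i])))
    len <- max(as.numeric(truth$end[i]) - as.numeric(truth$start[i]), 3600)
    j <- which.max(o)
    if (o[j] >= 0.5 * len) j else NA_integer_
  }, integer(1))
}

# stationary distribution via power iteration (independent of package internals)
hmm_stationary_for_test <- function(gamma) {
  d <- rep(1 / nrow(gamma), nrow(gamma))
  for (i in 1:10000) d <- as.numeric(d %*% gamma)
  d / sum(d)
}
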