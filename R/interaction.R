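#' Detect male-female interaction events from a dyad series
#'
#' Liberal proximity rule: paired fixes at distance `<= dist_threshold` are
#' "close"; successive close fixes whose time difference is at most
#' `gap_hours` belong to the same candidate event (so a far stretch strictly
#' longer than `gap_hours` splits events); far fixes falling inside a merged
#' span are retained as event fixes.  A candidate becomes an event when it
#' contains at least `min_run` consecutive close paired fixes and the mean
#' over all its fixes' distances is `<= dist_threshold`.  Events are
#' disjoint in time within a dyad.
#'
#' @param dyad A dyad series from [align_dyad()].
#' @param dist_threshold Close-proximity distance, meters (default 100).
#' @param min_run Minimum number of consecutive close fixes (default 2,
#'   i.e. one hour of sustained proximity at hourly fixes).
#' @param gap_hours Maximum far-gap bridged within one event, hours
#'   (default 2).
#' @return A tibble (class `tendr_events`), one row per event: `event_id`,
#'   `male_id`, `female_id`, `start`, `end`, `n_fixes`, `duration_h`,
#'   `mean_distance_m`, `classification` (`"liberal"`), and a list-column
#'   `fixes` holding each event's paired fixes.
#' @export
detect_events <- function(dyad, dist_threshold = 100, min_run = 2, gap_hours = 2) {
  stopifnot(dist_threshold > 0, min_run >= 1, gap_hours >= 0)
  empty <- tibble::tibble(
    event_id = character(), male_id = character(), female_id = character(),
    start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"),
    n_fixes = integer(), duration_h = numeric(), mean_distance_m = numeric(),
    classification = character(), fixes = list()
  )
  class(empty) <- c("tendr_events", class(empty))
  if (is.null(dyad) || nrow(dyad) == 0) return(empty)
  id_a <- attr(dyad, "id_a") %||% "A"
  id_b <- attr(dyad, "id_b") %||% "B"

  tt <- as.numeric(dyad$timestamp)
  close <- dyad$distance <= dist_threshold
  ci <- which(close)
  if (length(ci) == 0) return(empty)

  # group close fixes: new group when the time since the previous close fix
  # exceeds gap_hours
  grp <- cumsum(c(1, diff(tt[ci]) > gap_hours * 3600))
  rows <- purrr::map(unique(grp), function(g) {
    idx <- ci[grp == g]
    span <- seq(min(idx), max(idx))        # far fixes inside the span retained
    ev <- dyad[span, , drop = FALSE]
    # longest run of consecutive close fixes within the span
    cl <- close[span]
    runs <- rle(cl)
    max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    if (max_run < min_run) return(NULL)
    if (mean(ev$distance) > dist_threshold) return(NULL)
    tibble::tibble(
      male_id = id_a, female_id = id_b,
      start = ev$timestamp[1], end = ev$timestamp[nrow(ev)],
      n_fixes = nrow(ev),
      duration_h = as.numeric(difftime(ev$timestamp[nrow(ev)], ev$timestamp[1], units = "hours")),
      mean_distance_m = mean(ev$distance),
      classification = "liberal",
      fixes = list(tibble::as_tibble(ev))
    )
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) return(empty)
  out <- dplyr::arrange(out, .data$start)
  out <- dplyr::mutate(out,
    event_id = paste0(id_a, ".", id_b, ".", dplyr::row_number()),
    .before = 1
  )
  class(out) <- c("tendr_events", class(out))
  out
}

#' Dynamic interaction statistic for one event
#'
#' Per simultaneous step t (consecutive paired fixes for both animals), with
#' step lengths \eqn{d_a, d_b} and azimuths \eqn{\theta_a, \theta_b}:
#' \deqn{DI_t = \cos(\theta_a - \theta_b) \cdot
#'       \left(1 - \left(\frac{|d_a - d_b|}{d_a + d_b}\right)^{\alpha}\right)}
#' Values near 1 indicate cohesive movement displacement, near -1 opposing
#' displacement, near 0 independent movement.  Zero-step conventions: both
#' steps zero gives \eqn{DI_t = 1} (perfectly matched rest), exactly one
#' zero step gives \eqn{DI_t = 0}.  Returns the arithmetic mean over steps.
#'
#' @param event_fixes Paired fixes for one event (the `fixes` element of a
#'   [detect_events()] row): columns `x_a`, `y_a`, `x_b`, `y_b`, time-ordered.
#' @param alpha Displacement-similarity exponent (default 1).
#' @return Scalar mean DI in \eqn{[-1, 1]}, or `NA_real_` when no
#'   simultaneous step exists (such an event cannot be conservatively
#'   classified).
#' @export
dynamic_interaction <- function(event_fixes, alpha = 1) {
  n <- nrow(event_fixes)
  if (is.null(n) || n < 2) return(NA_real_)
  dxa <- diff(event_fixes$x_a); dya <- diff(event_fixes$y_a)
  dxb <- diff(event_fixes$x_b); dyb <- diff(event_fixes$y_b)
  da <- sqrt(dxa^2 + dya^2)
  db <- sqrt(dxb^2 + dyb^2)
  di <- numeric(length(da))
  both_zero <- da == 0 & db == 0
  one_zero <- xor(da == 0, db == 0)
  moving <- !both_zero & !one_zero
  di[both_zero] <- 1
  di[one_zero] <- 0
  if (any(moving)) {
    f <- cos(atan2(dya[moving], dxa[moving]) - atan2(dyb[moving], dxb[moving]))
    g <- 1 - (abs(da[moving] - db[moving]) / (da[moving] + db[moving]))^alpha
    di[moving] <- f * g
  }
  mean(di)
}

#' Attach mean DI to detected events
#'
#' @param events Events from [detect_events()].
#' @param alpha Passed to [dynamic_interaction()].
#' @return `events` with a `mean_DI` column.
#' @export
add_dynamic_interaction <- function(events, alpha = 1) {
  events$mean_DI <- purrr::map_dbl(events$fixes, dynamic_interaction, alpha = alpha)
  events
}

#' Conservative event filter
#'
#' Retains events whose mean dynamic interaction strictly exceeds
#' `di_threshold` (default 0.5, i.e. clearly cohesive movement).  Events
#' with undefined DI are dropped.  The conservative set is always a subset
#' of the liberal set.
#'
#' @param events Events carrying a `mean_DI` column (see
#'   [add_dynamic_interaction()]).
#' @param di_threshold Strict lower bound on mean DI (default 0.5).
#' @return The retained events, `classification` set to `"conservative"`.
#' @export
conservative_filter <- function(events, di_threshold = 0.5) {
  if (!"mean_DI" %in% names(events)) {
    abort("events must carry mean_DI; call add_dynamic_interaction() first",
      class = "tendr_validation_error"
    )
  }
  out <- dplyr::filter(events, !is.na(.data$mean_DI), .data$mean_DI > di_threshold)
  out$classification <- rep("conservative", nrow(out))
  out
}

#' Write an event table to CSV
#'
#' Flat export (the `fixes` list-column is dropped).
#'
#' @param events An event table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  flat <- dplyr::select(tibble::as_tibble(events), -dplyr::any_of("fixes"))
  flat <- dplyr::mutate(flat, dplyr::across(
    dplyr::where(~ inherits(.x, "POSIXct")),
    ~ format(.x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  ))
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}
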