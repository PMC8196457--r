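#' Flag the hourly locations belonging to an event
#'
#' All hourly timestamps between an event's start and end (inclusive at
#' both endpoints) are event locations.
#'
#' @param event One event row (needs `start` and `end`).
#' @param reg A regular hourly track covering the event span.
#' @return Logical vector, one flag per row of `reg`.
#' @export
label_event_hours <- function(event, reg) {
  if (event$start < min(reg$timestamp) || event$end > max(reg$timestamp)) {
    abort("event lies outside the regular track span", class = "tendr_validation_error")
  }
  reg$timestamp >= event$start & reg$timestamp <= event$end
}

#' Per-event UD-volume summaries
#'
#' For each event and evaluated animal, looks up the UD volume of the grid
#' cell containing each of that animal's event fixes and averages them
#' (averaging over fixes; a cell traversed twice counts twice), attaching
#' the event's mean male-female distance and duration as covariates.  Fixes
#' outside the grid are recorded as missing with a warning.
#'
#' @param events Event table from [detect_events()] (with `fixes`
#'   list-column).
#' @param volume_grids Named list of `tendr_ud_volume` objects keyed by
#'   animal id (e.g. one per animal for a season-scale fit, or per
#'   animal-phase subset).
#' @param sex Which dyad member to evaluate: `"male"` or `"female"`.
#' @param scope Label recorded in the output (e.g. `"season"`, `"early"`).
#' @return A tibble, one row per event: `event_id`, `animal_id`, `sex`,
#'   `scope`, `n_locations`, `mean_volume`, `min_volume`, `max_volume`,
#'   `mean_distance_m`, `duration_h`, plus a `volumes` list-column of
#'   per-location values.
#' @export
event_ud_summary <- function(events, volume_grids, sex = c("male", "female"),
                             scope = "season") {
  sex <- match.arg(sex)
  purrr::map_dfr(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    id <- if (sex == "male") ev$male_id else ev$female_id
    grid <- volume_grids[[id]]
    if (is.null(grid)) {
      abort(paste0("no volume grid for animal ", id), class = "tendr_validation_error")
    }
    fx <- ev$fixes[[1]]
    if (sex == "male") {
      vols <- volume_at(grid, fx$x_a, fx$y_a)
    } else {
      vols <- volume_at(grid, fx$x_b, fx$y_b)
    }
    tibble::tibble(
      event_id = ev$event_id, animal_id = id, sex = sex, scope = scope,
      n_locations = length(vols),
      mean_volume = mean(vols, na.rm = TRUE),
      min_volume = suppressWarnings(min(vols, na.rm = TRUE)),
      max_volume = suppressWarnings(max(vols, na.rm = TRUE)),
      mean_distance_m = ev$mean_distance_m,
      duration_h = ev$duration_h,
      volumes = list(vols)
    )
  })
}

#' Per-event decoded-state summaries
#'
#' For each event, the fraction of its flagged hourly locations decoded
#' into each HMM state, and the modal state (ties broken toward the lower
#' state index).
#'
#' @param events Event table.
#' @param reg Regular hourly track of the evaluated animal.
#' @param states Integer state sequence aligned with `reg` (from
#'   [viterbi_decode()]; note a step series is one element shorter than the
#'   location series - pass states positionally aligned with `reg` rows,
#'   e.g. `c(states, states[length(states)])` or decode per location as
#'   preferred; lengths must match `nrow(reg)`).
#' @param n_states Number of states in the fitted model.
#' @return A tibble, one row per event: `event_id`, `n_hours`,
#'   `prop_state_1` ... `prop_state_N`, `modal_state`, `majority_prop`,
#'   `mean_distance_m`, `duration_h`.
#' @export
event_state_summary <- function(events, reg, states, n_states) {
  stopifnot(length(states) == nrow(reg))
  purrr::map_dfr(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    flag <- label_event_hours(ev, reg)
    st <- states[flag]
    props <- vapply(seq_len(n_states), function(s) mean(st == s), numeric(1))
    out <- tibble::tibble(
      event_id = ev$event_id,
      n_hours = length(st),
      modal_state = which.max(props),
      majority_prop = max(props),
      mean_distance_m = ev$mean_distance_m,
      duration_h = ev$duration_h
    )
    for (s in seq_len(n_states)) out[[paste0("prop_state_", s)]] <- props[s]
    out
  })
}

#' Consistency report: can single-sex models flag the events?
#'
#' Operationalizes the expected-pattern logic of the two evaluation routes:
#' \itemize{
#'   \item UD side: the span of per-location volumes and, for every
#'     candidate threshold \eqn{v \in \{5, 10, \ldots, 95\}}, the fraction
#'     of event locations with volume \eqn{\le v} (core-use / male
#'     convention) and \eqn{\ge v} (periphery / female convention).  A
#'     usable threshold would capture nearly all event locations.
#'   \item HMM side: modal-state agreement (the largest fraction of events
#'     sharing one modal state) and the mean within-event majority-state
#'     proportion.  A usable model would decode nearly every event into the
#'     same single state.
#' }
#'
#' @param ud_summaries Output of [event_ud_summary()] (or `NULL`).
#' @param state_summaries Output of [event_state_summary()] (or `NULL`).
#' @param thresholds Candidate volume thresholds, percent.
#' @return A `tendr_report` list with elements `ud` (list: `volume_span`,
#'   `threshold_sweep` tibble, `per_event` tibble) and `hmm` (list:
#'   `modal_agreement`, `modal_state`, `mean_majority_prop`, `per_event`
#'   tibble), each `NULL` when the corresponding input was.
#' @export
consistency_report <- function(ud_summaries = NULL, state_summaries = NULL,
                               thresholds = seq(5, 95, by = 5)) {
  out <- list(ud = NULL, hmm = NULL)
  if (!is.null(ud_summaries) && nrow(ud_summaries) > 0) {
    vols <- unlist(ud_summaries$volumes)
    vols <- vols[!is.na(vols)]
    sweep <- tibble::tibble(
      threshold = thresholds,
      frac_below = vapply(thresholds, function(v) mean(vols <= v), numeric(1)),
      frac_above = vapply(thresholds, function(v) mean(vols >= v), numeric(1))
    )
    out$ud <- list(
      volume_span = range(vols),
      threshold_sweep = sweep,
      per_event = dplyr::select(ud_summaries, -dplyr::any_of("volumes"))
    )
  }
  if (!is.null(state_summaries) && nrow(state_summaries) > 0) {
    tab <- table(state_summaries$modal_state)
    out$hmm <- list(
      modal_agreement = max(tab) / nrow(state_summaries),
      modal_state = as.integer(names(tab)[which.max(tab)]),
      mean_majority_prop = mean(state_summaries$majority_prop),
      per_event = state_summaries
    )
  }
  class(out) <- "tendr_report"
  out
}

#' @export
print.tendr_report <- function(x, ...) {
  cat("<tendr_report>\n")
  if (!is.null(x$ud)) {
    cat(sprintf(
      "  UD: %d events, per-location volume span %.1f-%.1f%%\n",
      nrow(x$ud$per_event), x$ud$volume_span[1], x$ud$volume_span[2]
    ))
    best <- x$ud$threshold_sweep[which.max(x$ud$threshold_sweep$frac_below), ]
    cat(sprintf(
      "      best core-use threshold %g%% captures %.0f%% of event locations\n",
      best$threshold, 100 * best$frac_below
    ))
  }
  if (!is.null(x$hmm)) {
    cat(sprintf(
      "  HMM: %d events, modal-state agreement %.2f (state %d), mean majority prop %.2f\n",
      nrow(x$hmm$per_event), x$hmm$modal_agreement, x$hmm$modal_state,
      x$hmm$mean_majority_prop
    ))
  }
  invisible(x)
}

#' Permutation baseline for modal-state agreement
#'
#' Null reference for the HMM-side consistency index: event windows are
#' repeatedly shifted to random start positions within the decoded
#' sequence (preserving each event's length in hours, avoiding the true
#' event hours when possible is *not* required - the null is "windows of
#' the same sizes placed at random"), and the modal-state agreement is
#' recomputed for each placement.
#'
#' @param reg Regular hourly track.
#' @param states Decoded state sequence aligned with `reg`.
#' @param events Event table (for the window lengths).
#' @param n_states Number of states.
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed for the placements.
#' @return List: `observed` agreement, `null` vector of permuted
#'   agreements, `p_value` (fraction of null \eqn{\ge} observed, with the
#'   +1 correction).
#' @export
modal_agreement_permutation <- function(reg, states, events, n_states,
                                        n_perm = 999, seed = 1) {
  stopifnot(length(states) == nrow(reg))
  obs_summary <- event_state_summary(events, reg, states, n_states)
  observed <- max(table(obs_summary$modal_state)) / nrow(obs_summary)
  lens <- obs_summary$n_hours
  n <- length(states)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      modal <- vapply(lens, function(L) {
        s0 <- sample.int(n - L + 1, 1)
        window <- states[s0:(s0 + L - 1)]
        props <- tabulate(window, nbins = n_states)
        which.max(props)
      }, integer(1))
      max(tabulate(modal, nbins = n_states)) / length(modal)
    }, numeric(1))
  })
  list(
    observed = observed,
    null = null,
    p_value = (1 + sum(null >= observed)) / (n_perm + 1)
  )
}

#' Histogram of event-location UD volumes
#'
#' One bar chart of per-location UD volumes across events, shaded by each
#' event's mean male-female distance.
#'
#' @param ud_summaries Output of [event_ud_summary()].
#' @param binwidth Histogram bin width, percent.
#' @return A ggplot.
#' @export
plot_volume_histogram <- function(ud_summaries, binwidth = 5) {
  df <- ud_summaries |>
    dplyr::select("event_id", "mean_distance_m", "volumes") |>
    tidyr::unnest_longer("volumes", values_to = "volume") |>
    dplyr::filter(!is.na(.data$volume))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$volume, fill = .data$mean_distance_m,
                                   group = .data$event_id)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0, colour = "grey30",
                            linewidth = 0.1) +
    ggplot2::scale_fill_viridis_c(name = "Mean dyad\ndistance (m)") +
    ggplot2::labs(x = "UD volume of event location (%)", y = "Locations")
}

#' Stacked per-event state proportions
#'
#' Events on the x axis (ordered by mean dyad distance), stacked decoded
#' state proportions on the y axis.
#'
#' @param state_summaries Output of [event_state_summary()].
#' @return A ggplot.
#' @export
plot_state_proportions <- function(state_summaries) {
  df <- state_summaries |>
    dplyr::arrange(.data$mean_distance_m) |>
    dplyr::mutate(event = factor(.data$event_id, levels = .data$event_id)) |>
    tidyr::pivot_longer(dplyr::starts_with("prop_state_"),
      names_to = "state", names_prefix = "prop_state_", values_to = "prop"
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$event, y = .data$prop,
                                   fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "State") +
    ggplot2::labs(x = "Event (ordered by mean dyad distance)",
                  y = "Proportion of event hours") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
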