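make_reg <- function(n, t0 = "2015-11-01 00:00:00") {
  tibble::tibble(
    animal_id = "M1",
    timestamp = as.POSIXct(t0, tz = "UTC") + (seq_len(n) - 1) * 3600,
    x = seq_len(n) * 10, y = 0, imputed = FALSE
  )
}

make_event <- function(start_h, end_h, id = "e1", t0 = "2015-11-01 00:00:00",
                       dist = 50) {
  t0 <- as.POSIXct(t0, tz = "UTC")
  tibble::tibble(
    event_id = id, male_id = "M1", female_id = "F1",
    start = t0 + start_h * 3600, end = t0 + end_h * 3600,
    n_fixes = end_h - start_h + 1L,
    duration_h = end_h - start_h,
    mean_distance_m = dist, classification = "liberal"
  )
}

vol_grid <- function(values, cell = 30) {
  # direct construction of a volume surface for lookup tests
  structure(list(origin = c(x = 0, y = 0), cell_size = cell,
                 nx = length(values), ny = 1,
                 volume = matrix(values, length(values), 1),
                 mass = matrix(1 / length(values), length(values), 1)),
            class = "tendr_ud_volume")
}

test_that("event hours are flagged inclusively", {
  reg <- make_reg(24)
  flags <- label_event_hours(make_event(10, 13), reg)
  expect_equal(sum(flags), 4)
  expect_equal(which(flags), 11:14)
  expect_equal(sum(label_event_hours(make_event(5, 5), reg)), 1)
  expect_error(label_event_hours(make_event(20, 30), reg),
               class = "tendr_validation_error")
})

test_that("flagged hours of a dyad's events never overlap", {
  for (s in 1:3) {
    sim <- simulate_pair(scenario(seed = s, season_days = 28, n_events = 4))
    dy <- align_dyad(sim$tracks, "M1", "F1")
    ev <- detect_events(dy)
    reg <- make_reg(28 * 24, t0 = "2015-10-18 00:00:00")
    used <- rep(0, nrow(reg))
    for (i in seq_len(nrow(ev))) used <- used + label_event_hours(ev[i, ], reg)
    expect_true(all(used <= 1))
  }
})

test_that("per-event UD summaries average the looked-up volumes", {
  ev <- make_event(0, 2)
  # event fixes at the centers of cells with volumes 10, 20, 30
  ev$fixes <- list(tibble::tibble(
    x_a = c(15, 45, 75), y_a = rep(15, 3),
    x_b = c(15, 45, 75), y_b = rep(15, 3)
  ))
  grids <- list(M1 = vol_grid(c(10, 20, 30)), F1 = vol_grid(c(10, 20, 30)))
  out <- event_ud_summary(ev, grids, sex = "male")
  expect_equal(out$mean_volume, 20)
  expect_equal(out$n_locations, 3L)
  expect_equal(out$volumes[[1]], c(10, 20, 30))
  expect_error(event_ud_summary(ev, grids["F1"], sex = "male"),
               class = "tendr_validation_error")
})

test_that("a fix at the UD mode gets the minimum volume on the grid", {
  tr <- toy_fixes(c(0, 200), c(0, 0))
  vg <- ud_volume(compute_ud(tr, 2000, delta = 10, buffer = 300))
  idx <- which(vg$mass == max(vg$mass), arr.ind = TRUE)[1, ]
  xy <- vg$origin + (idx - 0.5) * vg$cell_size
  ev <- make_event(0, 0)
  ev$fixes <- list(tibble::tibble(x_a = xy[1], y_a = xy[2], x_b = 0, y_b = 0))
  out <- event_ud_summary(ev, list(M1 = vg), sex = "male")
  expect_equal(out$mean_volume, min(vg$volume))
})

test_that("state proportions and modal states follow the tie rule", {
  reg <- make_reg(10)
  ev <- make_event(2, 5)   # flags hours 3..6, whose states below are 1,1,2,2
  st <- c(1, 1, 1, 1, 2, 2, 1, 1, 1, 1)
  out <- event_state_summary(ev, reg, st, 2)
  expect_equal(out$prop_state_1, 0.5)
  expect_equal(out$prop_state_2, 0.5)
  expect_equal(out$modal_state, 1L)        # tie -> lower index
  expect_equal(out$n_hours, 4L)

  out2 <- event_state_summary(ev, reg, rep(2, 10), 2)
  expect_equal(out2$prop_state_1, 0)
  expect_equal(out2$prop_state_2, 1)
  expect_equal(out2$modal_state, 2L)
})

test_that("the consistency report matches the expected success patterns", {
  uds <- tibble::tibble(
    event_id = c("e1", "e2"), animal_id = "M1", sex = "male", scope = "season",
    n_locations = c(2L, 2L), mean_volume = c(15, 25), min_volume = c(10, 20),
    max_volume = c(20, 30), mean_distance_m = c(40, 60), duration_h = c(3, 5),
    volumes = list(c(10, 20), c(20, 30))
  )
  states <- tibble::tibble(
    event_id = paste0("e", 1:4), n_hours = 4L,
    modal_state = c(1L, 1L, 2L, 2L), majority_prop = c(1, 1, 0.75, 0.75),
    mean_distance_m = 50, duration_h = 4,
    prop_state_1 = c(1, 1, 0.25, 0.25), prop_state_2 = c(0, 0, 0.75, 0.75)
  )
  rep <- consistency_report(uds, states)
  # all volumes <= 30: the 30% core-use threshold captures every location
  expect_equal(rep$ud$threshold_sweep$frac_below[rep$ud$threshold_sweep$threshold == 30], 1)
  expect_equal(rep$ud$volume_span, c(10, 30))
  expect_equal(rep$hmm$modal_agreement, 0.5)
  expect_equal(rep$hmm$mean_majority_prop, 0.875)
  # sweep monotonicity: nondecreasing below, nonincreasing above
  expect_false(is.unsorted(rep$ud$threshold_sweep$frac_below))
  expect_false(is.unsorted(rev(rep$ud$threshold_sweep$frac_above)))
})

test_that("removing an event leaves the other summaries unchanged", {
  reg <- make_reg(48)
  st <- rep(c(1L, 2L), 24)
  ev <- dplyr::bind_rows(make_event(2, 6, "e1"), make_event(20, 30, "e2"),
                         make_event(40, 44, "e3"))
  all3 <- event_state_summary(ev, reg, st, 2)
  drop2 <- event_state_summary(ev[-2, ], reg, st, 2)
  expect_equal(all3[c(1, 3), ], drop2, ignore_attr = TRUE)
})

test_that("the permutation baseline behaves like a p-value machine", {
  reg <- make_reg(200)
  withr::with_seed(2, st <- sample(1:2, 200, replace = TRUE))
  ev <- dplyr::bind_rows(make_event(10, 20, "e1"), make_event(50, 70, "e2"),
                         make_event(100, 105, "e3"))
  out <- modal_agreement_permutation(reg, st, ev, 2, n_perm = 99, seed = 1)
  expect_length(out$null, 99)
  expect_true(out$p_value > 0 && out$p_value <= 1)
  expect_true(out$observed >= 1 / 3 && out$observed <= 1)
  # a decoded sequence that is constant inside events but noisy elsewhere
  # must look extreme against the baseline
  st2 <- st
  for (i in 1:3) st2[label_event_hours(ev[i, ], reg)] <- 2L
  out2 <- modal_agreement_permutation(reg, st2, ev, 2, n_perm = 99, seed = 1)
  expect_gte(out2$observed, out$observed)
})

test_that("evaluation plots build without error", {
  uds <- tibble::tibble(
    event_id = c("e1", "e2"), animal_id = "M1", sex = "male", scope = "season",
    n_locations = 2L, mean_volume = c(15, 25), min_volume = c(10, 20),
    max_volume = c(20, 30), mean_distance_m = c(40, 60), duration_h = c(3, 5),
    volumes = list(c(10, 20), c(20, 30))
  )
  states <- tibble::tibble(
    event_id = c("e1", "e2"), n_hours = 4L, modal_state = c(1L, 2L),
    majority_prop = c(1, 0.75), mean_distance_m = c(40, 60), duration_h = 4,
    prop_state_1 = c(1, 0.25), prop_state_2 = c(0, 0.75)
  )
  p1 <- plot_volume_histogram(uds)
  p2 <- plot_state_proportions(states)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p1))
  expect_no_error(ggplot2::ggplot_build(p2))
})
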