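#' Estimate Brownian motion variance by leave-one-out likelihood
#'
#' Fits the motion-variance parameter \eqn{\sigma^2_m} of a Brownian bridge
#' movement model by maximizing the leave-one-out likelihood: every second
#' interior fix \eqn{z_k} is treated as an observation of the bridge spanned
#' by its neighbours, with conditional mean
#' \eqn{z_{k-1} + \alpha (z_{k+1} - z_{k-1})} and per-coordinate variance
#' \deqn{\alpha (1-\alpha) T \sigma^2_m + (1-\alpha)^2 \delta^2 + \alpha^2 \delta^2,}
#' where \eqn{\alpha = (t_k - t_{k-1}) / (t_{k+1} - t_{k-1})},
#' \eqn{T = t_{k+1} - t_{k-1}}, and \eqn{\delta} is the GPS error SD.
#' Maximization is a 1-D bounded search on the log scale.
#'
#' Time is measured in hours throughout, so \eqn{\sigma^2_m} has units of
#' m\eqn{^2}/h.
#'
#' @param track Fix table rows for a single animal (columns `timestamp`,
#'   `x`, `y`), time-sorted.
#' @param delta GPS measurement-error SD in meters (default 10, from collar
#'   field testing).
#' @param max_lag Maximum triplet span in hours; triplets spanning longer
#'   gaps are excluded (default `Inf`: all used).
#' @param bounds Search interval for \eqn{\sigma^2_m} (m\eqn{^2}/h).
#' @param leave_out `"even"` (default) scores the 2nd, 4th, ... fixes;
#'   `"odd"` the 3rd, 5th, ...  The two differ negligibly.
#' @return Scalar \eqn{\sigma^2_m} estimate (m\eqn{^2}/h).
#' @export
fit_motion_variance <- function(track, delta = 10, max_lag = Inf,
                                bounds = c(1e-6, 1e7),
                                leave_out = c("even", "odd")) {
  leave_out <- match.arg(leave_out)
  n <- nrow(track)
  if (n < 3) abort("need at least 3 fixes", class = "tendr_validation_error")
  stopifnot(delta >= 0, bounds[1] > 0, bounds[2] > bounds[1])
  tt <- as.numeric(track$timestamp) / 3600
  ks <- seq(if (leave_out == "even") 2L else 3L, n - 1L, by = 2L)
  if (length(ks) == 0) ks <- 2L
  Tt <- tt[ks + 1] - tt[ks - 1]
  ok <- Tt > 0 & Tt <= max_lag
  if (!any(ok)) {
    abort("no usable fix triplets (all exceed max_lag or have zero span)",
      class = "tendr_validation_error"
    )
  }
  ks <- ks[ok]; Tt <- Tt[ok]
  a <- (tt[ks] - tt[ks - 1]) / Tt
  mx <- track$x[ks - 1] + a * (track$x[ks + 1] - track$x[ks - 1])
  my <- track$y[ks - 1] + a * (track$y[ks + 1] - track$y[ks - 1])
  rx <- track$x[ks] - mx
  ry <- track$y[ks] - my
  err_var <- ((1 - a)^2 + a^2) * delta^2
  nll <- function(log_s2) {
    v <- a * (1 - a) * Tt * exp(log_s2) + err_var
    sum(log(v) + (rx^2 + ry^2) / (2 * v))
  }
  opt <- optimize(nll, interval = log(bounds), tol = 1e-8)
  exp(opt$minimum)
}

#' Rasterize a Brownian bridge utilization distribution
#'
#' Builds the UD of one track over a regular grid: for each bridge between
#' consecutive fixes, the bivariate-normal bridge law is integrated over
#' `n_integration` equally spaced interior time points (conditional mean
#' interpolates the endpoints; per-coordinate variance
#' \eqn{\alpha(1-\alpha) T \sigma^2_m + ((1-\alpha)^2 + \alpha^2)\delta^2}),
#' bridges are averaged with weights proportional to their duration, and the
#' cell masses are renormalized to sum to one.
#'
#' @param track Fix table rows for one animal, time-sorted.
#' @param sigma2_m Motion variance (m\eqn{^2}/h), from
#'   [fit_motion_variance()].
#' @param delta GPS error SD, meters.
#' @param cell_size Grid resolution, meters (default 30).
#' @param buffer Margin added around the track bounding box, meters; default
#'   `max(300, 3.5 * max bridge SD)` so the grid holds essentially all
#'   bridge mass.
#' @param n_integration Interior time points per bridge (default 10).
#' @param max_lag Bridges spanning more than this many hours are skipped
#'   (default `Inf`).
#' @return A `tendr_ud` object: list with `origin` (lower-left corner),
#'   `cell_size`, `nx`, `ny`, and `mass` (an `nx` by `ny` matrix summing
#'   to 1; `mass[i, j]` is the cell with x-index i, y-index j).
#' @export
compute_ud <- function(track, sigma2_m, delta = 10, cell_size = 30,
                       buffer = NULL, n_integration = 10, max_lag = Inf) {
  n <- nrow(track)
  if (n < 2) abort("need at least 2 fixes", class = "tendr_validation_error")
  stopifnot(sigma2_m >= 0, delta >= 0, cell_size > 0, n_integration >= 1)
  tt <- as.numeric(track$timestamp) / 3600
  dt <- diff(tt)
  use <- dt > 0 & dt <= max_lag
  if (!any(use)) abort("no usable bridges", class = "tendr_validation_error")
  max_sd <- sqrt(max(dt[use]) / 4 * sigma2_m + delta^2)
  if (is.null(buffer)) buffer <- max(300, 3.5 * max_sd)
  if (buffer < 3.5 * max_sd) {
    warn(sprintf(
      "buffer %.0f m is below 3.5 bridge SDs (%.0f m); UD mass may be clipped",
      buffer, 3.5 * max_sd
    ))
  }

  x0 <- floor((min(track$x) - buffer) / cell_size) * cell_size
  y0 <- floor((min(track$y) - buffer) / cell_size) * cell_size
  nx <- ceiling((max(track$x) + buffer - x0) / cell_size)
  ny <- ceiling((max(track$y) + buffer - y0) / cell_size)
  xc <- x0 + (seq_len(nx) - 0.5) * cell_size
  yc <- y0 + (seq_len(ny) - 0.5) * cell_size

  mass <- matrix(0, nx, ny)
  alphas <- seq_len(n_integration) / (n_integration + 1)
  for (i in which(use)) {
    w <- dt[i] / n_integration
    for (a in alphas) {
      mux <- track$x[i] + a * (track$x[i + 1] - track$x[i])
      muy <- track$y[i] + a * (track$y[i + 1] - track$y[i])
      v <- a * (1 - a) * dt[i] * sigma2_m + ((1 - a)^2 + a^2) * delta^2
      s <- sqrt(v)
      # truncate to a 6-SD window for speed; tails beyond are negligible
      ix <- which(abs(xc - mux) <= 6 * s + cell_size)
      iy <- which(abs(yc - muy) <= 6 * s + cell_size)
      if (length(ix) == 0 || length(iy) == 0) next
      mass[ix, iy] <- mass[ix, iy] +
        w * (dnorm(xc[ix], mux, s) %o% dnorm(yc[iy], muy, s))
    }
  }
  total <- sum(mass)
  if (total <= 0) abort("UD has zero mass on the grid", class = "tendr_validation_error")
  ud <- list(
    origin = c(x = x0, y = y0), cell_size = cell_size,
    nx = nx, ny = ny, mass = mass / total
  )
  class(ud) <- "tendr_ud"
  ud
}

#' Percent-volume transform of a utilization distribution
#'
#' Converts cell probability masses into standardized UD volumes: cells are
#' ranked by density from highest to lowest, and each cell's volume is 100
#' times the cumulative mass of all cells with density greater than or equal
#' to its own.  Small values mark core use areas; the p% probability contour
#' is the set of cells with volume at most p.  Density ties share one
#' (inclusive) value.
#'
#' @param ud A `tendr_ud` from [compute_ud()].
#' @return A `tendr_ud_volume` object: same geometry, with a `volume` matrix
#'   of percentages in (0, 100].
#' @export
ud_volume <- function(ud) {
  stopifnot(inherits(ud, "tendr_ud"))
  m <- as.vector(ud$mass)
  ord <- order(m, decreasing = TRUE)
  cum <- cumsum(m[ord])
  vol_sorted <- numeric(length(m))
  vol_sorted[ord] <- cum
  # ties: every cell takes the cumulative mass at the *last* cell of its tie
  # group, i.e. total mass of all cells with density >= its own
  tie_max <- tapply(vol_sorted, m, max)
  vol <- 100 * as.numeric(tie_max[as.character(m)])
  out <- list(
    origin = ud$origin, cell_size = ud$cell_size,
    nx = ud$nx, ny = ud$ny,
    volume = matrix(vol, ud$nx, ud$ny),
    mass = ud$mass
  )
  class(out) <- "tendr_ud_volume"
  out
}

#' Look up UD volume at point locations
#'
#' Cells are half-open intervals `[edge, edge + cell_size)` in both
#' coordinates, so a point on a shared edge belongs to the higher cell.
#' Points outside the grid extent yield `NA` with a warning (reported, not
#' fatal).
#'
#' @param vol A `tendr_ud_volume` from [ud_volume()].
#' @param x,y Numeric vectors of projected coordinates (meters).
#' @return Numeric vector of volumes (percent).
#' @export
volume_at <- function(vol, x, y) {
  stopifnot(inherits(vol, "tendr_ud_volume"), length(x) == length(y))
  ix <- floor((x - vol$origin[["x"]]) / vol$cell_size) + 1
  iy <- floor((y - vol$origin[["y"]]) / vol$cell_size) + 1
  ok <- ix >= 1 & ix <= vol$nx & iy >= 1 & iy <= vol$ny
  if (any(!ok)) {
    warn(sprintf("%d point(s) outside the UD grid extent: returning NA", sum(!ok)))
  }
  out <- rep(NA_real_, length(x))
  out[ok] <- vol$volume[cbind(ix[ok], iy[ok])]
  out
}

#' Tidy a UD or volume grid into a tibble
#'
#' @param grid A `tendr_ud` or `tendr_ud_volume`.
#' @return Tibble with cell-center `x`, `y` and `mass` (and `volume` where
#'   available).
#' @export
ud_to_tibble <- function(grid) {
  xc <- grid$origin[["x"]] + (seq_len(grid$nx) - 0.5) * grid$cell_size
  yc <- grid$origin[["y"]] + (seq_len(grid$ny) - 0.5) * grid$cell_size
  out <- tidyr::expand_grid(y = yc, x = xc) |>
    dplyr::select("x", "y")
  out$mass <- as.vector(grid$mass[cbind(
    match(out$x, xc), match(out$y, yc)
  )])
  if (!is.null(grid$volume)) {
    out$volume <- as.vector(grid$volume[cbind(match(out$x, xc), match(out$y, yc))])
  }
  out
}

#' Export a grid as ESRI ASCII raster
#'
#' @param grid A `tendr_ud` or `tendr_ud_volume`.
#' @param path Output path.
#' @param layer `"mass"` or `"volume"`.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, layer = c("mass", "volume")) {
  layer <- match.arg(layer)
  m <- grid[[layer]]
  if (is.null(m)) abort(paste0("grid has no layer '", layer, "'"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$nx),
    paste("nrows", grid$ny),
    paste("xllcorner", grid$origin[["x"]]),
    paste("yllcorner", grid$origin[["y"]]),
    paste("cellsize", grid$cell_size),
    paste("NODATA_value", -9999)
  ), con)
  # ESRI ASCII rows run north to south
  for (j in rev(seq_len(grid$ny))) {
    writeLines(paste(format(m[, j], scientific = TRUE, digits = 7), collapse = " "), con)
  }
  invisible(path)
}

#' @export
print.tendr_ud <- function(x, ...) {
  cat(sprintf(
    "<tendr_ud> %d x %d cells of %g m, origin (%.0f, %.0f), total mass %.6f\n",
    x$nx, x$ny, x$cell_size, x$origin[["x"]], x$origin[["y"]], sum(x$mass)
  ))
  invisible(x)
}

#' @export
print.tendr_ud_volume <- function(x, ...) {
  cat(sprintf(
    "<tendr_ud_volume> %d x %d cells of %g m, volumes %.2f-%.2f%%\n",
    x$nx, x$ny, x$cell_size, min(x$volume), max(x$volume)
  ))
  invisible(x)
}

#' Plot a UD volume surface
#'
#' @param object A `tendr_ud_volume`.
#' @param contours Contour levels (percent) to outline (default 50 and 95).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.tendr_ud_volume <- function(object, contours = c(50, 95), ...) {
  df <- ud_to_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$volume)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$volume),
      breaks = contours, colour = "white", linewidth = 0.3
    ) +
    ggplot2::scale_fill_viridis_c(name = "UD volume (%)", direction = -1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)")
}
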