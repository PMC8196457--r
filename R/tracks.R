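#' Read animal relocation tracks from CSV
#'
#' Reads a relocation table with one row per GPS fix and validates it into
#' the canonical track format used throughout the package: a tibble with one
#' row per fix, sorted by animal and time.  Coordinates must arrive already
#' projected in meters; no geographic reprojection is performed (all
#' proximity thresholds in the pipeline are metric).
#'
#' @param path Path to a CSV file with columns `animal_id`, `sex`
#'   (`"male"`/`"female"`), `study_area`, `timestamp` (ISO-8601, read as
#'   UTC), `x` and `y` (projected meters).
#' @param col_map Optional named character vector mapping the canonical
#'   column names to the names used in the file, e.g.
#'   `c(animal_id = "individual-local-identifier", x = "utm-easting")` for
#'   Movebank-style exports.
#'
#' @return A tibble of fixes (class `tendr_tracks`) with the canonical
#'   columns, one animal per `animal_id`, fixes sorted by time within
#'   animal.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write.csv(data.frame(
#'   animal_id = "F1", sex = "female", study_area = "SN",
#'   timestamp = c("2015-11-01 00:00:00", "2015-11-01 01:00:00"),
#'   x = c(0, 30), y = c(0, 40)
#' ), path, row.names = FALSE)
#' read_tracks(path)
read_tracks <- function(path, col_map = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "tendr_format_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (canonical in names(col_map)) {
      if (col_map[[canonical]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[canonical]]] <- canonical
      }
    }
  }
  required <- c("animal_id", "sex", "study_area", "timestamp", "x", "y")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "tendr_format_error"
    )
  }
  out <- raw |>
    dplyr::select(dplyr::all_of(required)) |>
    dplyr::mutate(
      animal_id = as.character(.data$animal_id),
      sex = as.character(.data$sex),
      study_area = as.character(.data$study_area),
      timestamp = as_utc(.data$timestamp),
      x = as.numeric(.data$x),
      y = as.numeric(.data$y)
    )
  validate_tracks(out)
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(as.character(x), tz = "UTC")
}

#' Validate a fix table
#'
#' Checks the track invariants: required columns present, finite coordinates,
#' known sex labels, and strictly increasing timestamps within each animal
#' (duplicate fixes for the same animal and instant are rejected).  Rows are
#' returned sorted by animal then time.
#'
#' @param fixes A data frame of fixes with the canonical columns (see
#'   [read_tracks()]).
#' @return The validated, sorted tibble with class `tendr_tracks`.
#' @export
validate_tracks <- function(fixes) {
  fixes <- tibble::as_tibble(fixes)
  required <- c("animal_id", "sex", "study_area", "timestamp", "x", "y")
  missing_cols <- setdiff(required, names(fixes))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "tendr_format_error"
    )
  }
  if (!all(is.finite(fixes$x)) || !all(is.finite(fixes$y))) {
    abort("non-finite coordinates", class = "tendr_validation_error")
  }
  bad_sex <- setdiff(unique(fixes$sex), c("male", "female"))
  if (length(bad_sex) > 0) {
    abort(
      paste0("sex must be 'male' or 'female'; found: ", paste(bad_sex, collapse = ", ")),
      class = "tendr_validation_error"
    )
  }
  fixes <- dplyr::arrange(fixes, .data$animal_id, .data$timestamp)
  dup <- fixes |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::filter(duplicated(.data$timestamp)) |>
    dplyr::ungroup()
  if (nrow(dup) > 0) {
    abort(
      paste0(
        "duplicate timestamps within animal(s): ",
        paste(unique(dup$animal_id), collapse = ", ")
      ),
      class = "tendr_validation_error"
    )
  }
  class(fixes) <- c("tendr_tracks", class(fixes))
  fixes
}

#' Write tracks back to CSV
#'
#' @param fixes A fix table as returned by [read_tracks()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(fixes, path) {
  out <- dplyr::mutate(
    tibble::as_tibble(fixes),
    timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Breeding-season phase calendar
#'
#' Calendar of early / peak / late breeding (rut) phases for the northern
#' and southern study regions, as month-day intervals applied year-agnostically.
#' Endpoints are inclusive and phases are contiguous within each region.
#'
#' @param north,south Optional length-4 character vectors of month-day
#'   boundaries `c(early_start, peak_start, late_start, late_end)` in
#'   `"mm-dd"` form, overriding the defaults (north: Oct 18 - Nov 7 early,
#'   Nov 8 - Nov 28 peak, Nov 29 - Dec 19 late; south: Oct 16 - Nov 5 early,
#'   Nov 6 - Nov 29 peak, Nov 30 - Dec 20 late).
#' @return A tibble with columns `region`, `phase`, `start_md`, `end_md`
#'   (class `tendr_calendar`).
#' @export
breeding_calendar <- function(north = c("10-18", "11-08", "11-29", "12-19"),
                              south = c("10-16", "11-06", "11-30", "12-20")) {
  build_region <- function(region, b) {
    stopifnot(length(b) == 4)
    tibble::tibble(
      region = region,
      phase = c("early", "peak", "late"),
      start_md = b[1:3],
      end_md = c(md_shift(b[2], -1), md_shift(b[3], -1), b[4])
    )
  }
  cal <- dplyr::bind_rows(build_region("north", north), build_region("south", south))
  key <- md_key(cal$start_md)
  for (r in unique(cal$region)) {
    k <- key[cal$region == r]
    ke <- md_key(cal$end_md[cal$region == r])
    if (is.unsorted(k, strictly = TRUE) || any(ke < k)) {
      abort("calendar phases must be ordered and non-empty", class = "tendr_validation_error")
    }
  }
  class(cal) <- c("tendr_calendar", class(cal))
  cal
}

# month-day arithmetic on a fixed non-leap reference year
md_shift <- function(md, days) {
  d <- as.Date(paste0("2001-", md)) + days
  format(d, "%m-%d")
}

md_key <- function(md) {
  as.integer(format(as.Date(paste0("2001-", md)), "%j"))
}

#' Assign breeding phase to timestamps
#'
#' Year-agnostic inclusive-endpoint lookup of the breeding phase (early,
#' peak, late) for each timestamp, by region.  Dates outside the breeding
#' season map to `"outside"`.
#'
#' @param timestamp A `POSIXct` (or coercible) vector.
#' @param region `"north"` or `"south"` (scalar or vector).
#' @param calendar A calendar from [breeding_calendar()].
#' @return Character vector in `c("early", "peak", "late", "outside")`.
#' @export
assign_phase <- function(timestamp, region, calendar = breeding_calendar()) {
  timestamp <- as_utc(timestamp)
  if (any(!region %in% unique(calendar$region))) {
    abort(
      paste0(
        "unknown region(s): ",
        paste(setdiff(unique(region), unique(calendar$region)), collapse = ", ")
      ),
      class = "tendr_validation_error"
    )
  }
  region <- rep_len(region, length(timestamp))
  doy <- md_key(format(timestamp, "%m-%d"))
  out <- rep("outside", length(timestamp))
  for (i in seq_len(nrow(calendar))) {
    row <- calendar[i, ]
    hit <- region == row$region &
      doy >= md_key(row$start_md) & doy <= md_key(row$end_md)
    out[hit] <- row$phase
  }
  out
}

#' Map study areas to calendar regions
#'
#' The default mapping follows the study design: Susquehannock areas
#' (`SN`, `SS`) use the northern calendar, Rothrock and Bald Eagle
#' (`RR`, `BE`) the southern one.  Unknown areas default to `"north"` with
#' a warning.
#'
#' @param study_area Character vector of study-area codes.
#' @return Character vector of regions.
#' @export
area_region <- function(study_area) {
  map <- c(SN = "north", SS = "north", RR = "south", BE = "south")
  out <- unname(map[study_area])
  if (any(is.na(out))) {
    warn(paste0(
      "unknown study area(s) ",
      paste(unique(study_area[is.na(out)]), collapse = ", "),
      ": using northern calendar"
    ))
    out[is.na(out)] <- "north"
  }
  out
}

#' Align two tracks into a dyad series of simultaneous fixes
#'
#' Pairs fixes of two animals whose timestamps differ by at most `tolerance`
#' seconds, using globally nearest-time matching (candidate pairs are ranked
#' by absolute time difference and accepted greedily so that each fix is
#' used at most once).  The Euclidean distance between paired locations is
#' attached.  An empty overlap yields an empty series, not an error.
#'
#' @param fixes A fix table containing (at least) the two animals.
#' @param id_a,id_b Animal ids to pair (conventionally male, female; the
#'   result is symmetric up to column naming).
#' @param tolerance Maximum |time difference| for a pair, seconds.
#'   Default 300 s: nominal schedules are hourly but fix acquisition drifts
#'   by a few minutes.
#' @return A tibble (class `tendr_dyad`), one row per paired fix, ordered by
#'   time, with columns `timestamp` (midpoint of the two fix times), `t_a`,
#'   `t_b`, `x_a`, `y_a`, `x_b`, `y_b`, `distance`, and attributes `id_a`,
#'   `id_b`.
#' @export
align_dyad <- function(fixes, id_a, id_b, tolerance = 300) {
  stopifnot(tolerance >= 0)
  a <- dplyr::filter(tibble::as_tibble(fixes), .data$animal_id == id_a)
  b <- dplyr::filter(tibble::as_tibble(fixes), .data$animal_id == id_b)
  if (nrow(a) > 0 && nrow(b) > 0 &&
      length(intersect(unique(a$study_area), unique(b$study_area))) == 0) {
    warn("dyad members come from different study areas")
  }
  ta <- as.numeric(a$timestamp)
  tb <- as.numeric(b$timestamp)
  pairs <- empty_pairs <- tibble::tibble(ia = integer(), ib = integer(), dt = numeric())
  if (length(ta) > 0 && length(tb) > 0) {
    # candidate pairs within tolerance, via window join on sorted times
    cand <- purrr::map_dfr(seq_along(ta), function(i) {
      j <- which(abs(tb - ta[i]) <= tolerance)
      if (length(j) == 0) return(NULL)
      tibble::tibble(ia = i, ib = j, dt = abs(tb[j] - ta[i]))
    })
    if (nrow(cand) > 0) {
      cand <- dplyr::arrange(cand, .data$dt, .data$ia, .data$ib)
      used_a <- logical(length(ta))
      used_b <- logical(length(tb))
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        if (!used_a[cand$ia[k]] && !used_b[cand$ib[k]]) {
          keep[k] <- TRUE
          used_a[cand$ia[k]] <- TRUE
          used_b[cand$ib[k]] <- TRUE
        }
      }
      pairs <- cand[keep, ]
    }
  }
  out <- tibble::tibble(
    timestamp = as.POSIXct((ta[pairs$ia] + tb[pairs$ib]) / 2,
      origin = "1970-01-01", tz = "UTC"
    ),
    t_a = a$timestamp[pairs$ia],
    t_b = b$timestamp[pairs$ib],
    x_a = a$x[pairs$ia], y_a = a$y[pairs$ia],
    x_b = b$x[pairs$ib], y_b = b$y[pairs$ib]
  )
  out <- dplyr::arrange(out, .data$timestamp)
  out$distance <- sqrt((out$x_a - out$x_b)^2 + (out$y_a - out$y_b)^2)
  attr(out, "id_a") <- id_a
  attr(out, "id_b") <- id_b
  class(out) <- c("tendr_dyad", class(out))
  out
}

#' List male-female dyads sharing a study area
#'
#' @param fixes A fix table.
#' @return Tibble with columns `male_id`, `female_id`, `study_area`.
#' @export
list_dyads <- function(fixes) {
  meta <- dplyr::distinct(
    tibble::as_tibble(fixes),
    .data$animal_id, .data$sex, .data$study_area
  )
  males <- dplyr::filter(meta, .data$sex == "male")
  females <- dplyr::filter(meta, .data$sex == "female")
  dplyr::inner_join(
    dplyr::select(males, male_id = "animal_id", "study_area"),
    dplyr::select(females, female_id = "animal_id", "study_area"),
    by = "study_area",
    relationship = "many-to-many"
  ) |>
    dplyr::select("male_id", "female_id", "study_area")
}
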