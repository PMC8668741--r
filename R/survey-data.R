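#' Read a carcass-search table
#'
#' Reads a delimited text file with one row per carcass search (one
#' search-date-site combination) and returns a validated tibble in the
#' package's canonical layout. Carcass counts are *corrected* counts
#' (scaled upstream for persistence, detectability and off-transect
#' mortality) and may therefore be non-integer; they are accepted as given,
#' without re-rounding.
#'
#' @param path Path to a delimited text file.
#' @param column_map Named character vector mapping canonical column names
#'   (`date`, `site`, `period`, `n_carcass`, `interval_days`) to the column
#'   names used in the file. Canonical names missing from the map are
#'   looked up verbatim.
#' @param delim Field delimiter, `","` by default (use `"\t"` for TSV).
#'
#' @return A tibble with columns `date` (Date), `site` (`"impact"` or
#'   `"control"`), `period` (`"before"` or `"after"`), `n_carcass`
#'   (non-negative double) and `interval_days` (positive integer, days since
#'   the previous search at the same site).
#'
#' @details Rows violating an invariant (negative count, non-positive
#'   interval, unknown site/period label, duplicated site-date pair) raise a
#'   validation error naming the offending row(s). A missing mapped column is
#'   a configuration error.
#'
#' @seealso [pool_flights()], [write_carcass_table()]
#' @export
read_carcass_table <- function(path, column_map = NULL, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  x <- remap_columns(raw, column_map,
                     c("date", "site", "period", "n_carcass", "interval_days"))
  x <- dplyr::mutate(
    x,
    date = as.Date(.data$date),
    site = normalize_level(.data$site, c("impact", "control"), "site"),
    period = normalize_level(.data$period, c("before", "after"), "period"),
    n_carcass = as.numeric(.data$n_carcass),
    interval_days = as.integer(.data$interval_days)
  )
  validate_carcass(x)
  dplyr::arrange(tibble::as_tibble(x), .data$site, .data$date)
}

#' Read a flight-count table
#'
#' Reads a delimited text file with one row per flight-observation session
#' (one counting-point-date combination for one species group) and returns a
#' validated tibble, optionally restricted to a single species group.
#'
#' @inheritParams read_carcass_table
#' @param column_map Named character vector mapping the canonical names
#'   (`date`, `site`, `period`, `counting_point`, `species_group`,
#'   `individuals`, `hours`) to file columns.
#' @param species_group If non-`NULL`, keep only sessions of this species
#'   group. A label absent from the data yields an empty result with a
#'   warning.
#'
#' @return A tibble with columns `date`, `site`, `period`, `counting_point`,
#'   `species_group`, `individuals` (non-negative integer) and `hours`
#'   (positive double).
#' @seealso [test_synchronicity()], [pool_flights()]
#' @export
read_flight_table <- function(path, column_map = NULL, species_group = NULL,
                              delim = ",") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  x <- remap_columns(raw, column_map,
                     c("date", "site", "period", "counting_point",
                       "species_group", "individuals", "hours"))
  x <- dplyr::mutate(
    x,
    date = as.Date(.data$date),
    site = normalize_level(.data$site, c("impact", "control"), "site"),
    period = normalize_level(.data$period, c("before", "after"), "period"),
    counting_point = as.character(.data$counting_point),
    species_group = as.character(.data$species_group),
    individuals = as.integer(.data$individuals),
    hours = as.numeric(.data$hours)
  )
  validate_flight(x)
  x <- tibble::as_tibble(x)
  if (!is.null(species_group)) {
    if (!species_group %in% x$species_group) {
      warn(paste0("species group '", species_group,
                  "' not present in ", path, "; returning 0 rows"))
    }
    x <- dplyr::filter(x, .data$species_group == !!species_group)
  }
  dplyr::arrange(x, .data$site, .data$date, .data$counting_point)
}

#' Write survey tables in canonical form
#'
#' Serialize a carcass-search or flight-count tibble back to delimited text
#' using the canonical column names, so that reading the file again
#' reproduces the table field-for-field.
#'
#' @param x A tibble as returned by [read_carcass_table()] or
#'   [read_flight_table()].
#' @inheritParams read_carcass_table
#' @return `path`, invisibly.
#' @export
write_carcass_table <- function(x, path, delim = ",") {
  validate_carcass(x)
  cols <- c("date", "site", "period", "n_carcass", "interval_days")
  readr::write_delim(x[cols], path, delim = delim)
  invisible(path)
}

#' @rdname write_carcass_table
#' @export
write_flight_table <- function(x, path, delim = ",") {
  validate_flight(x)
  cols <- c("date", "site", "period", "counting_point", "species_group",
            "individuals", "hours")
  readr::write_delim(x[cols], path, delim = delim)
  invisible(path)
}

#' Pool flight sessions into carcass-search intervals
#'
#' Builds the fusion-design observation table for one site: every flight
#' session is attributed to the carcass search that closes the half-open
#' interval (previous search date, search date] containing it, and the
#' session counts inside each interval are pooled. A search whose interval
#' contains no flight session does not form an observation of its own:
#' its carcass count and interval length roll forward and are attributed to
#' the next search whose interval does contain flight data, so carcass and
#' exposure windows stay aligned.
#'
#' The earliest search at the site only anchors the first interval; its own
#' carcass count belongs to an unobserved earlier interval and is dropped.
#'
#' @param searches Carcass-search tibble (see [read_carcass_table()]).
#' @param flights Flight-count tibble (see [read_flight_table()]), already
#'   restricted to one species group.
#' @param site Which site to build observations for, `"impact"` (the
#'   diverter-equipped line) by default.
#'
#' @return A tibble of fusion observations with columns `date`, `jday`
#'   (day of year of the closing search), `period`, `n_carcass`,
#'   `interval_days`, `pooled_individuals`, `pooled_hours` and `exposure_A`
#'   (see [compute_exposure()]).
#' @export
pool_flights <- function(searches, flights, site = c("impact", "control")) {
  site <- match.arg(site)
  s <- dplyr::arrange(dplyr::filter(searches, .data$site == !!site),
                      .data$date)
  f <- dplyr::filter(flights, .data$site == !!site)
  if (nrow(f) == 0L) {
    abort(paste0("no flight data for site '", site,
                 "': fusion analysis impossible"))
  }
  if (nrow(s) < 2L) {
    abort("need at least two carcass searches to form an interval")
  }
  if (anyDuplicated(s$date)) {
    abort("duplicated search dates within site")
  }

  acc_carcass <- 0
  acc_days <- 0L
  out <- vector("list", nrow(s) - 1L)
  n_out <- 0L
  for (i in seq(2L, nrow(s))) {
    in_window <- f$date > s$date[i - 1L] & f$date <= s$date[i]
    acc_carcass <- acc_carcass + s$n_carcass[i]
    acc_days <- acc_days + s$interval_days[i]
    if (!any(in_window)) next
    n_out <- n_out + 1L
    out[[n_out]] <- tibble::tibble(
      date = s$date[i],
      jday = as.integer(strftime(s$date[i], "%j")),
      period = s$period[i],
      n_carcass = acc_carcass,
      interval_days = acc_days,
      pooled_individuals = sum(f$individuals[in_window]),
      pooled_hours = sum(f$hours[in_window])
    )
    acc_carcass <- 0
    acc_days <- 0L
  }
  if (n_out == 0L) {
    abort("no carcass-search interval contains flight data")
  }
  if (acc_days > 0L) {
    warn(sprintf(
      "%d trailing day(s) of search effort had no subsequent flight data and were dropped",
      acc_days))
  }
  compute_exposure(dplyr::bind_rows(out[seq_len(n_out)]))
}

#' Flight exposure of a fusion observation
#'
#' Computes the exposure measure A = interval_days x pooled_individuals /
#' pooled_hours for each fusion observation: the flight intensity
#' (birds per observation hour) scaled by the length of the carcass-search
#' interval. Downstream models use `log(1 + A)` as the regression offset.
#'
#' @param obs Tibble of fusion observations with columns `interval_days`,
#'   `pooled_individuals` and `pooled_hours` (see [pool_flights()]).
#' @return `obs` with the column `exposure_A` added or replaced. `A = 0`
#'   exactly when no birds were observed; positive individuals with zero
#'   observation hours is an error.
#' @export
compute_exposure <- function(obs) {
  bad <- obs$pooled_hours <= 0 & obs$pooled_individuals > 0
  if (any(bad)) {
    abort(paste0("rows with individuals > 0 but no observation hours: ",
                 paste(which(bad), collapse = ", ")))
  }
  dplyr::mutate(
    obs,
    exposure_A = dplyr::if_else(
      .data$pooled_individuals == 0, 0,
      .data$interval_days * .data$pooled_individuals / .data$pooled_hours)
  )
}

# --- internal helpers --------------------------------------------------------

remap_columns <- function(x, column_map, canonical) {
  map <- setNames(canonical, canonical)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), canonical)
    if (length(unknown)) {
      abort(paste0("column_map names not canonical: ",
                   paste(unknown, collapse = ", ")))
    }
    map[names(column_map)] <- column_map
  }
  missing <- map[!map %in% names(x)]
  if (length(missing)) {
    abort(paste0("mapped column(s) absent from file: ",
                 paste(missing, collapse = ", ")), class = "config_error")
  }
  out <- x[unname(map)]
  names(out) <- names(map)
  out
}

normalize_level <- function(x, levels, what) {
  y <- levels[match(tolower(trimws(as.character(x))), levels)]
  if (anyNA(y) && !all(is.na(x) == is.na(y))) {
    bad <- which(is.na(y) & !is.na(x))
    abort(sprintf("unrecognized %s label in row(s) %s (expected %s)",
                  what, paste(utils::head(bad, 5), collapse = ", "),
                  paste(levels, collapse = "/")),
          class = "validation_error")
  }
  y
}

validate_carcass <- function(x) {
  fail_rows(x$n_carcass < 0, "n_carcass < 0")
  fail_rows(is.na(x$interval_days) | x$interval_days < 1, "interval_days < 1")
  fail_rows(is.na(x$n_carcass), "missing n_carcass")
  dup <- duplicated(x[c("site", "date")])
  fail_rows(dup, "duplicated (site, date)")
  invisible(x)
}

validate_flight <- function(x) {
  fail_rows(is.na(x$hours) | x$hours <= 0, "hours <= 0")
  fail_rows(is.na(x$individuals) | x$individuals < 0, "individuals < 0")
  invisible(x)
}

fail_rows <- function(bad, msg) {
  if (any(bad)) {
    abort(sprintf("%s in row(s): %s", msg,
                  paste(utils::head(which(bad), 10), collapse = ", ")),
          class = "validation_error")
  }
}
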