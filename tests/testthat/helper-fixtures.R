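# In-code fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

day0 <- as.Date("2021-03-01")

make_searches <- function(offsets, n_carcass, site = "impact",
                          period = NULL) {
  period <- period %||% rep("before", length(offsets))
  tibble::tibble(
    date = day0 + offsets,
    site = site,
    period = period,
    n_carcass = n_carcass,
    interval_days = as.integer(c(1, diff(offsets)))
  )
}

make_flights <- function(offsets, individuals, hours, site = "impact",
                         period = "before", species_group = "geese",
                         counting_point = "P1") {
  tibble::tibble(
    date = day0 + offsets,
    site = site,
    period = period,
    counting_point = counting_point,
    species_group = species_group,
    individuals = as.integer(individuals),
    hours = hours
  )
}

# Carcass table with `reps` identical rows per site x period cell.
cell_searches <- function(means, reps = 20) {
  cells <- expand.grid(period = c("before", "after"),
                       site = c("impact", "control"),
                       stringsAsFactors = FALSE)
  dplyr::bind_rows(lapply(seq_len(nrow(cells)), function(i) {
    key <- paste(cells$site[i], cells$period[i], sep = "_")
    tibble::tibble(site = cells$site[i], period = cells$period[i],
                   n_carcass = rep(means[[key]], reps),
                   interval_days = 1L)
  }))
}

# Fusion-observation table built directly.
make_fusion <- function(period, n_carcass, exposure_A, interval_days = 1L,
                        pooled_hours = 1) {
  tibble::tibble(
    period = period, n_carcass = n_carcass,
    interval_days = interval_days,
    pooled_individuals = as.integer(round(exposure_A * pooled_hours /
                                            interval_days)),
    pooled_hours = pooled_hours,
    exposure_A = exposure_A
  )
}

write_fixture_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
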