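# shared fixtures, built once per test run

the <- new.env()

test_schedule <- function() {
  if (is.null(the$schedule)) the$schedule <- synthetic_mortality_schedule()
  the$schedule
}

test_fertility <- function() {
  if (is.null(the$fertility)) the$fertility <- synthetic_fertility_schedule()
  the$fertility
}

test_presets <- function() {
  if (is.null(the$presets)) {
    the$presets <- scenario_presets(test_schedule(), test_fertility())
  }
  the$presets
}

# constant-q schedule on the full projection window, one population group
constant_schedule <- function(q = 0, periods = seq(1981L, 2096L, 5L),
                              pop_group = "toy", max_age = TRUE) {
  df <- tidyr::expand_grid(
    pop_group = pop_group,
    period_start = as.integer(periods),
    age_lo = seq(0L, 95L, 5L)
  )
  df$q5 <- q
  if (max_age) df$q5[df$age_lo == 95L] <- 1
  df
}

# a complete census-count table from per-age counts (padded with zeros)
toy_counts <- function(counts_by_age, census_year = 2001L, language = "toy") {
  ladder <- age_ladder()
  tibble::tibble(
    language = language,
    census_year = as.integer(census_year),
    age_lo = ladder,
    count = as.integer(counts_by_age[match(ladder, as.integer(names(counts_by_age)))]) |>
      (\(x) ifelse(is.na(x), 0L, x))()
  )
}

# uniform weights over the reproductive ages
uniform_weights <- function() {
  tibble::tibble(age_lo = seq(15L, 45L, 5L), weight = rep(1 / 7, 7))
}

expect_tbl_equal <- function(a, b, tol = 1e-9) {
  strip <- function(x) {
    x <- as.data.frame(x)
    attributes(x) <- attributes(x)[c("names", "class", "row.names")]
    x
  }
  expect_equal(strip(a), strip(b), tolerance = tol)
}
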