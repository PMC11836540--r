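#' Read a census speaker-count table
#'
#' Reads a comma-separated table with columns `language`, `census_year`,
#' `age_lo`, `count` holding first-language speaker counts by five-year age
#' group. Every (language, census year) combination must carry the complete
#' age ladder 0-4 ... 100+ exactly once, and counts must be non-negative
#' integers. Published counts are typically perturbed by random rounding to
#' base 5; set `rounded_base5 = TRUE` to assert that property on input.
#'
#' @param path Path to a CSV file.
#' @param rounded_base5 If `TRUE`, additionally require every count to be a
#'   multiple of 5.
#' @return A validated tibble sorted by language, census year and age group.
#' @export
read_census_counts <- function(path, rounded_base5 = FALSE) {
  df <- readr::read_csv(path, col_types = readr::cols(
    language = readr::col_character(),
    census_year = readr::col_integer(),
    age_lo = readr::col_integer(),
    count = readr::col_double()
  ))
  validate_census_counts(df, rounded_base5 = rounded_base5)
}

#' @rdname read_census_counts
#' @param df A data frame of counts to validate in place.
#' @export
validate_census_counts <- function(df, rounded_base5 = FALSE) {
  need <- c("language", "census_year", "age_lo", "count")
  if (!all(need %in% names(df))) {
    rlang::abort(
      paste0("counts table must have columns ", paste(need, collapse = ", ")),
      class = "lingcast_schema_error"
    )
  }
  if (any(is.na(df$count)) || any(df$count < 0) || any(df$count != round(df$count))) {
    rlang::abort("counts must be non-negative integers",
      class = "lingcast_validation_error"
    )
  }
  if (rounded_base5 && any(df$count %% 5 != 0)) {
    rlang::abort("counts are declared random-rounded but are not multiples of 5",
      class = "lingcast_validation_error"
    )
  }
  ladder <- age_ladder()
  bad <- df |>
    dplyr::group_by(.data$language, .data$census_year) |>
    dplyr::summarise(
      ok = length(.data$age_lo) == length(ladder) &&
        setequal(.data$age_lo, ladder),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    rlang::abort(
      paste0(
        "incomplete age ladder for ",
        paste(bad$language, bad$census_year, sep = "/", collapse = ", ")
      ),
      class = "lingcast_schema_error"
    )
  }
  df |>
    dplyr::mutate(count = as.integer(.data$count)) |>
    dplyr::arrange(.data$language, .data$census_year, .data$age_lo) |>
    tibble::as_tibble()
}

#' @rdname read_census_counts
#' @export
write_census_counts <- function(df, path) {
  readr::write_csv(
    df[, c("language", "census_year", "age_lo", "count")], path
  )
  invisible(path)
}

#' Read a period life-table schedule of death probabilities
#'
#' Reads a CSV with columns `pop_group`, `period_start`, `age_lo`, `q5`,
#' where `q5` is the probability of dying within the five-year age interval
#' during the five-year period, conditional on being alive at its start.
#' The model assumes a maximum age at death of 100, so `q5` for the 95-99
#' interval is forced to 1 (with a warning if the input disagrees).
#'
#' @param path Path to a CSV file.
#' @param enforce_max_age Force `q5 = 1` for age group 95-99.
#' @return A validated tibble.
#' @export
read_mortality_schedule <- function(path, enforce_max_age = TRUE) {
  df <- readr::read_csv(path, col_types = readr::cols(
    pop_group = readr::col_character(),
    period_start = readr::col_integer(),
    age_lo = readr::col_integer(),
    q5 = readr::col_double()
  ))
  validate_mortality_schedule(df, enforce_max_age = enforce_max_age)
}

#' @rdname read_mortality_schedule
#' @param df A data frame to validate in place.
#' @export
validate_mortality_schedule <- function(df, enforce_max_age = TRUE) {
  need <- c("pop_group", "period_start", "age_lo", "q5")
  if (!all(need %in% names(df))) {
    rlang::abort(
      paste0("life table must have columns ", paste(need, collapse = ", ")),
      class = "lingcast_schema_error"
    )
  }
  if (any(is.na(df$q5)) || any(df$q5 < 0 | df$q5 > 1)) {
    rlang::abort("q5 must lie in [0, 1]", class = "lingcast_validation_error")
  }
  if (enforce_max_age) {
    off <- df$age_lo == 95L & df$q5 < 1
    if (any(off)) {
      rlang::warn(paste0(
        "q5 for age group 95-99 raised to 1 in ", sum(off),
        " row(s) to enforce the maximum age of 100"
      ))
      df$q5[off] <- 1
    }
  }
  df |>
    dplyr::arrange(.data$pop_group, .data$period_start, .data$age_lo) |>
    tibble::as_tibble()
}

#' @rdname read_mortality_schedule
#' @export
write_mortality_schedule <- function(df, path) {
  readr::write_csv(df[, c("pop_group", "period_start", "age_lo", "q5")], path)
  invisible(path)
}

#' Read an age-specific fertility-rate schedule
#'
#' Reads a CSV with columns `region`, `year`, `age_lo`, `asfr` (births per
#' person-year). Rates must cover exactly the reproductive age groups
#' 15-19 ... 45-49 for every (region, year).
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_fertility_schedule <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    region = readr::col_character(),
    year = readr::col_integer(),
    age_lo = readr::col_integer(),
    asfr = readr::col_double()
  ))
  validate_fertility_schedule(df)
}

#' @rdname read_fertility_schedule
#' @param df A data frame to validate in place.
#' @export
validate_fertility_schedule <- function(df) {
  need <- c("region", "year", "age_lo", "asfr")
  if (!all(need %in% names(df))) {
    rlang::abort(
      paste0("fertility table must have columns ", paste(need, collapse = ", ")),
      class = "lingcast_schema_error"
    )
  }
  if (any(is.na(df$asfr)) || any(df$asfr < 0)) {
    rlang::abort("asfr must be non-negative", class = "lingcast_validation_error")
  }
  repro <- seq.int(15L, 45L, 5L)
  bad <- df |>
    dplyr::group_by(.data$region, .data$year) |>
    dplyr::summarise(
      ok = length(.data$age_lo) == length(repro) && setequal(.data$age_lo, repro),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    rlang::abort(
      paste0(
        "fertility rates must cover exactly ages 15-49; offending: ",
        paste(bad$region, bad$year, sep = "/", collapse = ", ")
      ),
      class = "lingcast_schema_error"
    )
  }
  df |>
    dplyr::arrange(.data$region, .data$year, .data$age_lo) |>
    tibble::as_tibble()
}

#' @rdname read_fertility_schedule
#' @export
write_fertility_schedule <- function(df, path) {
  readr::write_csv(df[, c("region", "year", "age_lo", "asfr")], path)
  invisible(path)
}

#' Load a run configuration
#'
#' Reads a YAML mapping (or starts from nothing) and fills in the defaults:
#' 3000 Monte-Carlo replicates, the `freeze` transmission scenario (fitted
#' trend projected to 2046 and held constant thereafter), baseline year 2001,
#' horizon 2101, trend anchor year 2096.
#'
#' @param path Optional path to a YAML file; `NULL` uses defaults only.
#' @param ... Named overrides applied after the file.
#' @return A `run_config` list.
#' @export
load_config <- function(path = NULL, ...) {
  cfg <- list(
    languages = NULL,
    n_reps = 3000L,
    seed = 1L,
    scenario = "freeze",
    baseline_year = 2001L,
    horizon = 2101L,
    freeze_year = 2046L,
    anchor_year = 2096L,
    pop_group = NULL
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user) && !is.list(user)) {
      rlang::abort("config must be a YAML mapping", class = "lingcast_schema_error")
    }
    cfg[names(user)] <- user
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  validate_config(cfg)
}

validate_config <- function(cfg) {
  cfg$n_reps <- as.integer(cfg$n_reps)
  cfg$seed <- as.integer(cfg$seed)
  if (is.na(cfg$n_reps) || cfg$n_reps < 1L) {
    rlang::abort("n_reps must be a positive integer",
      class = "lingcast_validation_error"
    )
  }
  if (!cfg$scenario %in% c("freeze", "unlimited")) {
    rlang::abort('scenario must be "freeze" or "unlimited"',
      class = "lingcast_validation_error"
    )
  }
  ok <- cfg$baseline_year < cfg$freeze_year &&
    cfg$freeze_year < cfg$anchor_year &&
    cfg$anchor_year < cfg$horizon
  if (!ok) {
    rlang::abort(
      "need baseline_year < freeze_year < anchor_year < horizon",
      class = "lingcast_validation_error"
    )
  }
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat("  scenario:", x$scenario, " n_reps:", x$n_reps, " seed:", x$seed, "\n")
  cat(
    "  years:", x$baseline_year, "->", x$horizon,
    " (freeze", paste0(x$freeze_year, ","), "anchor", paste0(x$anchor_year, ")\n")
  )
  invisible(x)
}
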