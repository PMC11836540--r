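q_lower <- function(x, p) stats::quantile(x, p, type = 1, names = FALSE)

#' Summarise a projection ensemble
#'
#' Medians and 80% projection intervals (empirical quantiles 0.1 and 0.9,
#' inverse-empirical-CDF convention on the sorted integer counts) per year,
#' for the total population (`age_lo = NA`) and for each age group.
#'
#' @param ensemble A `speaker_ensemble` from [run_ensemble()].
#' @return An `ensemble_summary` tibble (`year`, `age_lo`, `median`, `q10`,
#'   `q90`).
#' @export
summarize_ensemble <- function(ensemble) {
  totals <- ensemble |>
    dplyr::summarise(
      count = sum(.data$count),
      .by = c("replicate", "year")
    ) |>
    dplyr::summarise(
      median = q_lower(.data$count, 0.5),
      q10 = q_lower(.data$count, 0.1),
      q90 = q_lower(.data$count, 0.9),
      .by = "year"
    ) |>
    dplyr::mutate(age_lo = NA_integer_, .after = "year")
  by_age <- ensemble |>
    dplyr::summarise(
      median = q_lower(.data$count, 0.5),
      q10 = q_lower(.data$count, 0.1),
      q90 = q_lower(.data$count, 0.9),
      .by = c("year", "age_lo")
    )
  out <- dplyr::bind_rows(totals, by_age) |>
    dplyr::arrange(.data$year, !is.na(.data$age_lo), .data$age_lo)
  stopifnot(all(out$q10 <= out$median & out$median <= out$q90))
  for (a in c("language", "n_reps", "seed", "scenario")) {
    attr(out, a) <- attr(ensemble, a)
  }
  class(out) <- c("ensemble_summary", class(out))
  out
}

band_filter <- function(df, band) {
  switch(band,
    all = df,
    under50 = df[df$age_lo < 50, ],
    under15 = df[df$age_lo < 15, ],
    rlang::abort('band must be one of "all", "under50", "under15"',
      class = "lingcast_validation_error"
    )
  )
}

#' Dormancy risk of a language
#'
#' The percentage of Monte-Carlo replicates in which the number of speakers
#' in the given age band (all ages, under 50, or under 15) is zero at each
#' projection year.
#'
#' @inheritParams summarize_ensemble
#' @param band `"all"`, `"under50"` or `"under15"`.
#' @param years Years to evaluate (default: all ensemble years).
#' @return A tibble (`year`, `risk`) with risks in percent.
#' @export
dormancy_risk <- function(ensemble, band = "all", years = NULL) {
  df <- band_filter(ensemble, band)
  out <- df |>
    dplyr::summarise(count = sum(.data$count), .by = c("replicate", "year")) |>
    dplyr::summarise(risk = 100 * mean(.data$count == 0), .by = "year") |>
    dplyr::arrange(.data$year)
  if (!is.null(years)) out <- out[out$year %in% years, ]
  out
}

#' First year at which a risk series reaches a threshold
#'
#' @param risks A tibble (`year`, `risk`) on the quinquennial grid.
#' @param threshold Risk threshold in percent (the first year with
#'   `risk >= threshold` is returned).
#' @return The year, or `NA` if the threshold is never reached.
#' @export
threshold_year <- function(risks, threshold) {
  hit <- risks$year[risks$risk >= threshold]
  if (length(hit) == 0) NA_integer_ else as.integer(min(hit))
}

#' Full dormancy summary of an ensemble
#'
#' Risks per year for the three age bands plus the years at which each
#' band's risk first reaches 10% and 50%. Asserts the structural
#' invariants: band ordering (all <= under50 <= under15 at every year) and
#' monotone growth over time for the absorbing bands (all ages, under 50).
#'
#' @inheritParams summarize_ensemble
#' @return A `dormancy_summary` tibble (`band`, `year`, `risk`), with the
#'   threshold years attached as attribute `thresholds` (tibble `band`,
#'   `threshold`, `year`).
#' @export
dormancy_summary <- function(ensemble) {
  bands <- c("all", "under50", "under15")
  risks <- purrr::map_dfr(bands, function(b) {
    dplyr::mutate(dormancy_risk(ensemble, b), band = b, .before = 1)
  })
  wide <- tidyr::pivot_wider(risks, names_from = "band", values_from = "risk")
  stopifnot(
    all(wide$all <= wide$under50 + 1e-9),
    all(wide$under50 <= wide$under15 + 1e-9),
    !is.unsorted(wide$all),
    !is.unsorted(wide$under50)
  )
  thresholds <- purrr::map_dfr(bands, function(b) {
    r <- risks[risks$band == b, ]
    tibble::tibble(
      band = b, threshold = c(10, 50),
      year = c(threshold_year(r, 10), threshold_year(r, 50))
    )
  })
  attr(risks, "thresholds") <- thresholds
  attr(risks, "language") <- attr(ensemble, "language")
  class(risks) <- c("dormancy_summary", class(risks))
  risks
}

#' Hindcast coverage of the 80% projection intervals
#'
#' Joins observed census counts onto the per-age-group projection intervals
#' of the overlapping years and records, cell by cell, whether the observed
#' count lies inside `[q10, q90]` (inclusive). The overall share of covered
#' cells -- near 80% when the observations are generated by the model's own
#' assumptions -- validates the calibration of the intervals.
#'
#' @param summary An `ensemble_summary` (or a tibble with `year`, `age_lo`,
#'   `q10`, `q90` rows per age group).
#' @param observed A census-count tibble for one language (`census_year`,
#'   `age_lo`, `count`).
#' @param years Years to validate (default: the overlap of both tables).
#' @return A tibble (`year`, `age_lo`, `count`, `q10`, `q90`, `covered`).
#' @export
validate_coverage <- function(summary, observed, years = NULL) {
  pred <- summary[!is.na(summary$age_lo), c("year", "age_lo", "q10", "q90")]
  obs <- observed |>
    dplyr::transmute(
      year = .data$census_year, age_lo = .data$age_lo, count = .data$count
    )
  if (is.null(years)) years <- intersect(unique(pred$year), unique(obs$year))
  if (length(years) == 0) {
    rlang::abort("no overlapping years between ensemble and observations",
      class = "lingcast_validation_error"
    )
  }
  dplyr::inner_join(
    obs[obs$year %in% years, ], pred[pred$year %in% years, ],
    by = c("year", "age_lo")
  ) |>
    dplyr::mutate(
      covered = .data$count >= .data$q10 & .data$count <= .data$q90
    ) |>
    dplyr::arrange(.data$year, .data$age_lo)
}

#' @rdname validate_coverage
#' @param coverage Cell-level output of `validate_coverage()` (rows from
#'   several languages may be pooled).
#' @param by Optional grouping column (`"year"` or `"age_lo"`).
#' @return `coverage_percent()`: overall (or per-group) percent of covered
#'   cells.
#' @export
coverage_percent <- function(coverage, by = NULL) {
  if (is.null(by)) {
    return(100 * mean(coverage$covered))
  }
  coverage |>
    dplyr::summarise(
      coverage = 100 * mean(.data$covered),
      n = dplyr::n(), .by = dplyr::all_of(by)
    )
}
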