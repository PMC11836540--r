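#' Look up five-year death probabilities
#'
#' Vectorised lookup of `q5` values in a mortality schedule. Missing
#' (group, period, age) combinations are an error unless `clamp_period`
#' allows periods before the schedule's first period to fall back on the
#' earliest available one (used only when burning in synthetic populations).
#'
#' @param schedule Mortality schedule tibble (`pop_group`, `period_start`,
#'   `age_lo`, `q5`).
#' @param pop_group Population group to use.
#' @param period_start Integer vector of period start years.
#' @param age_lo Integer vector of age-group lower bounds (recycled against
#'   `period_start`).
#' @param clamp_period Clamp periods before the schedule's first period.
#' @return Numeric vector of probabilities.
#' @export
q_lookup <- function(schedule, pop_group, period_start, age_lo,
                     clamp_period = FALSE) {
  sub <- schedule[schedule$pop_group == pop_group, ]
  if (nrow(sub) == 0) {
    rlang::abort(paste0("population group `", pop_group, "` not in schedule"),
      class = "lingcast_validation_error"
    )
  }
  n <- max(length(period_start), length(age_lo))
  period_start <- rep_len(period_start, n)
  age_lo <- rep_len(age_lo, n)
  if (clamp_period) {
    period_start <- pmax(period_start, min(sub$period_start))
  }
  idx <- match(
    paste(period_start, age_lo),
    paste(sub$period_start, sub$age_lo)
  )
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    rlang::abort(
      paste0(
        "mortality schedule has no entry for group `", pop_group,
        "`, period ", period_start[miss], ", age ", age_lo[miss]
      ),
      class = "lingcast_validation_error"
    )
  }
  sub$q5[idx]
}

#' Cumulative probability of dying between two grid years
#'
#' For a birth cohort alive in `from`, the probability of being dead by
#' `to` is the complement of the product of five-year survivorships across
#' the intervening periods; within each period the cohort is assigned the
#' age-group label it holds at the period's start (`period - birth_hi`).
#' Satisfies `M(a, a) = 0` and the composition identity
#' `1 - M(a, c) = (1 - M(a, b)) (1 - M(b, c))`.
#'
#' @param birth_hi Upper birth-year limit(s) of the cohort(s).
#' @param from,to Quinquennial grid years, `from <= to`.
#' @inheritParams q_lookup
#' @return Numeric vector of probabilities in `[0, 1]`, one per cohort.
#' @examples
#' # two five-year steps with q = 0.1 then 0.2: M = 1 - 0.9 * 0.8 = 0.28
#' @export
cumulative_death_probability <- function(birth_hi, from, to, schedule,
                                         pop_group, clamp_period = FALSE) {
  stopifnot(length(from) == 1, length(to) == 1, from <= to)
  if ((to - from) %% 5 != 0) {
    rlang::abort("`from` and `to` must lie on the same quinquennial grid",
      class = "lingcast_validation_error"
    )
  }
  if (from == to) {
    return(rep(0, length(birth_hi)))
  }
  steps <- seq.int(from, to - 5L, 5L)
  vapply(birth_hi, function(bh) {
    ages <- steps - bh
    if (any(ages < 0)) {
      rlang::abort(
        paste0("cohort ", bh - 4L, "-", bh, " not yet born in year ", from),
        class = "lingcast_validation_error"
      )
    }
    q <- q_lookup(schedule, pop_group, steps, ages, clamp_period = clamp_period)
    1 - prod(1 - q)
  }, numeric(1))
}

#' Recast census counts to the 2001 baseline year
#'
#' Identifies the birth cohort behind every closed age-group count, keeps
#' the cohorts 1917-1921 through 1997-2001, and converts each count observed
#' in census year t > 2001 into its mortality-free 2001 equivalent by
#' survivorship inversion: `estimate = count / (1 - M)`, where M is the
#' cumulative probability of dying between 2001 and t. Counts observed in
#' 2001 pass through unchanged, so each (language, cohort) yields up to five
#' comparable estimates of its 2001 size.
#'
#' @param counts Census count tibble (see [read_census_counts()]).
#' @inheritParams q_lookup
#' @return A tibble with columns `language`, `birth_lo`, `birth_hi`,
#'   `census_year`, `count`, `estimate`.
#' @export
recast_to_2001 <- function(counts, schedule, pop_group) {
  window <- baseline_cohorts()
  df <- counts |>
    dplyr::filter(.data$age_lo < 100L) |>
    dplyr::mutate(
      birth_lo = .data$census_year - .data$age_lo - 4L,
      birth_hi = .data$census_year - .data$age_lo
    ) |>
    dplyr::filter(.data$birth_lo %in% window$birth_lo)
  surv <- df |>
    dplyr::distinct(.data$birth_hi, .data$census_year) |>
    dplyr::rowwise() |>
    dplyr::mutate(M = cumulative_death_probability(
      .data$birth_hi, 2001L, .data$census_year, schedule, pop_group
    )) |>
    dplyr::ungroup()
  out <- df |>
    dplyr::left_join(surv, by = c("birth_hi", "census_year")) |>
    dplyr::mutate(estimate = .data$count / (1 - .data$M))
  if (any(!is.finite(out$estimate))) {
    bad <- out[!is.finite(out$estimate), ][1, ]
    rlang::abort(
      paste0(
        "cumulative mortality reaches 1; recast undefined for language `",
        bad$language, "`, cohort ", bad$birth_lo, "-", bad$birth_hi,
        ", census ", bad$census_year
      ),
      class = "lingcast_validation_error"
    )
  }
  out |>
    dplyr::select(
      "language", "birth_lo", "birth_hi", "census_year", "count", "estimate"
    ) |>
    dplyr::arrange(.data$language, .data$birth_lo, .data$census_year)
}

#' Recast a 2001 population backwards in time
#'
#' Converts cohort counts referenced to 2001 into the cohort sizes that
#' would have been alive at an earlier quinquennial year by inverting the
#' cumulative survivorship between that year and 2001:
#' `estimate = count / (1 - M(target, 2001))`. Cohorts not yet fully born at
#' the target year (`birth_hi > target_year`) are excluded.
#'
#' @param cohort_counts Tibble with columns `birth_lo`, `birth_hi`, `count`
#'   (2001-referenced cohort sizes; reals allowed).
#' @param target_year One of 1981, 1986, 1991, 1996 (any grid year < 2001
#'   is accepted).
#' @inheritParams q_lookup
#' @return A tibble with columns `birth_lo`, `birth_hi`, `age_lo` (age group
#'   at the target year) and `estimate`.
#' @export
recast_backward <- function(cohort_counts, schedule, pop_group, target_year) {
  stopifnot(target_year < 2001, (2001 - target_year) %% 5 == 0)
  df <- cohort_counts |>
    dplyr::filter(.data$birth_hi <= target_year)
  if (nrow(df) == 0) {
    return(tibble::tibble(
      birth_lo = integer(), birth_hi = integer(),
      age_lo = integer(), estimate = double()
    ))
  }
  M <- cumulative_death_probability(
    df$birth_hi, as.integer(target_year), 2001L, schedule, pop_group
  )
  if (any(M >= 1)) {
    rlang::abort("cumulative mortality reaches 1; backward recast undefined",
      class = "lingcast_validation_error"
    )
  }
  df |>
    dplyr::mutate(
      age_lo = as.integer(target_year - .data$birth_hi),
      estimate = .data$count / (1 - M)
    ) |>
    dplyr::select("birth_lo", "birth_hi", "age_lo", "estimate") |>
    dplyr::arrange(.data$age_lo)
}
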