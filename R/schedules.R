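#' Fit a log-normal age pattern to fertility rates
#'
#' Normalises the age-specific fertility rates over the reproductive groups
#' 15-19 ... 45-49 (averaging normalised profiles across regions when a
#' `region` column is present) and finds the log-normal location `m` and
#' scale `s` whose density, evaluated at the age-group midpoints
#' 17.5 ... 47.5 and renormalised over the same grid, is closest in least
#' squares to the observed profile.
#'
#' @param asfr A data frame with columns `age_lo`, `asfr` and optionally
#'   `region` (rates for a single calendar year), or a bare numeric vector
#'   of rates for ages 15-19 ... 45-49.
#' @return A `fertility_pattern` list with elements `m` and `s` (log-years).
#' @export
fit_lognormal_pattern <- function(asfr) {
  mids <- seq(17.5, 47.5, 5)
  if (is.numeric(asfr)) {
    profile <- asfr
  } else {
    df <- dplyr::arrange(asfr, .data$age_lo)
    if ("region" %in% names(df) && length(unique(df$region)) > 1) {
      profile <- df |>
        dplyr::group_by(.data$region) |>
        dplyr::mutate(p = .data$asfr / sum(.data$asfr)) |>
        dplyr::group_by(.data$age_lo) |>
        dplyr::summarise(p = mean(.data$p), .groups = "drop") |>
        dplyr::pull("p")
    } else {
      profile <- df$asfr
    }
  }
  if (length(profile) != length(mids)) {
    rlang::abort("need exactly the seven age groups 15-19 ... 45-49",
      class = "lingcast_schema_error"
    )
  }
  if (sum(profile) <= 0) {
    rlang::abort("all fertility rates are zero; cannot fit an age pattern",
      class = "lingcast_validation_error"
    )
  }
  p <- profile / sum(profile)
  lw <- log(mids)
  m0 <- sum(p * lw)
  s0 <- sqrt(max(sum(p * (lw - m0)^2), 1e-4))
  obj <- function(par) {
    d <- stats::dlnorm(mids, meanlog = par[1], sdlog = exp(par[2]))
    if (!all(is.finite(d)) || sum(d) == 0) {
      return(1e6)
    }
    sum((p - d / sum(d))^2)
  }
  fit <- stats::optim(c(m0, log(s0)), obj,
    method = "Nelder-Mead",
    control = list(reltol = 1e-14, maxit = 5000)
  )
  structure(
    list(m = fit$par[1], s = exp(fit$par[2])),
    class = "fertility_pattern"
  )
}

#' Interpolate the fertility age pattern between two anchor years
#'
#' The location and scale of the log-normal age pattern are modelled as
#' linear functions of calendar year between the 2001 and 2100 anchor fits
#' (and extrapolated linearly for 2101).
#'
#' @param p2001,p2100 `fertility_pattern` objects fitted to the anchor years.
#' @param year Calendar year (2001-2101).
#' @param anchor_years Calendar years of the two anchor patterns.
#' @return A `fertility_pattern` for `year`.
#' @export
interpolate_pattern <- function(p2001, p2100, year,
                                anchor_years = c(2001, 2100)) {
  w <- (year - anchor_years[1]) / diff(anchor_years)
  structure(
    list(
      m = p2001$m + w * (p2100$m - p2001$m),
      s = p2001$s + w * (p2100$s - p2001$s)
    ),
    class = "fertility_pattern"
  )
}

#' Allocate births to reproductive age groups
#'
#' Converts a log-normal age pattern into a proper weight vector over the
#' seven reproductive age groups: the density at each group midpoint,
#' normalised to sum to one. The weights decide which speakers a period's
#' births are attributed to in the projection.
#'
#' @param pattern A `fertility_pattern`.
#' @return A tibble (`age_lo`, `weight`) with weights summing to 1.
#' @export
birth_allocation_weights <- function(pattern) {
  age_lo <- seq(15L, 45L, 5L)
  mids <- age_lo + 2.5
  d <- stats::dlnorm(mids, meanlog = pattern$m, sdlog = pattern$s)
  if (sum(d) == 0) { # extreme s -> 0: all mass at the midpoint closest to exp(m)
    d <- as.numeric(seq_along(mids) == which.min(abs(log(mids) - pattern$m)))
  }
  tibble::tibble(age_lo = age_lo, weight = d / sum(d))
}

#' Survival of newborns over their first two and a half years
#'
#' Newborns enter the 0-4 age group only if they survive the first half of
#' the age interval; under a constant hazard within the interval this is the
#' square root of the five-year survivorship: `(1 - q5(0-4))^(1/2)`.
#'
#' @inheritParams q_lookup
#' @param period_start Period whose infant mortality applies.
#' @return A survival probability.
#' @export
infant_survival <- function(schedule, pop_group, period_start,
                            clamp_period = FALSE) {
  q <- q_lookup(schedule, pop_group, period_start, 0L, clamp_period = clamp_period)
  sqrt(1 - q)
}

#' Period life expectancy at birth from five-year death probabilities
#'
#' Standard abridged life-table closure on the q5 column (ages 0-4 through
#' 95-99, with the last interval closing the table at age 100): survivors
#' `l(x)` by cumulative survivorship and person-years by the trapezoidal
#' rule within each five-year interval.
#'
#' @param q5 Numeric vector of 20 five-year death probabilities.
#' @return Life expectancy at birth in years.
#' @export
life_expectancy <- function(q5) {
  stopifnot(length(q5) == 20)
  l <- cumprod(c(1, 1 - q5))
  sum(5 * (l[-length(l)] + l[-1]) / 2)
}

#' Synthetic period mortality schedule
#'
#' A Gompertz-Makeham life table generated from scratch: the senescent
#' hazard `a * exp(beta * x)` plus a background hazard, with the level `a`
#' calibrated per period (by root finding on the abridged life-table
#' closure) so that life expectancy at birth moves linearly from `e0_start`
#' in the first period to `e0_end` in the last. Values are realistic for a
#' contemporary population but synthetic; the `e0` targets are attached as
#' attribute `e0`.
#'
#' @param pop_group Name given to the population group.
#' @param periods Quinquennial period start years.
#' @param e0_start,e0_end Target life expectancies (years) in the first and
#'   last period.
#' @param beta Gompertz slope (per year of age).
#' @param makeham Background hazard (per year).
#' @return A mortality-schedule tibble (with `q5 = 1` at ages 95-99).
#' @export
synthetic_mortality_schedule <- function(pop_group = "synthetic",
                                         periods = seq(1981L, 2096L, 5L),
                                         e0_start = 72, e0_end = 86.5,
                                         beta = 0.09, makeham = 8e-4) {
  ages <- seq(0L, 95L, 5L)
  mids <- ages + 2.5
  e0_targets <- seq(e0_start, e0_end, length.out = length(periods))
  q_for_level <- function(loga) {
    h <- exp(loga) * exp(beta * mids) + makeham
    q <- 1 - exp(-5 * h)
    q[length(q)] <- 1
    q
  }
  rows <- purrr::map2_dfr(periods, e0_targets, function(p, e0) {
    f <- function(loga) life_expectancy(q_for_level(loga)) - e0
    loga <- stats::uniroot(f, c(-25, -2), tol = 1e-10)$root
    tibble::tibble(
      pop_group = pop_group, period_start = as.integer(p),
      age_lo = ages, q5 = q_for_level(loga)
    )
  })
  attr(rows, "e0") <- tibble::tibble(
    period_start = as.integer(periods), e0 = e0_targets
  )
  rows
}

#' Synthetic age-specific fertility schedules
#'
#' Four synthetic regions with 2001 total fertility rates between 3 and 4
#' and log-normal age patterns, plus their 2100 counterparts (lower TFR,
#' later and more concentrated childbearing). Rates are exact log-normal
#' profiles, so pattern fitting on them is self-consistent.
#'
#' @return A fertility-schedule tibble (`region`, `year`, `age_lo`, `asfr`).
#' @export
synthetic_fertility_schedule <- function() {
  regions <- tibble::tibble(
    region = paste0("region_", letters[1:4]),
    tfr2001 = c(3.1, 3.4, 3.6, 3.9),
    m2001 = c(3.27, 3.30, 3.32, 3.29),
    s2001 = c(0.27, 0.26, 0.28, 0.25),
    tfr2100 = c(1.6, 1.7, 1.8, 1.9),
    m2100 = c(3.43, 3.45, 3.44, 3.46),
    s2100 = c(0.22, 0.21, 0.23, 0.22)
  )
  age_lo <- seq(15L, 45L, 5L)
  mids <- age_lo + 2.5
  one <- function(region, year, tfr, m, s) {
    d <- stats::dlnorm(mids, m, s)
    w <- d / sum(d)
    tibble::tibble(
      region = region, year = as.integer(year),
      age_lo = age_lo, asfr = tfr * w / 5
    )
  }
  purrr::pmap_dfr(regions, function(region, tfr2001, m2001, s2001,
                                    tfr2100, m2100, s2100) {
    dplyr::bind_rows(
      one(region, 2001, tfr2001, m2001, s2001),
      one(region, 2100, tfr2100, m2100, s2100)
    )
  })
}
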