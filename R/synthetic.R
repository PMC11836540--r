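#' Specify a synthetic speaker-population scenario
#'
#' A scenario bundles the ground truth needed to emulate census data for
#' one language: an initial age pyramid, a mortality schedule population
#' group, a known transmission (xTFR) trajectory, and the census error
#' model -- negative binomial overdispersion around the true counts
#' (variance `phi * mean^2`), optional per-census undercount factors, and
#' random rounding of published counts to base 5.
#'
#' @param language Language identifier.
#' @param init Tibble (`age_lo`, `count`) at `init_year` (reals allowed).
#' @param init_year Quinquennial year of the initial pyramid; years before
#'   1981 give the population a burn-in so its 1981 structure is consistent
#'   with the trajectory.
#' @param xtfr_trajectory Tibble (`year`, `xtfr`) covering at least
#'   1981-2016; years outside the range are clamped to the nearest value.
#' @param phi True overdispersion of census counts (variance / mean^2).
#' @param undercount Optional tibble (`census_year`, `factor`) of
#'   multiplicative enumeration errors, factors in (0, 2].
#' @param round_base5 Apply Statistics-Canada-style unbiased random
#'   rounding to base 5 to published counts.
#' @param noise `"nbinom"` (quadratic mean-variance) or `"poisson"`
#'   (misspecification switch for robustness tests).
#' @param pop_group Mortality-schedule population group.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(language, init, init_year, xtfr_trajectory,
                          phi = 0.005, undercount = NULL,
                          round_base5 = TRUE, noise = c("nbinom", "poisson"),
                          pop_group = "synthetic") {
  noise <- match.arg(noise)
  stopifnot(phi > 0, init_year %% 5 == 1 || init_year %% 5 == 2001 %% 5)
  if (!is.null(undercount)) {
    stopifnot(all(undercount$factor > 0), all(undercount$factor <= 2))
  }
  structure(
    list(
      language = language, init = init, init_year = as.integer(init_year),
      xtfr_trajectory = xtfr_trajectory, phi = phi,
      undercount = undercount, round_base5 = round_base5,
      noise = noise, pop_group = pop_group
    ),
    class = "scenario_spec"
  )
}

#' @rdname scenario_spec
#' @param spec A `scenario_spec`.
#' @param census_year Census year to contaminate.
#' @param factor Multiplicative undercount/overcount factor in (0, 2].
#' @export
with_undercount <- function(spec, census_year, factor) {
  spec$undercount <- dplyr::bind_rows(
    spec$undercount,
    tibble::tibble(census_year = as.integer(census_year), factor = factor)
  )
  spec
}

clamp_trajectory <- function(trajectory, years) {
  yr <- pmin(pmax(years, min(trajectory$year)), max(trajectory$year))
  idx <- vapply(yr, function(y) {
    which.min(abs(trajectory$year - y))
  }, integer(1))
  tibble::tibble(year = as.integer(years), xtfr = trajectory$xtfr[idx])
}

#' Ground-truth population of a synthetic scenario
#'
#' Runs the deterministic expectation recursion from the scenario's initial
#' pyramid to 2021 under the true mortality schedule and true xTFR
#' trajectory (values clamped outside the trajectory's range; mortality
#' periods before the schedule's first period fall back on it). Returns the
#' real-valued true counts for the census window 1981-2021.
#'
#' @inheritParams with_undercount
#' @param schedule Mortality schedule containing the scenario's
#'   `pop_group`.
#' @param fertility Fertility schedule with anchor years 2001 and 2100.
#' @return A tibble (`year`, `age_lo`, `count`) for years 1981-2021.
#' @export
make_true_population <- function(spec, schedule, fertility) {
  years <- seq(spec$init_year, 2021L, 5L)
  path <- clamp_trajectory(spec$xtfr_trajectory, years[-length(years)])
  truth <- expectation_recursion(
    spec$init, path, schedule, spec$pop_group, fertility,
    years = years, clamp_period = TRUE
  )
  truth[truth$year >= 1981L, ]
}

#' Unbiased random rounding to base 5
#'
#' Disclosure-control perturbation used on published census counts: a count
#' with remainder r modulo 5 is rounded up with probability r/5 and down
#' otherwise, so the rounding is unbiased.
#'
#' @param x Non-negative counts.
#' @return Integer multiples of 5.
#' @export
random_round5 <- function(x) {
  r <- x %% 5
  up <- stats::runif(length(x)) < r / 5
  as.integer(x - r + 5 * up)
}

#' Simulate census observations from a true population
#'
#' Draws the published count of every (census year, age group) cell from
#' the scenario's error model: negative binomial with mean equal to the
#' true count (times any undercount factor) and variance `phi * mean^2`
#' (Poisson when that variance does not exceed the mean, or under the
#' `"poisson"` misspecification switch), followed by unbiased random
#' rounding to base 5 when enabled. The open-ended 100+ group is published
#' as zero (the truth caps age at 100).
#'
#' @param truth Output of [make_true_population()].
#' @inheritParams with_undercount
#' @return A census-count tibble for the years 2001-2021.
#' @export
simulate_censuses <- function(truth, spec) {
  years <- seq(2001L, 2021L, 5L)
  out <- purrr::map_dfr(years, function(y) {
    cells <- truth[truth$year == y, ]
    fac <- 1
    if (!is.null(spec$undercount) && y %in% spec$undercount$census_year) {
      fac <- spec$undercount$factor[match(y, spec$undercount$census_year)]
    }
    mu <- cells$count * fac
    n <- draw_census_noise(mu, spec$phi, spec$noise)
    if (spec$round_base5) n <- random_round5(n)
    tibble::tibble(
      language = spec$language, census_year = y,
      age_lo = c(cells$age_lo, 100L), count = c(n, 0L)
    )
  })
  validate_census_counts(out, rounded_base5 = spec$round_base5)
}

draw_census_noise <- function(mu, phi, noise) {
  n <- integer(length(mu))
  pos <- mu > 0
  if (!any(pos)) {
    return(n)
  }
  m <- mu[pos]
  if (noise == "poisson") {
    n[pos] <- stats::rpois(sum(pos), m)
  } else {
    v <- phi * m^2
    nb <- v > m
    draw <- integer(length(m))
    if (any(nb)) {
      draw[nb] <- stats::rnbinom(sum(nb), size = m[nb]^2 / (v[nb] - m[nb]), mu = m[nb])
    }
    if (any(!nb)) draw[!nb] <- stats::rpois(sum(!nb), m[!nb])
    n[pos] <- draw
  }
  n
}

flat_pyramid <- function(per_group = 100) {
  tibble::tibble(age_lo = seq(0L, 95L, 5L), count = per_group)
}

# scale the initial pyramid so the true 2001 total hits `target`
# (the expectation recursion is linear in the initial counts)
calibrate_init <- function(spec, target_2001, schedule, fertility) {
  truth <- make_true_population(spec, schedule, fertility)
  tot <- sum(truth$count[truth$year == 2001L])
  spec$init$count <- spec$init$count * target_2001 / tot
  spec
}

#' Named synthetic scenario presets
#'
#' Four archetypes spanning the qualitative regimes of endangered-language
#' demography, each burnt in from 1941 so that the 1981 age structure is
#' dynamically consistent with its transmission trajectory, and each
#' calibrated (exactly, by linearity of the recursion) to its nominal true
#' 2001 size:
#' \describe{
#'   \item{large_growing}{~6000 speakers, transmission above replacement.}
#'   \item{large_declining}{~80000 speakers, transmission sliding below 1.}
#'   \item{small_declining}{~700 speakers, transmission collapsing to 0 by
#'     1991 (no true speakers under 10 by 2001).}
#'   \item{tiny_near_dormant}{~120 speakers, marginal transmission.}
#' }
#'
#' @param schedule,fertility Schedules used for calibration (defaults: the
#'   synthetic ones).
#' @return A named list of `scenario_spec` objects.
#' @export
scenario_presets <- function(schedule = synthetic_mortality_schedule(),
                             fertility = synthetic_fertility_schedule()) {
  grid <- seq(1981L, 2016L, 5L)
  traj <- function(v) tibble::tibble(year = grid, xtfr = v)
  base <- list(
    large_growing = list(
      xtfr = traj(seq(1.45, 1.20, length.out = 8)), target = 6000
    ),
    large_declining = list(
      xtfr = traj(seq(1.10, 0.80, length.out = 8)), target = 80000
    ),
    small_declining = list(
      xtfr = traj(c(0.5, 0.2, 0, 0, 0, 0, 0, 0)), target = 700
    ),
    tiny_near_dormant = list(
      xtfr = traj(c(0.35, 0.30, 0.25, 0.20, 0.15, 0.12, 0.10, 0.10)),
      target = 120
    )
  )
  out <- purrr::imap(base, function(b, nm) {
    spec <- scenario_spec(
      language = nm, init = flat_pyramid(), init_year = 1941L,
      xtfr_trajectory = b$xtfr
    )
    calibrate_init(spec, b$target, schedule, fertility)
  })
  out
}

#' @rdname scenario_presets
#' @param n Number of languages in the bundle.
#' @return `scenario_bundle()`: a list of `n` specs cycling through the
#'   four archetype trajectories with true 2001 sizes log-spaced between
#'   150 and 60000.
#' @export
scenario_bundle <- function(n = 27,
                            schedule = synthetic_mortality_schedule(),
                            fertility = synthetic_fertility_schedule()) {
  presets <- scenario_presets(schedule, fertility)
  targets <- exp(seq(log(150), log(60000), length.out = n))
  out <- lapply(seq_len(n), function(i) {
    arch <- presets[[(i - 1) %% length(presets) + 1]]
    spec <- arch
    spec$language <- sprintf("lang_%02d", i)
    calibrate_init(spec, targets[i], schedule, fertility)
  })
  names(out) <- vapply(out, function(s) s$language, character(1))
  out
}
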