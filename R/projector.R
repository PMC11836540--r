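#' One five-year step of the individual-based projection
#'
#' Advances a population state (counts in age groups 0-4 ... 95-99) by five
#' years. Every individual independently survives their age group's
#' five-year death probability -- realised in aggregate as binomial draws --
#' and survivors move up one age group; the 95-99 group always dies
#' (maximum age 100). Expected births are
#' `B = xtfr * sum(count(a) * weight(a))` over the reproductive groups, so
#' an individual passing through all reproductive ages accumulates `xtfr`
#' expected children; realised births are Poisson, and newborns enter the
#' 0-4 group if they survive their first two and a half years (binomial
#' thinning by `infant_surv`).
#'
#' @param state Tibble (`age_lo`, `count`) covering ages 0-95 by 5.
#' @param xtfr Mean number of child speakers per adult speaker in the step.
#' @param q5 Numeric vector of 20 death probabilities (ages 0-4 ... 95-99);
#'   the final entry is forced to 1.
#' @param weights Tibble (`age_lo`, `weight`) over ages 15-45 summing to 1
#'   (see [birth_allocation_weights()]).
#' @param infant_surv Probability that a newborn survives into the 0-4 group.
#' @return The next state tibble, five years on.
#' @export
project_step <- function(state, xtfr, q5, weights, infant_surv) {
  ages <- seq(0L, 95L, 5L)
  counts <- state$count[match(ages, state$age_lo)]
  counts[is.na(counts)] <- 0L
  w <- weights$weight[order(weights$age_lo)]
  nxt <- step_stochastic(as.integer(counts), q5, xtfr, w, infant_surv)
  tibble::tibble(age_lo = ages, count = nxt)
}

# fast inner step on bare vectors; counts length 20, q5 length 20,
# w length 7 (ages 15-45)
step_stochastic <- function(counts, q5, xtfr, w, infant_surv) {
  q5[20] <- 1
  surv <- stats::rbinom(20L, counts, 1 - q5)
  nxt <- c(0L, surv[1:19])
  B <- xtfr * sum(counts[4:10] * w)
  births <- stats::rpois(1L, B)
  nxt[1] <- stats::rbinom(1L, births, infant_surv)
  nxt
}

step_expected <- function(counts, q5, xtfr, w, infant_surv) {
  q5[20] <- 1
  surv <- counts * (1 - q5)
  nxt <- c(0, surv[1:19])
  nxt[1] <- xtfr * sum(counts[4:10] * w) * infant_surv
  nxt
}

# per-period projection inputs: survival matrix, weights, infant survival
projection_schedules <- function(schedule, pop_group, fertility,
                                 periods, clamp_period = FALSE) {
  ages <- seq(0L, 95L, 5L)
  p2001 <- fit_lognormal_pattern(fertility[fertility$year == 2001, ])
  p2100 <- fit_lognormal_pattern(fertility[fertility$year == 2100, ])
  q_mat <- vapply(periods, function(p) {
    q <- q_lookup(schedule, pop_group, p, ages, clamp_period = clamp_period)
    q[20] <- 1
    q
  }, numeric(20))
  w_mat <- vapply(periods, function(p) {
    birth_allocation_weights(interpolate_pattern(p2001, p2100, p))$weight
  }, numeric(7))
  s_inf <- vapply(periods, function(p) {
    infant_survival(schedule, pop_group, p, clamp_period = clamp_period)
  }, numeric(1))
  list(periods = periods, q = q_mat, w = w_mat, s_inf = s_inf)
}

path_lookup <- function(xtfr_path, periods) {
  v <- xtfr_path$xtfr[match(periods, xtfr_path$year)]
  if (anyNA(v)) {
    rlang::abort(
      paste0(
        "xTFR path is missing years: ",
        paste(periods[is.na(v)], collapse = ", ")
      ),
      class = "lingcast_validation_error"
    )
  }
  v
}

init_counts_vector <- function(init) {
  ages <- seq(0L, 95L, 5L)
  counts <- init$count[match(ages, init$age_lo)]
  counts[is.na(counts)] <- 0
  counts
}

#' Run one stochastic trajectory 2001-2101
#'
#' Applies [project_step()] iteratively over the periods 2001-2006 ...
#' 2096-2101 starting from a baseline draw. The xTFR path must provide a
#' value for every period start year 2001, 2006, ..., 2096 (the 2001 value
#' is the one estimated from the draw itself; later values come from the
#' projected trend).
#'
#' @param draw Tibble (`age_lo`, `count`): the 2001 population.
#' @param xtfr_path Tibble (`year`, `xtfr`) covering 2001-2096.
#' @inheritParams q_lookup
#' @param fertility Fertility-schedule tibble with anchor years 2001 and 2100.
#' @param years Quinquennial state years (default 2001-2101).
#' @return A tibble (`year`, `age_lo`, `count`) with one state per year.
#' @export
run_trajectory <- function(draw, xtfr_path, schedule, pop_group, fertility,
                           years = seq(2001L, 2101L, 5L)) {
  periods <- years[-length(years)]
  sch <- projection_schedules(schedule, pop_group, fertility, periods)
  xt <- path_lookup(xtfr_path, periods)
  counts <- as.integer(round(init_counts_vector(draw)))
  states <- matrix(0L, nrow = 20L, ncol = length(years))
  states[, 1] <- counts
  for (i in seq_along(periods)) {
    counts <- step_stochastic(counts, sch$q[, i], xt[i], sch$w[, i], sch$s_inf[i])
    states[, i + 1] <- counts
  }
  tibble::tibble(
    year = rep(as.integer(years), each = 20L),
    age_lo = rep(seq(0L, 95L, 5L), length(years)),
    count = as.integer(states)
  )
}

#' Deterministic expectation recursion (projection oracle)
#'
#' The exact expectation of the stochastic projection: survival and birth
#' rates applied as real-valued multiplications instead of random draws.
#' Used as an independent oracle for the Monte-Carlo engine and as the
#' ground-truth generator for synthetic populations.
#'
#' @inheritParams run_trajectory
#' @param clamp_period Clamp look-ups before the schedule's first period
#'   (burn-in use).
#' @return A tibble (`year`, `age_lo`, `count`) with real-valued counts.
#' @export
expectation_recursion <- function(draw, xtfr_path, schedule, pop_group,
                                  fertility, years = seq(2001L, 2101L, 5L),
                                  clamp_period = FALSE) {
  periods <- years[-length(years)]
  sch <- projection_schedules(schedule, pop_group, fertility, periods,
    clamp_period = clamp_period
  )
  xt <- path_lookup(xtfr_path, periods)
  counts <- init_counts_vector(draw)
  states <- matrix(0, nrow = 20L, ncol = length(years))
  states[, 1] <- counts
  for (i in seq_along(periods)) {
    counts <- step_expected(counts, sch$q[, i], xt[i], sch$w[, i], sch$s_inf[i])
    states[, i + 1] <- counts
  }
  tibble::tibble(
    year = rep(as.integer(years), each = 20L),
    age_lo = rep(seq(0L, 95L, 5L), length(years)),
    count = as.vector(states)
  )
}

# precomputed backward-recast geometry for the 1981-1996 xTFR years:
# per year, the included cohort indices (in age_lo order), their
# survivorship to 2001 and the C / W / 25-34 masks at that year
backcast_geometry <- function(cohorts, schedule, pop_group) {
  lapply(stats::setNames(nm = seq(1981L, 1996L, 5L)), function(y) {
    inc <- which(cohorts$birth_hi <= y)
    M <- cumulative_death_probability(
      cohorts$birth_hi[inc], y, 2001L, schedule, pop_group
    )
    age <- y - cohorts$birth_hi[inc]
    list(
      idx = inc, surv = 1 - M,
      mask_c = age < 5,
      mask_w = age >= 15 & age < 50,
      mask_pi = age >= 25 & age < 35
    )
  })
}

xtfr_from_masks <- function(est, g) {
  W <- sum(est[g$mask_w])
  if (W == 0) {
    return(0)
  }
  C <- sum(est[g$mask_c])
  pi2534 <- sum(est[g$mask_pi]) / W
  max(0, (10.65 - 12.55 * pi2534) * C / W)
}

#' Run the Monte-Carlo projection ensemble for one language
#'
#' Each replicate redraws the whole chain: a fresh baseline realisation
#' (one t-distributed total plus 17 cohort counts), a fresh 1981-2001 xTFR
#' series computed from that realisation by backward recast, a freshly
#' fitted and extrapolated transmission trend, and a fresh stochastic
#' trajectory 2001-2101. Replicate sub-seeds are drawn once from the master
#' seed, so any replicate can be reproduced in isolation.
#'
#' @param baseline A `speaker_baseline` object.
#' @inheritParams run_trajectory
#' @param config A [load_config()] list (uses `n_reps`, `scenario`,
#'   `freeze_year`, `anchor_year`).
#' @param seed Master seed for this ensemble (defaults to `config$seed`).
#' @return A `speaker_ensemble` tibble (`replicate`, `year`, `age_lo`,
#'   `count`) with attributes `language`, `n_reps`, `seed`, `scenario`.
#' @export
run_ensemble <- function(baseline, schedule, pop_group, fertility,
                         config = load_config(), seed = config$seed) {
  n_reps <- config$n_reps
  years <- seq(config$baseline_year, config$horizon, 5L)
  periods <- years[-length(years)]
  sch <- projection_schedules(schedule, pop_group, fertility, periods)
  cohorts <- dplyr::arrange(baseline$cohorts, .data$age_lo)
  geom <- backcast_geometry(cohorts, schedule, pop_group)
  proj_years <- seq(config$baseline_year + 5L, config$anchor_year, 5L)

  set.seed(seed)
  subseeds <- sample.int(2147483646L, n_reps)
  states <- array(0L, dim = c(20L, length(years), n_reps))
  series_years <- seq(1981L, 2001L, 5L)

  for (r in seq_len(n_reps)) {
    set.seed(subseeds[r])
    total <- draw_total(baseline$total)
    raw <- draw_cohort_counts(cohorts)
    if (sum(raw) == 0) {
      raw <- if (sum(cohorts$mu) > 0) cohorts$mu else rep(1, nrow(cohorts))
    }
    counts17 <- largest_remainder(raw, total)

    # xTFR series 1981-2001 from this realisation
    xtfr <- numeric(5)
    for (k in 1:4) {
      g <- geom[[k]]
      est <- counts17[g$idx] / g$surv
      xtfr[k] <- xtfr_from_masks(est, g)
    }
    a01 <- cohorts$age_lo
    g01 <- list(
      mask_c = a01 < 5, mask_w = a01 >= 15 & a01 < 50,
      mask_pi = a01 >= 25 & a01 < 35
    )
    xtfr[5] <- xtfr_from_masks(counts17, g01)

    series <- tibble::tibble(year = series_years, xtfr = xtfr)
    trend <- fit_trend(series, anchor_year = config$anchor_year)
    path <- project_xtfr(trend,
      scenario = config$scenario,
      years = proj_years, freeze_year = config$freeze_year
    )
    xt <- c(xtfr[5], path$xtfr)[match(periods, c(2001L, proj_years))]

    counts <- c(counts17, integer(20L - length(counts17)))
    states[, 1, r] <- counts
    for (i in seq_along(periods)) {
      counts <- step_stochastic(
        counts, sch$q[, i], xt[i], sch$w[, i], sch$s_inf[i]
      )
      states[, i + 1, r] <- counts
    }
  }

  out <- tibble::tibble(
    replicate = rep(seq_len(n_reps), each = 20L * length(years)),
    year = rep(rep(as.integer(years), each = 20L), n_reps),
    age_lo = rep(seq(0L, 95L, 5L), length(years) * n_reps),
    count = as.integer(states)
  )
  attr(out, "language") <- baseline$language
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- seed
  attr(out, "scenario") <- config$scenario
  class(out) <- c("speaker_ensemble", class(out))
  out
}
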