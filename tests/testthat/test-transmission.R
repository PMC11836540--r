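age_vec <- function(...) {
  v <- c(...)
  tibble::tibble(age_lo = as.integer(names(v)), count = as.numeric(v))
}

test_that("the xTFR formula evaluates as printed and scales correctly", {
  # C = 100, W = 1000 over 15-49, pi(25-34) = 0.2:
  # (10.65 - 12.55 * 0.2) * 0.1 = 0.814
  v <- age_vec(`0` = 100, `15` = 400, `25` = 100, `30` = 100, `40` = 400)
  expect_equal(compute_xtfr(v), 0.814, tolerance = 1e-12)

  # the bracket's root: pi = 10.65 / 12.55 makes the value 0 regardless of C/W
  root <- 10.65 / 12.55
  v2 <- age_vec(`0` = 500, `25` = root * 1000, `45` = (1 - root) * 1000)
  expect_equal(compute_xtfr(v2), 0, tolerance = 1e-12)

  # linear in C; invariant to uniform scaling of the pyramid
  v3 <- v
  v3$count[v3$age_lo == 0] <- 200
  expect_equal(compute_xtfr(v3), 2 * compute_xtfr(v))
  v4 <- dplyr::mutate(v, count = count * 7.3)
  expect_equal(compute_xtfr(v4), compute_xtfr(v))

  expect_error(compute_xtfr(age_vec(`0` = 10)), class = "lingcast_validation_error")
})

test_that("a stationary pyramid without mortality yields five equal xTFR values", {
  draw <- baseline_cohorts() |>
    dplyr::rename(age_lo = "age_lo_2001") |>
    dplyr::mutate(count = 100)
  s <- estimate_xtfr_series(draw, constant_schedule(q = 0), "toy")
  expect_equal(s$year, seq(1981L, 2001L, 5L))
  expect_equal(s$xtfr, rep(s$xtfr[1], 5), tolerance = 1e-12)

  # no speakers under 35 in 2001: the 2001 estimate is 0 (C = 0)
  old <- dplyr::mutate(draw, count = ifelse(age_lo < 35, 0, 100))
  s2 <- estimate_xtfr_series(old, constant_schedule(q = 0), "toy")
  expect_equal(s2$xtfr[s2$year == 2001], 0)
})

test_that("xTFR series on a two-cohort pyramid matches the survivorship oracle", {
  # cohorts 1977-1981 (ages 20-24 in 2001) and 1942-1946 (ages 55-59 in 2001)
  draw <- tibble::tibble(
    birth_lo = c(1977L, 1942L), birth_hi = c(1981L, 1946L),
    age_lo = c(20L, 55L), count = c(90, 120)
  )
  sched <- constant_schedule(q = 0)
  sched$q5[sched$age_lo < 95] <- 0.1
  s <- estimate_xtfr_series(draw, sched, "toy", quiet = TRUE)
  # hand oracle at 1981: ages 0-4 (C) and 35-39 (W, outside 25-34, pi = 0);
  # both estimates inflate by 1/0.9^4, which cancels in C/W
  expect_equal(
    s$xtfr[s$year == 1981],
    10.65 * (90 / 0.9^4) / (120 / 0.9^4),
    tolerance = 1e-12
  )
  # at 1986 the 1977-1981 cohort is 5-9: C = 0, so xTFR = 0
  expect_equal(s$xtfr[s$year == 1986], 0)
})

test_that("trend classification uses the sign of the least-squares slope", {
  yrs <- seq(1981L, 2001L, 5L)
  expect_equal(
    classify_trend(tibble::tibble(year = yrs, xtfr = c(1, .8, .6, .4, .2))),
    "decreasing"
  )
  expect_equal(
    classify_trend(tibble::tibble(year = yrs, xtfr = c(.2, .3, .4, .5, .6))),
    "non-decreasing"
  )
  expect_equal(
    classify_trend(tibble::tibble(year = yrs, xtfr = rep(.5, 5))),
    "non-decreasing"
  )
})

test_that("an exact exponential series is recovered to numerical precision", {
  yrs <- seq(1981L, 2001L, 5L)
  a <- -0.3
  b <- -0.02
  series <- tibble::tibble(year = yrs, xtfr = exp(a + b * (yrs - 2001)))
  tr <- fit_trend(series)
  expect_equal(tr$form, "log-linear-decline")
  expect_equal(tr$intercept, a, tolerance = 1e-9)
  expect_equal(tr$slope, b, tolerance = 1e-9)
  # projection continues the same exponential
  path <- project_xtfr(tr, "unlimited")
  expect_equal(path$xtfr, exp(a + b * (path$year - 2001)), tolerance = 1e-9)
  expect_true(all(diff(path$xtfr) < 0))
})

test_that("non-decreasing trends pass through the 2096 anchor at the observed mean", {
  yrs <- seq(1981L, 2001L, 5L)
  series <- tibble::tibble(year = yrs, xtfr = c(0.5, 0.62, 0.7, 0.81, 0.9))
  tr <- fit_trend(series)
  expect_equal(tr$form, "log-year-anchored")
  path <- project_xtfr(tr, "unlimited")
  expect_equal(path$xtfr[path$year == 2096], mean(series$xtfr), tolerance = 1e-9)

  # a constant series projects flat at its own value in both scenarios
  const <- tibble::tibble(year = yrs, xtfr = rep(0.7, 5))
  trc <- fit_trend(const)
  expect_equal(project_xtfr(trc, "freeze")$xtfr, rep(0.7, 19), tolerance = 1e-9)
  expect_equal(project_xtfr(trc, "unlimited")$xtfr, rep(0.7, 19), tolerance = 1e-9)
})

test_that("freeze and unlimited agree through 2046, then freeze holds constant", {
  yrs <- seq(1981L, 2001L, 5L)
  series <- tibble::tibble(year = yrs, xtfr = exp(-0.2 - 0.015 * (yrs - 2001)))
  tr <- fit_trend(series)
  fr <- project_xtfr(tr, "freeze")
  un <- project_xtfr(tr, "unlimited")
  expect_equal(fr$xtfr[fr$year <= 2046], un$xtfr[un$year <= 2046])
  expect_equal(
    fr$xtfr[fr$year > 2046],
    rep(fr$xtfr[fr$year == 2046], sum(fr$year > 2046))
  )
  expect_true(all(un$xtfr[un$year > 2046] < fr$xtfr[fr$year > 2046]))

  # an all-zero series yields the degenerate all-zero path
  zero <- fit_trend(tibble::tibble(year = yrs, xtfr = rep(0, 5)))
  expect_equal(zero$form, "zero")
  expect_equal(project_xtfr(zero, "freeze")$xtfr, rep(0, 19))
})

test_that("a stationary population at xTFR around one renews itself", {
  # expectation recursion: no mortality below the maximum age, uniform
  # allocation weights, xtfr = 1; a flat pyramid should drift < 2% per step
  counts <- rep(100, 20)
  w <- rep(1 / 7, 7)
  tot0 <- sum(counts)
  for (step in 1:5) {
    surv <- counts
    nxt <- c(0, surv[1:19])
    nxt[1] <- 1 * sum(counts[4:10] * w)
    counts <- nxt
  }
  expect_lt(abs(sum(counts) - tot0) / tot0, 0.02 * 5)
})

test_that("a value-decreasing series with a growing log fit stays bounded", {
  # big early value, floor-compressed middle, slight late rise: the value
  # slope is negative but the log-linear fit grows; the bounded anchored
  # model must take over rather than an exploding exponential
  yrs <- seq(1981L, 2001L, 5L)
  series <- tibble::tibble(year = yrs, xtfr = c(2.0, 0.004, 0.003, 0.2, 0.6))
  expect_equal(classify_trend(series), "decreasing")
  tr <- fit_trend(series)
  expect_equal(tr$form, "log-year-anchored")
  path <- project_xtfr(tr, "unlimited")
  expect_lte(max(path$xtfr), max(series$xtfr) + 1)
})
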