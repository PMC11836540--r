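test_that("age groups map to the correct birth cohorts across censuses", {
  expect_equal(assign_cohort(0L, 2001L)$birth_lo, 1997L)
  expect_equal(assign_cohort(0L, 2001L)$birth_hi, 2001L)
  # the same cohort reappears five years older at each census
  aliases <- assign_cohort(seq(0L, 20L, 5L), seq(2001L, 2021L, 5L))
  expect_true(all(aliases$birth_lo == 1997L & aliases$birth_hi == 2001L))
  expect_error(assign_cohort(100L, 2021L), class = "lingcast_validation_error")
})

test_that("cumulative death probabilities multiply survivorships stepwise", {
  sched <- constant_schedule(q = 0)
  sched$q5[sched$period_start == 2001L & sched$age_lo == 0L] <- 0.1
  sched$q5[sched$period_start == 2006L & sched$age_lo == 5L] <- 0.2

  # M(a, a) = 0
  expect_equal(cumulative_death_probability(2001L, 2001, 2001, sched, "toy"), 0)
  # single step equals its q
  expect_equal(cumulative_death_probability(2001L, 2001, 2006, sched, "toy"), 0.1)
  # two steps: 1 - 0.9 * 0.8 = 0.28
  expect_equal(cumulative_death_probability(2001L, 2001, 2011, sched, "toy"), 0.28)
  # cohort not yet born at `from` is an error
  expect_error(
    cumulative_death_probability(2001L, 1996, 2001, sched, "toy"),
    class = "lingcast_validation_error"
  )
})

test_that("cumulative mortality satisfies the composition identity on a grid", {
  set.seed(42)
  sched <- constant_schedule(q = 0)
  sched$q5 <- ifelse(sched$age_lo == 95L, 1, runif(nrow(sched), 0, 0.3))
  grid <- seq(1981L, 2021L, 5L)
  for (bh in c(1961L, 1976L)) {
    for (a in grid) {
      for (b in grid[grid > a]) {
        for (cc in grid[grid > b]) {
          lhs <- 1 - cumulative_death_probability(bh, a, cc, sched, "toy")
          rhs <- (1 - cumulative_death_probability(bh, a, b, sched, "toy")) *
            (1 - cumulative_death_probability(bh, b, cc, sched, "toy"))
          expect_equal(lhs, rhs, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("recasting to 2001 inverts survivorship and is identity without mortality", {
  counts <- dplyr::bind_rows(
    toy_counts(c(`0` = 100L, `10` = 50L), 2001L),
    toy_counts(c(`5` = 80L, `15` = 40L), 2006L)
  )
  # no mortality: estimates equal observed counts
  zero <- constant_schedule(q = 0)
  rec <- recast_to_2001(counts, zero, "toy")
  expect_equal(rec$estimate, as.numeric(rec$count))

  # M(2001 -> 2006) = 0.2 for the 1997-2001 cohort: 80 observed -> 100 recast
  sched <- constant_schedule(q = 0)
  sched$q5[sched$period_start == 2001L & sched$age_lo == 0L] <- 0.2
  rec <- recast_to_2001(counts, sched, "toy")
  cell <- rec[rec$birth_lo == 1997L & rec$census_year == 2006L, ]
  expect_equal(cell$estimate, 100)
  # the 2001 observation of the same cohort is untouched
  expect_equal(rec$estimate[rec$birth_lo == 1997L & rec$census_year == 2001L], 100)

  # lethal schedules make the recast undefined, with the cell named
  lethal <- constant_schedule(q = 0)
  lethal$q5[lethal$period_start == 2001L & lethal$age_lo == 0L] <- 1
  expect_error(
    recast_to_2001(counts, lethal, "toy"),
    "cohort 1997-2001",
    class = "lingcast_validation_error"
  )
})

test_that("backward recast excludes unborn cohorts and inverts exactly", {
  cohorts <- tibble::tibble(
    birth_lo = c(1997L, 1977L, 1957L),
    birth_hi = c(2001L, 1981L, 1961L),
    count = c(100, 100, 100)
  )
  sched <- constant_schedule(q = 0)
  # constant q = 0.1 below age 95 gives M(1981 -> 2001) = 1 - 0.9^4
  sched$q5[sched$age_lo < 95L] <- 0.1
  back <- recast_backward(cohorts, sched, "toy", 1981L)
  # cohort 1997-2001 is not yet born in 1981
  expect_false(1997L %in% back$birth_lo)
  expect_equal(nrow(back), 2L)
  expect_equal(
    back$estimate[back$birth_lo == 1977L], 100 / (1 - (1 - 0.9^4)),
    tolerance = 1e-12
  )
  # age groups at the target year
  expect_equal(back$age_lo[back$birth_lo == 1977L], 0L)
  expect_equal(back$age_lo[back$birth_lo == 1957L], 20L)

  # 50% cumulative mortality doubles the earlier count
  half <- constant_schedule(q = 0)
  half$q5[half$period_start == 1996L & half$age_lo == 35L] <- 0.5
  one <- tibble::tibble(birth_lo = 1957L, birth_hi = 1961L, count = 100)
  expect_equal(
    recast_backward(one, half, "toy", 1996L)$estimate, 200
  )

  # without mortality the backward recast is the identity
  back0 <- recast_backward(cohorts, constant_schedule(q = 0), "toy", 1981L)
  expect_equal(back0$estimate, c(100, 100))
})

test_that("backward and forward recasts are inverse to numerical precision", {
  set.seed(7)
  sched <- constant_schedule(q = 0)
  sched$q5 <- ifelse(sched$age_lo == 95L, 1, runif(nrow(sched), 0, 0.25))
  cohorts <- baseline_cohorts() |>
    dplyr::mutate(count = runif(17, 10, 500))
  for (y in seq(1981L, 1996L, 5L)) {
    back <- recast_backward(cohorts, sched, "toy", y)
    M <- cumulative_death_probability(back$birth_hi, y, 2001L, sched, "toy")
    recovered <- back$estimate * (1 - M)
    expect_equal(
      recovered,
      cohorts$count[match(back$birth_lo, cohorts$birth_lo)],
      tolerance = 1e-9
    )
  }
})
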