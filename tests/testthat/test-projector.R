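test_that("a step without deaths or births is a pure age shift", {
  set.seed(1)
  state <- tibble::tibble(age_lo = seq(0L, 95L, 5L), count = 100L)
  q0 <- rep(0, 20) # the engine forces q = 1 at 95-99 itself
  nxt <- project_step(state, xtfr = 0, q5 = q0, uniform_weights(), infant_surv = 1)
  expect_equal(nxt$count, c(0L, rep(100L, 19)))
  # totals conserved except for ageing past the maximum age
  expect_equal(sum(nxt$count), sum(state$count) - 100L)
})

test_that("a lethal step leaves only the new entrants", {
  set.seed(2)
  state <- tibble::tibble(age_lo = seq(0L, 95L, 5L), count = 50L)
  nxt <- project_step(state, xtfr = 1, q5 = rep(1, 20), uniform_weights(), 1)
  expect_equal(nxt$count[-1], rep(0L, 19))
  expect_gte(nxt$count[1], 0L)
})

test_that("realised births are Poisson around the expected total", {
  set.seed(3)
  state <- tibble::tibble(
    age_lo = seq(0L, 95L, 5L),
    count = ifelse(seq(0L, 95L, 5L) == 25L, 1000L, 0L)
  )
  w <- tibble::tibble(
    age_lo = seq(15L, 45L, 5L),
    weight = as.numeric(seq(15L, 45L, 5L) == 25L)
  )
  births <- replicate(3000, {
    project_step(state, xtfr = 0.8, q5 = rep(0, 20), w, infant_surv = 1)$count[1]
  })
  # expectation 1000 * 0.8 * 1 = 800; CLT bound at 3 standard errors
  expect_lt(abs(mean(births) - 800), 3 * sqrt(800 / 3000))
  expect_equal(var(births), 800, tolerance = 0.15)
})

test_that("trajectories keep cohort bookkeeping: no resurrection, no immigration", {
  set.seed(4)
  sched <- test_schedule()
  fert <- test_fertility()
  draw <- tibble::tibble(age_lo = seq(0L, 80L, 5L), count = 40L)
  path <- tibble::tibble(year = seq(2001L, 2096L, 5L), xtfr = 0.9)
  for (i in 1:5) {
    traj <- run_trajectory(draw, path, sched, "synthetic", fert)
    wide <- tidyr::pivot_wider(traj, names_from = "year", values_from = "count")
    m <- as.matrix(wide[, -1])
    for (j in seq_len(ncol(m) - 1)) {
      expect_true(all(m[-1, j + 1] <= m[-nrow(m), j]))
    }
  }
})

test_that("dormancy is absorbing and the all-zero draw stays at zero", {
  sched <- test_schedule()
  fert <- test_fertility()
  path <- tibble::tibble(year = seq(2001L, 2096L, 5L), xtfr = 1.2)
  zero <- tibble::tibble(age_lo = seq(0L, 80L, 5L), count = 0L)
  traj <- run_trajectory(zero, path, sched, "synthetic", fert)
  expect_true(all(traj$count == 0L))

  # deterministic limit: no mortality below the cap, no births
  q0 <- constant_schedule(q = 0, periods = seq(2001L, 2096L, 5L))
  draw <- tibble::tibble(age_lo = seq(0L, 80L, 5L), count = 10L)
  traj <- run_trajectory(
    draw, tibble::tibble(year = seq(2001L, 2096L, 5L), xtfr = 0),
    q0, "toy", fert
  )
  m <- matrix(traj$count, nrow = 20)
  for (j in 2:21) {
    expect_equal(m[, j], c(0L, m[1:19, j - 1]))
  }
})

test_that("an xTFR of one with balanced weights keeps the population stationary", {
  # expectation recursion under no mortality below the cap: drift < 5%
  q0 <- constant_schedule(q = 0, periods = seq(2001L, 2096L, 5L))
  fert <- test_fertility()
  draw <- tibble::tibble(age_lo = seq(0L, 95L, 5L), count = 1000)
  exp_traj <- expectation_recursion(
    draw, tibble::tibble(year = seq(2001L, 2096L, 5L), xtfr = 1),
    q0, "toy", fert
  )
  totals <- exp_traj |>
    dplyr::summarise(total = sum(count), .by = year)
  horizon_drift <- abs(totals$total[totals$year == 2051] /
    totals$total[totals$year == 2001] - 1)
  expect_lt(horizon_drift, 0.05)
})

test_that("the ensemble is bit-reproducible from its master seed", {
  sched <- test_schedule()
  fert <- test_fertility()
  model <- structure(
    list(
      language = "toy",
      total = list(mu = 800, tau = 40, df = 4L, n = 5L),
      cohorts = baseline_cohorts() |>
        dplyr::rename(age_lo = "age_lo_2001") |>
        dplyr::mutate(
          mu = 800 / 17, phi = NA_real_, family = "poisson",
          size = NA_real_, n_est = 5L
        )
    ),
    class = "speaker_baseline"
  )
  cfg <- load_config(n_reps = 25, seed = 9)
  e1 <- run_ensemble(model, sched, "synthetic", fert, cfg)
  e2 <- run_ensemble(model, sched, "synthetic", fert, cfg)
  expect_identical(e1$count, e2$count)
  e3 <- run_ensemble(model, sched, "synthetic", fert, cfg, seed = 10)
  expect_false(identical(e1$count, e3$count))
})

test_that("ensemble means match the deterministic expectation recursion", {
  # pure projection noise: fixed draw, fixed xTFR path, many replicates
  set.seed(12)
  sched <- test_schedule()
  fert <- test_fertility()
  draw <- tibble::tibble(age_lo = seq(0L, 80L, 5L), count = 60L)
  path <- tibble::tibble(year = seq(2001L, 2096L, 5L), xtfr = 1.1)
  n <- 400
  states <- array(0L, dim = c(20, 21, n))
  for (r in seq_len(n)) {
    traj <- run_trajectory(draw, path, sched, "synthetic", fert)
    states[, , r] <- matrix(traj$count, nrow = 20)
  }
  expected <- matrix(
    expectation_recursion(draw, path, sched, "synthetic", fert)$count,
    nrow = 20
  )
  mc_mean <- apply(states, c(1, 2), mean)
  mc_se <- apply(states, c(1, 2), stats::sd) / sqrt(n)
  z <- (mc_mean - expected) / ifelse(mc_se > 0, mc_se, 1)
  # familywise threshold for 420 correlated cells at overall alpha = 0.01
  zcrit <- stats::qnorm(1 - 0.01 / (2 * sum(mc_se > 0)))
  expect_lt(max(abs(z)), zcrit)
  # cells with no Monte-Carlo spread must agree exactly
  expect_true(all(mc_mean[mc_se == 0] == expected[mc_se == 0]))
})
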