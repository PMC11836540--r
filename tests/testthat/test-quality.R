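# minimal recast-shaped table from a named list of census-year totals,
# spread over three cohorts with fixed shares
fake_recast <- function(totals, language = "toy",
                        shares = c(0.5, 0.3, 0.2)) {
  purrr::imap_dfr(totals, function(tot, yr) {
    tibble::tibble(
      language = language,
      birth_lo = c(1997L, 1992L, 1987L),
      birth_hi = c(2001L, 1996L, 1991L),
      census_year = as.integer(yr),
      count = NA_integer_,
      estimate = tot * shares
    )
  })
}

test_that("census totals are flagged only when incompatible with the others", {
  # identical totals: nothing to flag
  eq <- fake_recast(c(`2001` = 100, `2006` = 100, `2011` = 100, `2016` = 100, `2021` = 100))
  expect_false(any(flag_total_outliers(eq)$flagged))

  # one wildly discrepant census is flagged
  out <- flag_total_outliers(
    fake_recast(c(`2001` = 100, `2006` = 101, `2011` = 99, `2016` = 100, `2021` = 400))
  )
  expect_identical(out$census_year[out$flagged], 2021L)

  # an ordinary spread is not flagged
  mild <- flag_total_outliers(
    fake_recast(c(`2001` = 90, `2006` = 95, `2011` = 100, `2016` = 105, `2021` = 110))
  )
  expect_false(any(mild$flagged))
})

test_that("the totals filter is scale-equivariant and keeps enough censuses", {
  totals <- c(`2001` = 80, `2006` = 120, `2011` = 100, `2016` = 95, `2021` = 300)
  f1 <- flag_total_outliers(fake_recast(totals))
  f2 <- flag_total_outliers(fake_recast(totals * 1000))
  expect_equal(f1$flagged, f2$flagged)

  # never fewer than three usable censuses per language
  extreme <- fake_recast(c(`2001` = 1, `2006` = 1e6, `2011` = 1, `2016` = 1e6, `2021` = 1))
  expect_gte(sum(!flag_total_outliers(extreme)$flagged), 3L)
})

test_that("age-cell flags pick out cells that break the language's age pattern", {
  # perfectly proportional matrix: no flags
  prop <- fake_recast(c(`2001` = 100, `2006` = 200, `2011` = 150, `2016` = 120, `2021` = 180))
  expect_false(any(flag_age_outliers(prop)$flagged))

  # one cell at ten times its row pattern is flagged, on a 3x3 toy matrix
  toy <- fake_recast(c(`2001` = 1000, `2006` = 1000, `2011` = 1000))
  toy$estimate[toy$birth_lo == 1992L & toy$census_year == 2011L] <-
    10 * toy$estimate[toy$birth_lo == 1992L & toy$census_year == 2011L]
  flags <- flag_age_outliers(toy)
  expect_true(flags$flagged[flags$birth_lo == 1992L & flags$census_year == 2011L])

  # an all-zero cohort row produces no flags
  z <- prop
  z$estimate[z$birth_lo == 1987L] <- 0
  fz <- flag_age_outliers(z)
  expect_false(any(fz$flagged[fz$birth_lo == 1987L]))
})

test_that("under the model's own noise the filters flag at most their nominal rates", {
  set.seed(2024)
  n_lang <- 200
  tot_rate <- cell_rate <- numeric(n_lang)
  for (i in seq_len(n_lang)) {
    mu <- c(400, 250, 150) # three cohorts, Poisson census noise
    est <- purrr::map_dfr(seq(2001L, 2021L, 5L), function(yr) {
      tibble::tibble(
        language = "sim",
        birth_lo = c(1997L, 1992L, 1987L),
        birth_hi = c(2001L, 1996L, 1991L),
        census_year = yr,
        count = NA_integer_,
        estimate = as.numeric(rpois(3, mu))
      )
    })
    tot_rate[i] <- mean(flag_total_outliers(est)$flagged)
    cell_rate[i] <- mean(flag_age_outliers(est)$flagged)
  }
  # nominal sizes 0.001 and 0.01, with Monte-Carlo slack (3 sigma)
  expect_lte(mean(tot_rate), 0.001 + 3 * sqrt(0.001 / (5 * n_lang)))
  expect_lte(mean(cell_rate), 0.01 + 3 * sqrt(0.01 / (15 * n_lang)))
})

test_that("a census undercounted threefold is flagged reliably, clean ones are not", {
  set.seed(31)
  presets <- test_presets()
  spec <- presets$large_growing
  truth <- make_true_population(spec, test_schedule(), test_fertility())
  hits <- clean_false <- logical(60)
  for (i in seq_along(hits)) {
    cc <- simulate_censuses(truth, with_undercount(spec, 2011L, 1 / 3))
    rec <- recast_to_2001(cc, test_schedule(), "synthetic")
    fl <- flag_total_outliers(rec)
    hits[i] <- fl$flagged[fl$census_year == 2011L]
    clean_false[i] <- any(fl$flagged[fl$census_year != 2011L])
  }
  expect_gte(mean(hits), 0.95)
  expect_lte(mean(clean_false), 0.05)
})
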