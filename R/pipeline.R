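#' End-to-end probabilistic speaker projection
#'
#' Runs the whole chain for every language in a census-count table: recast
#' of all counts to the 2001 baseline year, quality screening (implausible
#' census totals at p < 0.001, implausible age cells at p < 0.01),
#' baseline fitting (t-distribution for the total, 17 per-cohort negative
#' binomials), and the Monte-Carlo ensemble of stochastic cohort-component
#' trajectories to 2101 with per-replicate transmission trends. Per
#' language the master seed is combined with the language's rank by a
#' fixed affine-modular rule, so results are independent of which other
#' languages are in the run.
#'
#' @param counts Census-count tibble (see [read_census_counts()]).
#' @param schedule Mortality schedule covering periods 1981-2096.
#' @param fertility Fertility schedule with anchor years 2001 and 2100.
#' @param config A [load_config()] list.
#' @param pop_group Population group of `schedule` to use (default: the
#'   schedule's only group; `config$pop_group` may name one, or a named
#'   character vector may map languages to groups).
#' @param keep_ensembles Keep the full replicate-level ensembles (memory
#'   heavy) instead of only their summaries.
#' @return A `speaker_projection` object: per language the fitted baseline,
#'   the ensemble summary and the dormancy summary, plus the quality flags
#'   and the configuration.
#' @export
project_speakers <- function(counts, schedule, fertility,
                             config = load_config(), pop_group = NULL,
                             keep_ensembles = FALSE) {
  langs <- sort(unique(counts$language))
  if (!is.null(config$languages)) langs <- intersect(langs, config$languages)
  if (is.null(pop_group)) pop_group <- config$pop_group
  if (is.null(pop_group)) {
    groups <- unique(schedule$pop_group)
    if (length(groups) > 1) {
      rlang::abort("schedule has several population groups; name one via `pop_group`",
        class = "lingcast_validation_error"
      )
    }
    pop_group <- groups
  }
  group_of <- function(lg) {
    if (length(pop_group) > 1 || !is.null(names(pop_group))) {
      out <- pop_group[[lg]]
      if (is.null(out)) {
        rlang::abort(paste0("no population group mapped for language ", lg),
          class = "lingcast_validation_error"
        )
      }
      out
    } else {
      pop_group
    }
  }

  results <- lapply(seq_along(langs), function(i) {
    lg <- langs[i]
    pg <- group_of(lg)
    recast <- recast_to_2001(counts[counts$language == lg, ], schedule, pg)
    total_flags <- flag_total_outliers(recast)
    cell_flags <- flag_age_outliers(recast)
    baseline <- fit_baseline(recast, total_flags, cell_flags)[[lg]]
    ens <- run_ensemble(
      baseline, schedule, pg, fertility, config,
      seed = language_seed(config$seed, i)
    )
    out <- list(
      language = lg,
      baseline = baseline,
      summary = summarize_ensemble(ens),
      dormancy = dormancy_summary(ens),
      total_flags = total_flags,
      cell_flags = cell_flags
    )
    if (keep_ensembles) out$ensemble <- ens
    out
  })
  names(results) <- langs
  structure(
    list(languages = results, config = config),
    class = "speaker_projection"
  )
}

# deterministic per-language sub-seed from the master seed
language_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 7919) %% 2147483647)
}

#' @export
print.speaker_projection <- function(x, ...) {
  cat("<speaker_projection> ", length(x$languages), " language(s), ",
    x$config$n_reps, " replicates, scenario ", x$config$scenario, "\n",
    sep = ""
  )
  print(glance(x))
  invisible(x)
}

#' @method tidy speaker_projection
#' @export
tidy.speaker_projection <- function(x, ...) {
  purrr::map_dfr(x$languages, function(r) {
    dplyr::mutate(tibble::as_tibble(r$summary), language = r$language, .before = 1)
  })
}

#' @method glance speaker_projection
#' @export
glance.speaker_projection <- function(x, ...) {
  table_speakers(x) |>
    dplyr::left_join(
      table_dormancy(x) |>
        dplyr::filter(.data$band == "all") |>
        dplyr::select("language", risk_2101 = "risk"),
      by = "language"
    )
}

#' Headline projection tables
#'
#' `table_speakers()` reports, per language, the median speaker numbers
#' and 80% projection intervals in the baseline year and at the horizon.
#' `table_dormancy()` reports, per language and age band, the dormancy
#' risk at the horizon and the years at which the risk first reaches 10%
#' and 50% (`NA` when never).
#'
#' @param x A `speaker_projection`.
#' @return A tibble.
#' @export
table_speakers <- function(x) {
  y0 <- x$config$baseline_year
  y1 <- x$config$horizon
  purrr::map_dfr(x$languages, function(r) {
    s <- r$summary
    tot <- s[is.na(s$age_lo) & s$year %in% c(y0, y1), ]
    tibble::tibble(
      language = r$language,
      median_2001 = tot$median[tot$year == y0],
      q10_2001 = tot$q10[tot$year == y0],
      q90_2001 = tot$q90[tot$year == y0],
      median_2101 = tot$median[tot$year == y1],
      q10_2101 = tot$q10[tot$year == y1],
      q90_2101 = tot$q90[tot$year == y1]
    )
  })
}

#' @rdname table_speakers
#' @export
table_dormancy <- function(x) {
  y1 <- x$config$horizon
  purrr::map_dfr(x$languages, function(r) {
    d <- r$dormancy
    th <- attr(d, "thresholds")
    d[d$year == y1, c("band", "risk")] |>
      dplyr::mutate(
        language = r$language, .before = 1
      ) |>
      dplyr::left_join(
        tidyr::pivot_wider(th,
          names_from = "threshold", values_from = "year",
          names_prefix = "year_risk_"
        ),
        by = "band"
      )
  })
}

#' Pooled hindcast coverage of a projection
#'
#' Validates every language of a projection against its observed census
#' counts (years 2001-2021) and pools the cell-level results; see
#' [validate_coverage()].
#'
#' @param x A `speaker_projection`.
#' @param counts The observed census-count tibble.
#' @return A cell-level coverage tibble with a `language` column.
#' @export
hindcast_coverage <- function(x, counts) {
  purrr::map_dfr(x$languages, function(r) {
    validate_coverage(r$summary, counts[counts$language == r$language, ]) |>
      dplyr::mutate(language = r$language, .before = 1)
  })
}

#' Write a synthetic fixture bundle to disk
#'
#' Generates the true populations and census observations of a list of
#' scenarios and writes the three canonical CSV inputs (counts, life
#' table, fertility) plus a JSON manifest recording the seed.
#'
#' @param dir Output directory (created if needed).
#' @param specs List of `scenario_spec` objects.
#' @param seed Seed for the census noise.
#' @param schedule,fertility Schedules to use and to write.
#' @return Invisibly, the named list of file paths.
#' @export
simulate_fixture_bundle <- function(dir, specs, seed = 1L,
                                    schedule = synthetic_mortality_schedule(),
                                    fertility = synthetic_fertility_schedule()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  counts <- purrr::map_dfr(specs, function(spec) {
    simulate_censuses(make_true_population(spec, schedule, fertility), spec)
  })
  paths <- list(
    counts = file.path(dir, "census_counts.csv"),
    lifetable = file.path(dir, "lifetable.csv"),
    fertility = file.path(dir, "fertility.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_census_counts(counts, paths$counts)
  write_mortality_schedule(schedule, paths$lifetable)
  write_fertility_schedule(fertility, paths$fertility)
  jsonlite::write_json(
    list(
      seed = seed,
      languages = vapply(specs, function(s) s$language, character(1)),
      created = format(Sys.time(), tz = "UTC")
    ),
    paths$manifest,
    auto_unbox = TRUE
  )
  invisible(paths)
}

#' Reproducibility manifest of a run
#'
#' @param config A `run_config`.
#' @param inputs Optional named character vector of input file paths whose
#'   MD5 digests are recorded.
#' @param path Optional JSON output path.
#' @return The manifest list (invisibly written to `path` when given).
#' @export
run_manifest <- function(config, inputs = NULL, path = NULL) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("lingcast")),
    seed = config$seed,
    config = unclass(config),
    input_digests = if (!is.null(inputs)) {
      digests <- tools::md5sum(inputs)
      if (!is.null(names(inputs))) names(digests) <- names(inputs)
      as.list(digests)
    }
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(manifest)
}
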