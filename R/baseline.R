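#' Fit the t-distribution for a language's total 2001 size
#'
#' The repeated, mortality-free census totals of one language are treated as
#' replicate estimates of the same 2001 population size. Their mean `mu`,
#' the standard error of the mean `tau = sd / sqrt(n)` and `n - 1` degrees
#' of freedom define a location-scale t-distribution for the total.
#'
#' @param totals Numeric vector of recast census totals (after exclusions).
#' @return A list with `mu`, `tau`, `df`, `n`.
#' @export
fit_total_distribution <- function(totals) {
  n <- length(totals)
  if (n < 3) {
    rlang::abort("need at least 3 recast totals to fit the t-distribution",
      class = "lingcast_validation_error"
    )
  }
  list(
    mu = mean(totals),
    tau = stats::sd(totals) / sqrt(n),
    df = n - 1L,
    n = n
  )
}

#' Fit the count distribution for one birth cohort
#'
#' Moment fit of a negative binomial with quadratic mean-variance
#' relationship to the (up to five) mortality-free estimates of one cohort's
#' 2001 size: `mu` is the sample mean and the dispersion
#' `phi = variance / mu^2`, so the fitted variance is `mu + mu^2/size` with
#' `size = mu^2 / (variance - mu)`. Underdispersed cohorts (variance below
#' the mean, where no negative binomial exists) fall back to a Poisson with
#' the same mean; empty cohorts are degenerate at zero.
#'
#' @param estimates Numeric vector of recast cohort estimates (>= 0).
#' @return A list with `mu`, `phi`, `family` (`"nbinom"`, `"poisson"` or
#'   `"degenerate"`), `size` (NB only) and `n`.
#' @export
fit_cohort_distribution <- function(estimates) {
  stopifnot(all(estimates >= 0))
  n <- length(estimates)
  mu <- mean(estimates)
  if (mu == 0) {
    return(list(mu = 0, phi = NA_real_, family = "degenerate", size = NA_real_, n = n))
  }
  v <- if (n >= 2) stats::var(estimates) else NA_real_
  if (is.na(v) || v <= mu) {
    return(list(mu = mu, phi = if (is.na(v)) NA_real_ else v / mu^2,
                family = "poisson", size = NA_real_, n = n))
  }
  phi <- v / mu^2
  list(mu = mu, phi = phi, family = "nbinom", size = mu^2 / (v - mu), n = n)
}

#' Fit the probabilistic 2001 baseline of each language
#'
#' Combines the per-census totals (t-distribution) and the per-cohort
#' estimates (17 negative binomial distributions, cohorts 1917-1921 through
#' 1997-2001) into one baseline model per language, honouring the quality
#' exclusions.
#'
#' @param recast Recast estimates from [recast_to_2001()].
#' @param total_flags Optional output of [flag_total_outliers()].
#' @param cell_flags Optional output of [flag_age_outliers()].
#' @return A named list of `speaker_baseline` objects, one per language.
#' @export
fit_baseline <- function(recast, total_flags = NULL, cell_flags = NULL) {
  langs <- sort(unique(recast$language))
  out <- lapply(langs, function(lg) {
    df <- recast[recast$language == lg, ]
    drop_tot <- integer()
    if (!is.null(total_flags)) {
      drop_tot <- total_flags$census_year[
        total_flags$language == lg & total_flags$flagged
      ]
    }
    totals <- df |>
      dplyr::filter(!.data$census_year %in% drop_tot) |>
      dplyr::group_by(.data$census_year) |>
      dplyr::summarise(total = sum(.data$estimate), .groups = "drop")
    total <- fit_total_distribution(totals$total)

    cells_drop <- NULL
    if (!is.null(cell_flags)) {
      cells_drop <- cell_flags |>
        dplyr::filter(.data$language == lg, .data$flagged) |>
        dplyr::select("birth_lo", "census_year")
    }
    window <- baseline_cohorts()
    cohorts <- purrr::map_dfr(seq_len(nrow(window)), function(i) {
      bl <- window$birth_lo[i]
      est <- df$estimate[df$birth_lo == bl]
      yrs <- df$census_year[df$birth_lo == bl]
      if (!is.null(cells_drop) && nrow(cells_drop) > 0) {
        bad <- cells_drop$census_year[cells_drop$birth_lo == bl]
        est <- est[!yrs %in% bad]
      }
      if (length(est) == 0) est <- 0
      fit <- fit_cohort_distribution(est)
      tibble::tibble(
        birth_lo = bl, birth_hi = window$birth_hi[i],
        age_lo = window$age_lo_2001[i],
        mu = fit$mu, phi = fit$phi, family = fit$family,
        size = fit$size, n_est = fit$n
      )
    })
    structure(
      list(language = lg, total = total, cohorts = cohorts),
      class = "speaker_baseline"
    )
  })
  names(out) <- langs
  out
}

#' @export
print.speaker_baseline <- function(x, ...) {
  cat("<speaker_baseline> ", x$language, "\n", sep = "")
  cat(sprintf(
    "  total 2001: t(mu = %.1f, tau = %.2f, df = %d) from %d censuses\n",
    x$total$mu, x$total$tau, x$total$df, x$total$n
  ))
  cat("  cohorts:", nrow(x$cohorts), "fitted distributions (",
      paste(table(x$cohorts$family), names(table(x$cohorts$family)),
            collapse = ", "), ")\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy speaker_baseline
#' @export
tidy.speaker_baseline <- function(x, ...) {
  dplyr::mutate(x$cohorts, language = x$language, .before = 1)
}

#' @method glance speaker_baseline
#' @export
glance.speaker_baseline <- function(x, ...) {
  tibble::tibble(
    language = x$language,
    mu = x$total$mu, tau = x$total$tau, df = x$total$df,
    n_censuses = x$total$n, n_cohorts = nrow(x$cohorts)
  )
}

# one random count from a fitted cohort distribution (vectorised over rows)
draw_cohort_counts <- function(cohorts) {
  k <- nrow(cohorts)
  out <- integer(k)
  nb <- cohorts$family == "nbinom"
  po <- cohorts$family == "poisson"
  if (any(nb)) {
    out[nb] <- stats::rnbinom(sum(nb), size = cohorts$size[nb], mu = cohorts$mu[nb])
  }
  if (any(po)) out[po] <- stats::rpois(sum(po), cohorts$mu[po])
  out
}

# integer apportionment of total T proportional to x, exact sum by
# largest remainder; ties broken towards younger cohorts for determinism
largest_remainder <- function(x, total) {
  if (total <= 0) {
    return(integer(length(x)))
  }
  if (sum(x) == 0) x <- rep(1, length(x))
  target <- x * total / sum(x)
  base <- floor(target)
  rem <- target - base
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    idx <- order(-rem, seq_along(rem))[seq_len(short)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Draw one baseline population realisation
#'
#' A realisation of a language's 2001 population: one total drawn from the
#' t-distribution (truncated below at zero and rounded to the nearest
#' integer) and 17 cohort counts drawn from the fitted per-cohort
#' distributions, rescaled by largest-remainder apportionment so that the
#' age counts sum exactly to the realised total. Should every cohort draw
#' come back zero while the total is positive, the total is spread in
#' proportion to the fitted cohort means.
#'
#' @param model A `speaker_baseline` object.
#' @return A tibble (`birth_lo`, `birth_hi`, `age_lo`, `count`) with 17
#'   rows, ages 0-4 ... 80-84; the realised total is attached as attribute
#'   `total`.
#' @export
sample_baseline <- function(model) {
  total <- draw_total(model$total)
  raw <- draw_cohort_counts(model$cohorts)
  if (sum(raw) == 0) {
    base <- model$cohorts$mu
    raw <- if (sum(base) > 0) base else rep(1, length(raw))
  }
  counts <- largest_remainder(raw, total)
  out <- tibble::tibble(
    birth_lo = model$cohorts$birth_lo,
    birth_hi = model$cohorts$birth_hi,
    age_lo = model$cohorts$age_lo,
    count = counts
  ) |>
    dplyr::arrange(.data$age_lo)
  attr(out, "total") <- total
  out
}

draw_total <- function(total) {
  t_raw <- if (total$tau == 0) {
    total$mu
  } else {
    total$mu + total$tau * stats::rt(1, df = total$df)
  }
  as.integer(round(max(0, t_raw)))
}
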