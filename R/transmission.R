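#' xTFR: mean number of child speakers per adult speaker
#'
#' Indirect fertility estimate from a single age pyramid,
#' `xTFR = (10.65 - 12.55 * pi_25_34) * C / W`, where `C` counts speakers
#' aged 0-4, `W` speakers aged 15-49 and `pi_25_34` is the share of ages
#' 25-34 within `W`. Applied to all speakers (both genders) rather than
#' women only, so a value of about 1 -- one child speaker per adult
#' speaker -- marks replacement. Negative values of the bracket are floored
#' at zero.
#'
#' @param age_counts Data frame with columns `age_lo` and `count` (reals
#'   allowed; e.g. a baseline draw or a backward-recast population).
#' @return A single non-negative number.
#' @examples
#' pop <- tibble::tibble(age_lo = seq(0, 80, 5), count = 100)
#' compute_xtfr(pop)
#' @export
compute_xtfr <- function(age_counts) {
  count_col <- if ("count" %in% names(age_counts)) "count" else "estimate"
  a <- age_counts$age_lo
  n <- age_counts[[count_col]]
  C <- sum(n[a < 5])
  W <- sum(n[a >= 15 & a < 50])
  if (W == 0) {
    rlang::abort("no speakers aged 15-49: xTFR undefined (W = 0)",
      class = "lingcast_validation_error"
    )
  }
  pi2534 <- sum(n[a >= 25 & a < 35]) / W
  max(0, (10.65 - 12.55 * pi2534) * C / W)
}

#' Estimate a 1981-2001 xTFR series from one baseline draw
#'
#' Backward-recasts the 2001 cohort counts of a baseline draw to 1981,
#' 1986, 1991 and 1996 (cohorts not yet born at a year are excluded) and
#' evaluates the xTFR formula on the resulting age pyramid of each year,
#' plus on the draw itself for 2001. Years whose pyramid has no speakers
#' aged 15-49 get an xTFR of 0 (with a warning unless `quiet`).
#'
#' @param draw A baseline draw from [sample_baseline()] (or any tibble with
#'   `birth_lo`, `birth_hi`, `age_lo`, `count` referenced to 2001).
#' @inheritParams q_lookup
#' @param quiet Suppress the degenerate-pyramid warning.
#' @return A tibble (`year`, `xtfr`) with the five years 1981-2001.
#' @export
estimate_xtfr_series <- function(draw, schedule, pop_group, quiet = FALSE) {
  years <- seq.int(1981L, 2001L, 5L)
  xtfr <- vapply(years, function(y) {
    pyramid <- if (y == 2001L) {
      dplyr::select(draw, "age_lo", "count")
    } else {
      recast_backward(draw, schedule, pop_group, y) |>
        dplyr::transmute(age_lo = .data$age_lo, count = .data$estimate)
    }
    if (sum(pyramid$count[pyramid$age_lo >= 15 & pyramid$age_lo < 50]) == 0) {
      if (!quiet) {
        rlang::warn(paste0("no speakers aged 15-49 in ", y, "; xTFR set to 0"))
      }
      return(0)
    }
    compute_xtfr(pyramid)
  }, numeric(1))
  tibble::tibble(year = years, xtfr = xtfr)
}

#' Classify the direction of an xTFR series
#'
#' The trend is `"decreasing"` when the least-squares slope of xTFR on
#' calendar year is strictly negative, `"non-decreasing"` otherwise
#' (a zero slope counts as non-decreasing, which routes constant series to
#' the bounded, mean-anchored model).
#'
#' @param series A tibble (`year`, `xtfr`), typically five points.
#' @return `"decreasing"` or `"non-decreasing"`.
#' @export
classify_trend <- function(series) {
  x <- series$year - mean(series$year)
  slope <- sum(x * series$xtfr) / sum(x^2)
  if (slope < 0) "decreasing" else "non-decreasing"
}

#' Fit an extrapolable trend to the five xTFR estimates
#'
#' Decreasing series get an exponential-decay model: ordinary least squares
#' of `log(xtfr)` on calendar year (centred at 2001 for numerical hygiene;
#' values are floored at `eps` before the log). Non-decreasing series get a
#' model linear in `log(year)` constrained through an anchor point at
#' `anchor_year` whose value is the 1981-2001 mean, which keeps the
#' extrapolated path bounded. An all-zero series yields a degenerate model
#' whose path is identically zero.
#'
#' @param series A tibble (`year`, `xtfr`) of five estimates 1981-2001.
#' @param anchor_year Calendar year at which the non-decreasing model is
#'   pinned to the observed mean.
#' @param eps Floor applied to xTFR values before taking logs.
#' @return An `xtfr_trend` object.
#' @export
fit_trend <- function(series, anchor_year = 2096L, eps = 0.005) {
  stopifnot(nrow(series) >= 2)
  v <- series$xtfr
  if (all(v == 0)) {
    return(structure(
      list(
        form = "zero", intercept = 0, slope = 0,
        anchor_year = anchor_year, anchor_value = 0,
        mean_obs = 0, eps = eps, series = series
      ),
      class = "xtfr_trend"
    ))
  }
  direction <- classify_trend(series)
  if (direction == "decreasing") {
    y <- log(pmax(v, eps))
    x <- series$year - 2001
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    a <- mean(y) - b * mean(x)
    # a value-decreasing series can still fit a growing exponential when the
    # floor compresses near-zero values; an unbounded growth path would be
    # self-contradictory, so such series use the bounded anchored model
    if (b > 0) direction <- "non-decreasing"
  }
  if (direction == "decreasing") {
    structure(
      list(
        form = "log-linear-decline", intercept = a, slope = b,
        anchor_year = anchor_year, anchor_value = NA_real_,
        mean_obs = mean(v), eps = eps, series = series
      ),
      class = "xtfr_trend"
    )
  } else {
    vbar <- mean(v)
    L <- log(anchor_year)
    lx <- log(series$year) - L
    b <- if (sum(lx^2) == 0) 0 else sum((v - vbar) * lx) / sum(lx^2)
    a <- vbar - b * L
    structure(
      list(
        form = "log-year-anchored", intercept = a, slope = b,
        anchor_year = anchor_year, anchor_value = vbar,
        mean_obs = vbar, eps = eps, series = series
      ),
      class = "xtfr_trend"
    )
  }
}

#' @export
print.xtfr_trend <- function(x, ...) {
  cat("<xtfr_trend> form:", x$form, "\n")
  cat(sprintf("  intercept %.4g  slope %.4g\n", x$intercept, x$slope))
  if (x$form == "log-year-anchored") {
    cat(sprintf("  anchored at %d to mean %.3f\n", x$anchor_year, x$anchor_value))
  }
  invisible(x)
}

#' @method tidy xtfr_trend
#' @export
tidy.xtfr_trend <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @method glance xtfr_trend
#' @export
glance.xtfr_trend <- function(x, ...) {
  tibble::tibble(
    form = x$form, mean_obs = x$mean_obs,
    anchor_year = x$anchor_year, anchor_value = x$anchor_value
  )
}

eval_trend <- function(trend, years) {
  switch(trend$form,
    "zero" = rep(0, length(years)),
    "log-linear-decline" = exp(trend$intercept + trend$slope * (years - 2001)),
    "log-year-anchored" = pmax(0, trend$intercept + trend$slope * log(years))
  )
}

#' Project an xTFR trend into 2006-2096
#'
#' Evaluates a fitted trend at quinquennial years. Under the `"freeze"`
#' scenario the path follows the model until `freeze_year` (2046) and is
#' held constant thereafter; under `"unlimited"` the fitted curve runs to
#' the final year unconstrained. Values are floored at zero.
#'
#' @param trend An `xtfr_trend` object.
#' @param scenario `"freeze"` or `"unlimited"`.
#' @param years Quinquennial years to evaluate (default 2006-2096).
#' @param freeze_year Year after which the freeze scenario holds the path
#'   constant.
#' @return A tibble (`year`, `xtfr`).
#' @export
project_xtfr <- function(trend, scenario = c("freeze", "unlimited"),
                         years = seq(2006L, 2096L, 5L), freeze_year = 2046L) {
  scenario <- match.arg(scenario)
  vals <- eval_trend(trend, years)
  if (scenario == "freeze") {
    frozen <- eval_trend(trend, freeze_year)
    vals[years > freeze_year] <- frozen
  }
  tibble::tibble(year = as.integer(years), xtfr = pmax(0, vals))
}
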