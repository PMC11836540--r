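#' Five-year age-group ladder
#'
#' Census counts are tabulated in five-year age groups `0-4`, `5-9`, ...,
#' `95-99` plus the open-ended `100+` category. Groups are encoded by their
#' lower bound; `age_lo = 100` denotes the open-ended group.
#'
#' @param open Logical; include the open-ended `100+` group.
#' @return Integer vector of age-group lower bounds.
#' @export
age_ladder <- function(open = TRUE) {
  if (open) seq.int(0L, 100L, 5L) else seq.int(0L, 95L, 5L)
}

#' @rdname age_ladder
#' @param age_lo Integer vector of age-group lower bounds.
#' @return `age_group_label()`: character labels such as `"0-4"` or `"100+"`.
#' @export
age_group_label <- function(age_lo) {
  ifelse(age_lo >= 100L, "100+", paste0(age_lo, "-", age_lo + 4L))
}

#' Map an observed age group to its birth cohort
#'
#' A five-year age group observed at a quinquennial census identifies a
#' five-year birth cohort: the cohort limits are the census year minus the
#' upper and lower age limits. The `0-4` group in 2001 is the 1997-2001
#' cohort; the same cohort reappears as `5-9` in 2006, `10-14` in 2011, and
#' so on. The open-ended `100+` group cannot be assigned to a single cohort
#' and is excluded from cohort-level analysis.
#'
#' @param age_lo Integer vector of closed age-group lower bounds (0, 5, ..., 95).
#' @param census_year Integer vector (recycled) of census years.
#' @return A tibble with columns `age_lo`, `census_year`, `birth_lo`,
#'   `birth_hi` (`birth_hi = birth_lo + 4`).
#' @examples
#' assign_cohort(0, 2001)  # 1997-2001
#' assign_cohort(5, 2006)  # 1997-2001 again
#' @export
assign_cohort <- function(age_lo, census_year) {
  if (any(age_lo >= 100L)) {
    rlang::abort(
      "open-ended age group `100+` cannot be assigned to a birth cohort",
      class = "lingcast_validation_error"
    )
  }
  if (any(age_lo %% 5 != 0 | age_lo < 0)) {
    rlang::abort("`age_lo` must be a multiple of 5 in [0, 95]",
      class = "lingcast_validation_error"
    )
  }
  tibble::tibble(
    age_lo = as.integer(age_lo),
    census_year = as.integer(census_year),
    birth_lo = as.integer(census_year - age_lo - 4L),
    birth_hi = as.integer(census_year - age_lo)
  )
}

#' Baseline birth-cohort window
#'
#' The cohorts retained for baseline estimation are those observable at all
#' five censuses 2001-2021 within closed age groups: 1917-1921 through
#' 1997-2001, i.e. ages 0-4 to 80-84 in 2001. (The oldest cohort falls into
#' the open-ended `100+` group by 2021 and therefore contributes only four
#' usable observations.)
#'
#' @return A tibble with columns `birth_lo`, `birth_hi`, `age_lo_2001`.
#' @export
baseline_cohorts <- function() {
  birth_lo <- seq.int(1917L, 1997L, 5L)
  tibble::tibble(
    birth_lo = birth_lo,
    birth_hi = birth_lo + 4L,
    age_lo_2001 = 2001L - (birth_lo + 4L)
  )
}
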