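#' Flag implausible census totals
#'
#' Sums the mortality-free (recast) cohort estimates of each census into a
#' per-census total and tests each total's deviation from the language's
#' other censuses under a normal model: for census i the z-score uses the
#' leave-one-out mean and standard deviation of the remaining totals, and
#' the two-sided p-value of the externally studentized residual
#' (`z / sqrt(1 + 1/m)` referred to a t-distribution with `m - 1` degrees
#' of freedom, `m` the number of other censuses -- the exact null
#' distribution under normality) is compared with `alpha`. A census is only
#' flagged when its total is incompatible with the spread of the others
#' (typical causes: incomplete enumeration in one census year). Flags never
#' reduce a language below `min_keep` usable censuses.
#'
#' @param recast Recast estimates from [recast_to_2001()].
#' @param alpha Flagging threshold on the two-sided p-value.
#' @param min_keep Minimum number of censuses that must remain per language.
#' @return A tibble (`language`, `census_year`, `total`, `z`, `p_value`,
#'   `flagged`).
#' @export
flag_total_outliers <- function(recast, alpha = 0.001, min_keep = 3L) {
  totals <- recast |>
    dplyr::group_by(.data$language, .data$census_year) |>
    dplyr::summarise(total = sum(.data$estimate), .groups = "drop")
  totals |>
    dplyr::group_by(.data$language) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (n < 3) {
        rlang::abort("need at least 3 census totals per language",
          class = "lingcast_validation_error"
        )
      }
      z <- vapply(seq_len(n), function(i) {
        rest <- df$total[-i]
        s <- stats::sd(rest)
        if (!is.finite(s) || s == 0) {
          if (df$total[i] == mean(rest)) 0 else Inf
        } else {
          (df$total[i] - mean(rest)) / s
        }
      }, numeric(1))
      m <- n - 1
      p <- 2 * stats::pt(-abs(z) / sqrt(1 + 1 / m), df = m - 1)
      flagged <- p < alpha
      # never drop below min_keep censuses: release the weakest flags first
      while (sum(!flagged) < min_keep && any(flagged)) {
        release <- which(flagged)[which.max(p[flagged])]
        flagged[release] <- FALSE
      }
      df$z <- z
      df$p_value <- p
      df$flagged <- flagged
      df
    }) |>
    dplyr::ungroup()
}

#' Flag implausible age-specific census cells
#'
#' Tests every (cohort, census) recast estimate of a language against the
#' value expected if all censuses shared the language's cohort composition.
#' The expected cell is built robustly (so that a grossly wrong cell cannot
#' mask itself by dragging its own row and column along): the cohort shares
#' are medians of the column-normalised estimates across censuses, and each
#' census column's level is the median of its estimates over the shares.
#' Residuals are standardised by a quadratic mean-variance law
#' `sd = sqrt(exp + phi * exp^2)` -- `phi` estimated robustly per language
#' from the median squared relative residual, so the filter stays
#' calibrated both for small (Poisson-like) and for large, overdispersed
#' counts -- with the standard deviation floored at 2.5 (the worst-case
#' noise of base-5 random rounding). Cells with a two-sided normal p-value
#' below `alpha` are flagged; all-zero cohort rows are skipped; flags
#' never reduce a cohort below `min_keep` usable estimates.
#'
#' @inheritParams flag_total_outliers
#' @param alpha Flagging threshold on the two-sided p-value.
#' @param min_keep Minimum estimates that must remain per (language, cohort).
#' @return A tibble (`language`, `birth_lo`, `census_year`, `estimate`,
#'   `expected`, `z`, `p_value`, `flagged`).
#' @export
flag_age_outliers <- function(recast, alpha = 0.01, min_keep = 2L) {
  recast |>
    dplyr::group_by(.data$language) |>
    dplyr::group_modify(function(df, key) flag_age_outliers_one(df, alpha, min_keep)) |>
    dplyr::ungroup()
}

flag_age_outliers_one <- function(df, alpha, min_keep) {
  wide <- df |>
    dplyr::select("birth_lo", "census_year", "estimate") |>
    tidyr::pivot_wider(names_from = "census_year", values_from = "estimate")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$birth_lo
  # robust cohort shares: median across censuses of the column-normalised cells
  col_tot <- colSums(m, na.rm = TRUE)
  ratio <- sweep(m, 2, ifelse(col_tot > 0, col_tot, 1), "/")
  share <- apply(ratio, 1, stats::median, na.rm = TRUE)
  share[!is.finite(share)] <- 0
  if (sum(share) > 0) share <- share / sum(share)
  # robust census levels: median of the cells over their shares
  expm <- m * NA_real_
  for (j in seq_len(ncol(m))) {
    have <- !is.na(m[, j]) & share > 0
    if (!any(have)) {
      expm[!is.na(m[, j]), j] <- 0
      next
    }
    scale_j <- stats::median(m[have, j] / share[have])
    expm[!is.na(m[, j]), j] <- share[!is.na(m[, j])] * scale_j
  }
  obs <- as.vector(m)
  expv <- as.vector(expm)
  ok <- !is.na(obs) & !is.na(expv) & expv > 0
  phi_hat <- if (any(ok)) {
    stats::median(((obs[ok] - expv[ok]) / expv[ok])^2) / stats::qchisq(0.5, 1)
  } else {
    0
  }
  sdv <- pmax(sqrt(expv + phi_hat * expv^2), 2.5)
  z <- (obs - expv) / sdv
  p <- 2 * stats::pnorm(-abs(z))
  out <- tibble::tibble(
    birth_lo = rep(as.integer(wide$birth_lo), ncol(m)),
    census_year = rep(as.integer(colnames(m)), each = nrow(m)),
    estimate = obs,
    expected = expv,
    z = z,
    p_value = p
  ) |>
    dplyr::filter(!is.na(.data$estimate)) |>
    dplyr::mutate(flagged = !is.na(.data$p_value) & .data$p_value < alpha)
  # keep at least min_keep estimates per cohort
  out |>
    dplyr::group_by(.data$birth_lo) |>
    dplyr::group_modify(function(g, key) {
      while (sum(!g$flagged) < min_keep && any(g$flagged)) {
        release <- which(g$flagged)[which.max(g$p_value[g$flagged])]
        g$flagged[release] <- FALSE
      }
      g
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$birth_lo, .data$census_year)
}
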