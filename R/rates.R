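#' Noncumulative return rate for one cohort and year
#'
#' The noncumulative return rate of a birth cohort in a calendar year is the
#' percentage of that cohort classified as returned in that year (a child can
#' drop out of the returned state again in later years, so rates need not be
#' monotone).
#'
#' @param panel A status panel (see [build_status_panel()]).
#' @param profiles Profiles tibble.
#' @param cohort Birth-cohort year.
#' @param year Year of movement (must be `>= cohort`).
#' @param ... Optional filter expressions evaluated on `profiles`
#'   (e.g. `child_type == "A"`, `mother_edu == "4"`) restricting the
#'   denominator to a stratum.
#' @return A one-row tibble with `rate` (percentage of the stratum returned,
#'   unrounded; `NA` when the stratum is empty -- an absent cell, not 0) and
#'   `n` (denominator: number of children in the cohort stratum).
#' @export
return_rate <- function(panel, profiles, cohort, year, ...) {
  if (year < cohort) abort("year must be >= cohort")
  profiles <- as_profiles(profiles)
  kids <- dplyr::filter(profiles, .data$birth_year == cohort, ...)
  n <- nrow(kids)
  if (n == 0) {
    return(tibble::tibble(rate = NA_real_, n = 0L))
  }
  rows <- panel[panel$child_id %in% kids$child_id & panel$year == year, ]
  if (nrow(rows) != n) {
    abort("panel does not cover every child of the cohort in that year")
  }
  tibble::tibble(rate = 100 * mean(rows$status), n = n)
}

#' Cohort-by-year return-rate table
#'
#' Builds the full grid of noncumulative return rates: one cell per birth
#' cohort and year of movement, optionally restricted to one child type and
#' stratified by a parental education level. Cells whose denominator is zero
#' are absent (no row), not zero; small denominators are flagged because
#' their rates are unstable.
#'
#' @param panel A status panel.
#' @param profiles Profiles tibble.
#' @param child_type Optional `"A"` or `"B"` restriction.
#' @param stratify_by `"none"`, `"mother_edu"` or `"father_edu"`.
#' @param small_n Flag cells with denominator below this (default 30).
#' @return A tibble of class `"rate_table"` with columns `cohort`, `year`,
#'   optionally `child_type` and `stratum`, plus `rate` (unrounded
#'   percentage), `n` (denominator) and `small_cell`. Rates are rounded only
#'   at presentation (see [format_rate_table()]).
#' @export
rate_table <- function(panel, profiles,
                       child_type = NULL,
                       stratify_by = c("none", "mother_edu", "father_edu"),
                       small_n = 30L) {
  stratify_by <- match.arg(stratify_by)
  profiles <- as_profiles(profiles)
  if (!is.null(child_type)) {
    child_type <- match.arg(child_type, CHILD_TYPES)
    profiles <- profiles[profiles$child_type == child_type, ]
  }
  df <- dplyr::inner_join(
    tibble::as_tibble(panel), profiles, by = "child_id"
  )
  keys <- c(cohort = "birth_year", year = "year", child_type = "child_type")
  if (stratify_by != "none") keys <- c(keys, stratum = stratify_by)
  df <- dplyr::rename(df, dplyr::all_of(keys))
  out <- dplyr::summarise(
    dplyr::group_by(df, dplyr::across(dplyr::all_of(names(keys)))),
    rate = 100 * mean(.data$status),
    n = dplyr::n(),
    .groups = "drop"
  )
  out$small_cell <- out$n < small_n
  out <- dplyr::arrange(out, dplyr::across(dplyr::all_of(names(keys))))
  class(out) <- c("rate_table", class(out))
  out
}

#' Present a rate table with conventional rounding
#'
#' Rates are printed to one decimal place; small cells are marked with an
#' asterisk. Rounding happens only here: the `rate_table` itself keeps
#' unrounded values.
#'
#' @param x A [rate_table()].
#' @param digits Decimal places for rates (default 1).
#' @return A tibble with `rate` as a formatted character column.
#' @export
format_rate_table <- function(x, digits = 1L) {
  out <- tibble::as_tibble(x)
  out$rate <- paste0(
    formatC(round(out$rate, digits), format = "f", digits = digits),
    ifelse(out$small_cell, "*", "")
  )
  out
}

#' Tabulate Type A / Type B births per cohort year
#'
#' @param profiles Profiles tibble.
#' @return A tibble with columns `year`, `type_a`, `type_b`.
#' @export
count_births <- function(profiles) {
  profiles <- as_profiles(profiles)
  tab <- table(profiles$birth_year, profiles$child_type)
  tibble::tibble(
    year = as.integer(rownames(tab)),
    type_a = as.integer(tab[, "A"]),
    type_b = as.integer(tab[, "B"])
  )
}

#' Yearly breakdown of births by child category
#'
#' Combines Type A and Type B birth counts with externally supplied counts
#' of all other births ("Other": local children and other non-study births)
#' into per-year totals and percentage shares.
#'
#' @param births Either a profiles tibble (tabulated via [count_births()])
#'   or a tibble with columns `year`, `type_a`, `type_b` of birth counts.
#' @param other_counts Other births per year: a tibble with columns `year`
#'   and `other`, or a numeric vector named by year.
#' @return A tibble with columns `year`, `type_a`, `type_b`, `other`,
#'   `total`, shares `share_a`, `share_b`, `share_other` (percent, rounded
#'   to 2 decimal places) and `flagged` (`TRUE` for all-zero years whose
#'   shares are undefined).
#' @export
birth_breakdown <- function(births, other_counts) {
  if ("child_id" %in% names(births)) births <- count_births(births)
  births <- tibble::as_tibble(births)
  if (!all(c("year", "type_a", "type_b") %in% names(births))) {
    abort("births must have columns year, type_a, type_b")
  }
  if (is.numeric(other_counts) && !is.null(names(other_counts))) {
    other_counts <- tibble::tibble(
      year = as.integer(names(other_counts)), other = as.numeric(other_counts)
    )
  }
  out <- dplyr::inner_join(births, other_counts, by = "year")
  counts <- out[, c("type_a", "type_b", "other")]
  if (any(counts < 0)) abort("negative birth counts")
  out$total <- out$type_a + out$type_b + out$other
  share <- function(x) ifelse(out$total > 0, round(100 * x / out$total, 2),
                              NA_real_)
  out$share_a <- share(out$type_a)
  out$share_b <- share(out$type_b)
  out$share_other <- share(out$other)
  out$flagged <- out$total == 0
  dplyr::arrange(out, .data$year)
}
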