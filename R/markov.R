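#' Tally year-to-year status transitions for one birth cohort
#'
#' Under the model, a child's returned status in one year depends only on
#' the previous year's status (a first-order, two-state chain, homogeneous
#' in age within a cohort). Each child contributes one transition per pair
#' of consecutive observed years; transitions are pooled over children and
#' ages within the cohort.
#'
#' @param panel A status panel (see [build_status_panel()]).
#' @param profiles Profiles tibble.
#' @param cohort Birth-cohort year.
#' @param ... Optional filter expressions on `profiles` (e.g.
#'   `child_type == "A"`) restricting the cohort to a stratum.
#' @return A one-row tibble of class `"transition_counts"` with `cohort`,
#'   `n00`, `n01`, `n10`, `n11` (`nab` = transitions from status `a` to
#'   status `b`). `n00 + n01 + n10 + n11` equals the number of consecutive
#'   year pairs summed over children.
#' @export
count_transitions <- function(panel, profiles, cohort, ...) {
  profiles <- as_profiles(profiles)
  kids <- dplyr::filter(profiles, .data$birth_year == cohort, ...)
  if (nrow(kids) == 0) abort(paste0("no children in cohort ", cohort))
  df <- tibble::as_tibble(panel)
  df <- df[df$child_id %in% kids$child_id, ]
  if (nrow(df) == 0) abort(paste0("cohort ", cohort, " absent from panel"))
  df <- dplyr::arrange(df, .data$child_id, .data$year)
  if (max(df$year) - min(df$year) < 1) {
    abort("panel covers fewer than 2 years for this cohort; no transitions observable")
  }
  from <- df$status[-nrow(df)]
  to <- df$status[-1L]
  same <- df$child_id[-nrow(df)] == df$child_id[-1L]
  from <- from[same]
  to <- to[same]
  out <- tibble::tibble(
    cohort = as.integer(cohort),
    n00 = sum(from == 0L & to == 0L),
    n01 = sum(from == 0L & to == 1L),
    n10 = sum(from == 1L & to == 0L),
    n11 = sum(from == 1L & to == 1L)
  )
  class(out) <- c("transition_counts", class(out))
  out
}

#' Maximum-likelihood transition probabilities from pooled counts
#'
#' For a homogeneous two-state chain the MLE of the transition matrix is the
#' row-wise proportion of observed transitions: `theta1 = n00 / (n00 + n01)`
#' (stay not-returned) and `theta2 = n11 / (n10 + n11)` (stay returned).
#' Wald 95% intervals from the binomial counts are attached; the paper-level
#' analysis reports none, so they are additional tooling.
#'
#' @param counts A [count_transitions()] result (or anything with `n00`,
#'   `n01`, `n10`, `n11` and optionally `cohort`).
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#' @return A `"transition_matrix"` object: list with `cohort`, `theta1`,
#'   `theta2`, their standard errors and confidence limits, row exposures
#'   `n0`, `n1`, and logical flags `theta1_estimable`, `theta2_estimable`.
#'   A row with zero exposure yields an `NA` estimate and a `FALSE` flag
#'   rather than a silent imputation.
#' @export
estimate_theta <- function(counts, conf_level = 0.95) {
  n0 <- counts$n00 + counts$n01
  n1 <- counts$n10 + counts$n11
  if (n0 + n1 == 0) abort("no observed transitions; cannot estimate")
  z <- qnorm(1 - (1 - conf_level) / 2)
  est_row <- function(stay, n) {
    if (n == 0) {
      return(list(theta = NA_real_, se = NA_real_, lo = NA_real_,
                  hi = NA_real_, ok = FALSE))
    }
    th <- stay / n
    se <- sqrt(th * (1 - th) / n)
    list(theta = th, se = se, lo = max(0, th - z * se),
         hi = min(1, th + z * se), ok = TRUE)
  }
  r0 <- est_row(counts$n00, n0)
  r1 <- est_row(counts$n11, n1)
  structure(
    list(
      cohort = if ("cohort" %in% names(counts)) counts$cohort else NA_integer_,
      theta1 = r0$theta, theta1_se = r0$se,
      theta1_lower = r0$lo, theta1_upper = r0$hi,
      theta2 = r1$theta, theta2_se = r1$se,
      theta2_lower = r1$lo, theta2_upper = r1$hi,
      n0 = n0, n1 = n1,
      theta1_estimable = r0$ok, theta2_estimable = r1$ok,
      conf_level = conf_level
    ),
    class = "transition_matrix"
  )
}

#' Construct a transition matrix directly from probabilities
#'
#' @param theta1 Probability of staying not-returned given not-returned.
#' @param theta2 Probability of staying returned given returned.
#' @param cohort Optional cohort label.
#' @return A `"transition_matrix"` object (without sampling uncertainty).
#' @export
transition_matrix <- function(theta1, theta2, cohort = NA_integer_) {
  stopifnot(theta1 >= 0, theta1 <= 1, theta2 >= 0, theta2 <= 1)
  structure(
    list(
      cohort = cohort,
      theta1 = theta1, theta1_se = NA_real_,
      theta1_lower = NA_real_, theta1_upper = NA_real_,
      theta2 = theta2, theta2_se = NA_real_,
      theta2_lower = NA_real_, theta2_upper = NA_real_,
      n0 = NA_integer_, n1 = NA_integer_,
      theta1_estimable = TRUE, theta2_estimable = TRUE,
      conf_level = NA_real_
    ),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Two-state transition matrix",
      if (!is.na(x$cohort)) paste0(" (cohort ", x$cohort, ")"), "\n", sep = "")
  m <- as.matrix(x)
  print(round(m, 4))
  if (!is.na(x$theta1_se) || !is.na(x$theta2_se)) {
    cat(sprintf(
      "theta1 = %.4f (SE %.4g), theta2 = %.4f (SE %.4g)\n",
      x$theta1, x$theta1_se, x$theta2, x$theta2_se
    ))
  }
  invisible(x)
}

#' @export
as.matrix.transition_matrix <- function(x, ...) {
  matrix(
    c(x$theta1, 1 - x$theta1, 1 - x$theta2, x$theta2),
    nrow = 2, byrow = TRUE,
    dimnames = list(from = c("0", "1"), to = c("0", "1"))
  )
}

#' Fit cohort-specific transition matrices across the panel
#'
#' Convenience wrapper running [count_transitions()] and [estimate_theta()]
#' for every birth cohort (optionally crossed with child type) and returning
#' a tidy table, one row per fit.
#'
#' @param panel A status panel.
#' @param profiles Profiles tibble.
#' @param by_type Also split by child type (default `TRUE`).
#' @return A tibble with cohort (and `child_type`), transition counts,
#'   estimates, standard errors and confidence limits.
#' @export
fit_transitions <- function(panel, profiles, by_type = TRUE) {
  profiles <- as_profiles(profiles)
  cohorts <- sort(unique(profiles$birth_year))
  types <- if (by_type) CHILD_TYPES else NA_character_
  grid <- expand.grid(cohort = cohorts, child_type = types,
                      stringsAsFactors = FALSE)
  rows <- purrr::pmap(grid, function(cohort, child_type) {
    prof <- profiles
    if (!is.na(child_type)) prof <- prof[prof$child_type == child_type, ]
    if (!cohort %in% prof$birth_year) return(NULL)
    cnt <- count_transitions(panel, prof, cohort)
    th <- estimate_theta(cnt)
    tibble::tibble(
      cohort = cohort, child_type = child_type,
      n00 = cnt$n00, n01 = cnt$n01, n10 = cnt$n10, n11 = cnt$n11,
      theta1 = th$theta1, theta1_se = th$theta1_se,
      theta1_lower = th$theta1_lower, theta1_upper = th$theta1_upper,
      theta2 = th$theta2, theta2_se = th$theta2_se,
      theta2_lower = th$theta2_lower, theta2_upper = th$theta2_upper
    )
  })
  dplyr::bind_rows(rows)
}

#' Observed return probability at a reference year
#'
#' The empirical fraction of a cohort in the returned state at one observed
#' year, used to initialise projections (it equals [return_rate()] / 100).
#'
#' @inheritParams return_rate
#' @return A probability in `[0, 1]`.
#' @export
initial_state <- function(panel, profiles, cohort, year, ...) {
  rr <- return_rate(panel, profiles, cohort, year, ...)
  if (rr$n == 0) abort(paste0("no children in cohort ", cohort))
  rr$rate / 100
}

#' Project the return probability forward
#'
#' Iterates the one-step recursion
#' `p_{t+1} = p_t * theta2 + (1 - p_t) * (1 - theta1)` from a starting
#' probability, equivalently the second component of `(1 - p0, p0)` times
#' the t-step matrix power. The chain converges geometrically (factor
#' `|theta1 + theta2 - 1|`) to the stationary limit
#' `p* = (1 - theta1) / ((1 - theta1) + (1 - theta2))` whenever either
#' off-diagonal probability is positive.
#'
#' @param matrix A `"transition_matrix"` (fully estimable) or anything with
#'   `theta1`, `theta2` elements.
#' @param p0 Starting probability of the returned state.
#' @param steps Number of years to project (`>= 0`).
#' @param from_year Optional calendar year of `p0`; if given, the result
#'   carries a `year` column.
#' @return A tibble of class `"projection"` with columns `step` (0 ...
#'   `steps`), optionally `year`, and `p`; attributes `theta1`, `theta2`,
#'   `p_star` (stationary limit, `NA` when both rows are absorbing) and
#'   `cohort`.
#' @export
project_return <- function(matrix, p0, steps, from_year = NULL) {
  th1 <- matrix$theta1
  th2 <- matrix$theta2
  if (inherits(matrix, "transition_matrix") &&
      !(matrix$theta1_estimable && matrix$theta2_estimable)) {
    abort(paste0(
      "transition matrix not fully estimable (a row has no exposure); ",
      "pool adjacent cohorts or supply probabilities directly"
    ))
  }
  stopifnot(p0 >= 0, p0 <= 1, steps >= 0)
  p <- numeric(steps + 1)
  p[1] <- p0
  if (steps > 0) {
    for (t in seq_len(steps)) {
      p[t + 1] <- p[t] * th2 + (1 - p[t]) * (1 - th1)
    }
  }
  denom <- (1 - th1) + (1 - th2)
  p_star <- if (denom > 0) (1 - th1) / denom else NA_real_
  out <- tibble::tibble(step = 0:steps, p = p)
  if (!is.null(from_year)) {
    out <- tibble::add_column(out, year = from_year + 0:steps,
                              .after = "step")
  }
  structure(
    out,
    class = c("projection", class(out)),
    theta1 = th1, theta2 = th2, p_star = p_star,
    cohort = matrix$cohort %||% NA_integer_
  )
}

#' Expected number of returnees across cohorts
#'
#' Sums `N_j * p_{j}` over cohorts, where `N_j` is the cohort size and
#' `p_j` the projected probability of the returned state at the year in
#' which cohort `j` reaches `target_age`. A named rate map can replace the
#' projections to evaluate an alternative scenario (e.g. official
#' survey-based return rates) on the same cohort sizes.
#'
#' @param cohort_sizes Named numeric vector (names = cohort years) or a
#'   tibble with columns `cohort`, `n`.
#' @param projections Named list of [project_return()] results keyed by
#'   cohort year; each must carry a `year` column reaching
#'   `cohort + target_age`. Ignored when `scenario_rates` is given.
#' @param target_age Age at which returnees are counted.
#' @param scenario_rates Optional named probability vector (names = cohort
#'   years) overriding the projections.
#' @param scenario Free-text label carried in the result.
#' @return A list of class `"returnee_aggregate"`: `total` (expected
#'   returnees), `per_cohort` tibble (`cohort`, `n`, `year`, `p`,
#'   `expected`), `target_age`, `scenario`.
#' @export
aggregate_returnees <- function(cohort_sizes, projections = NULL,
                                target_age, scenario_rates = NULL,
                                scenario = "projected") {
  if (is.data.frame(cohort_sizes)) {
    sizes <- setNames(cohort_sizes$n, cohort_sizes$cohort)
  } else {
    sizes <- cohort_sizes
  }
  if (is.null(names(sizes))) abort("cohort_sizes must be named by cohort year")
  cohorts <- as.integer(names(sizes))
  p <- vapply(seq_along(cohorts), function(i) {
    j <- cohorts[i]
    if (!is.null(scenario_rates)) {
      pj <- scenario_rates[[as.character(j)]]
      if (is.null(pj) || is.na(pj)) {
        abort(paste0("scenario_rates missing cohort ", j))
      }
      return(pj)
    }
    proj <- projections[[as.character(j)]]
    if (is.null(proj)) abort(paste0("projections missing cohort ", j))
    if (!"year" %in% names(proj)) {
      abort("projections must carry a year column (use from_year =)")
    }
    hit <- which(proj$year == j + target_age)
    if (length(hit) != 1) {
      abort(paste0("projection for cohort ", j, " does not reach age ",
                   target_age))
    }
    proj$p[hit]
  }, numeric(1))
  per_cohort <- tibble::tibble(
    cohort = cohorts, n = as.numeric(sizes),
    year = cohorts + target_age, p = p, expected = as.numeric(sizes) * p
  )
  structure(
    list(
      total = sum(per_cohort$expected),
      per_cohort = per_cohort,
      target_age = target_age,
      scenario = scenario
    ),
    class = "returnee_aggregate"
  )
}

#' @export
print.returnee_aggregate <- function(x, ...) {
  cat(sprintf(
    "Expected returnees by age %d (%s scenario): %.0f of %.0f children\n",
    x$target_age, x$scenario, x$total, sum(x$per_cohort$n)
  ))
  invisible(x)
}
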