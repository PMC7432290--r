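#' Configuration for the synthetic microdata generator
#'
#' Describes a synthetic study population whose yearly returned status
#' follows a cohort-specific two-state Markov chain, rendered as plausible
#' arrival/departure event streams. The generator emulates the structure of
#' the confidential immigration movement records: cohort-stratified
#' populations of Type A / Type B children with parental-education
#' covariates drawn from configurable categorical distributions.
#'
#' @param cohort_years Birth-cohort years.
#' @param cohort_sizes Children per cohort (recycled).
#' @param theta1,theta2 Per-cohort transition probabilities (recycled):
#'   `theta1` = stay not-returned, `theta2` = stay returned.
#' @param p0 Per-cohort probability of being in the returned state in the
#'   birth year (recycled). Default 0.35: most newborns are brought back to
#'   the Mainland within about a month of birth, but a substantial minority
#'   of families (mostly Type A, with a resident father) keep the child in
#'   Hong Kong through its first year.
#' @param type_share_a Probability a child is Type A (father a Hong Kong
#'   resident); default 0.25, the approximate share of Type A among
#'   Mainland-parent births (about 10% of all births Type A vs 30% Type B).
#' @param edu_probs_a,edu_probs_b Categorical education distributions over
#'   levels `0,1,2,3,4,X` for parents of Type A / Type B children, applied
#'   independently to mother and father. Defaults skew Type B parents
#'   towards tertiary education, as observed on the registration forms.
#' @param observation_end_year Last observed calendar year (default 2016).
#' @param night_threshold Nights within one half-year window required for
#'   the returned classification (default 31).
#' @param persist_prob When two consecutive years are both returned, the
#'   probability that the rendered stay runs continuously across the year
#'   boundary instead of closing and re-opening (default 0.5); exercises
#'   open-ended presence intervals.
#' @param visit_prob Probability that a not-returned child-year still shows
#'   a short leisure visit of at most 7 nights (default 0.2).
#' @param scattered Render returned years as several separate short stays
#'   summing past the threshold, instead of one long stay (default
#'   `FALSE`); exercises the "not necessarily consecutive" clause.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A list of class `"sim_config"` with a per-cohort tibble
#'   `cohorts` (`cohort`, `size`, `theta1`, `theta2`, `p0`) and the scalar
#'   settings above.
#' @export
sim_config <- function(cohort_years = 2004:2005,
                       cohort_sizes = 1000L,
                       theta1 = 0.9, theta2 = 0.8, p0 = 0.35,
                       type_share_a = 0.25,
                       edu_probs_a = c("0" = 0.02, "1" = 0.15, "2" = 0.55,
                                       "3" = 0.13, "4" = 0.10, "X" = 0.05),
                       edu_probs_b = c("0" = 0.01, "1" = 0.08, "2" = 0.45,
                                       "3" = 0.20, "4" = 0.21, "X" = 0.05),
                       observation_end_year = 2016L,
                       night_threshold = 31L,
                       persist_prob = 0.5,
                       visit_prob = 0.2,
                       scattered = FALSE,
                       seed = 1L) {
  cohorts <- tibble::tibble(
    cohort = as.integer(cohort_years),
    size = as.integer(rep_len(cohort_sizes, length(cohort_years))),
    theta1 = rep_len(theta1, length(cohort_years)),
    theta2 = rep_len(theta2, length(cohort_years)),
    p0 = rep_len(p0, length(cohort_years))
  )
  stopifnot(
    all(cohorts$size >= 0),
    all(cohorts$theta1 >= 0 & cohorts$theta1 <= 1),
    all(cohorts$theta2 >= 0 & cohorts$theta2 <= 1),
    all(cohorts$p0 >= 0 & cohorts$p0 <= 1),
    type_share_a >= 0, type_share_a <= 1,
    persist_prob >= 0, persist_prob <= 1,
    visit_prob >= 0, visit_prob <= 1,
    all(cohorts$cohort <= observation_end_year)
  )
  check_probs <- function(p, what) {
    if (!setequal(names(p), EDU_LEVELS) || abs(sum(p) - 1) > 1e-8) {
      abort(paste0(what, " must be named over ", paste(EDU_LEVELS, collapse = ","),
                   " and sum to 1"))
    }
    p[EDU_LEVELS]
  }
  structure(
    list(
      cohorts = cohorts,
      type_share_a = type_share_a,
      edu_probs_a = check_probs(edu_probs_a, "edu_probs_a"),
      edu_probs_b = check_probs(edu_probs_b, "edu_probs_b"),
      observation_end_year = as.integer(observation_end_year),
      night_threshold = as.integer(night_threshold),
      persist_prob = persist_prob,
      visit_prob = visit_prob,
      scattered = isTRUE(scattered),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Generate synthetic child profiles
#'
#' Draws the cohort-stratified population: child type with probability
#' `type_share_a`, and mother's/father's education level independently from
#' the type-specific categorical distribution. Deterministic for a fixed
#' `config$seed`; the RNG state of the caller is left untouched.
#'
#' @param config A [sim_config()].
#' @return A profiles tibble (see [as_profiles()]).
#' @export
generate_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_preserve_seed()
  set.seed(config$seed)
  ch <- config$cohorts
  n <- sum(ch$size)
  if (n == 0) {
    return(as_profiles(tibble::tibble(
      child_id = character(), birth_year = integer(),
      child_type = character(), mother_edu = character(),
      father_edu = character()
    )))
  }
  birth_year <- rep(ch$cohort, ch$size)
  type <- ifelse(runif(n) < config$type_share_a, "A", "B")
  draw_edu <- function(is_a) {
    out <- character(n)
    for (ty in c(TRUE, FALSE)) {
      idx <- which(is_a == ty)
      if (length(idx) > 0) {
        p <- if (ty) config$edu_probs_a else config$edu_probs_b
        out[idx] <- sample(EDU_LEVELS, length(idx), replace = TRUE, prob = p)
      }
    }
    out
  }
  is_a <- type == "A"
  as_profiles(tibble::tibble(
    child_id = sprintf("C%06d", seq_len(n)),
    birth_year = birth_year,
    child_type = type,
    mother_edu = draw_edu(is_a),
    father_edu = draw_edu(is_a)
  ))
}

#' Simulate Markov status paths
#'
#' Runs the cohort-specific two-state chain generatively: the birth-year
#' status is Bernoulli(`p0`), and each subsequent year's status follows the
#' transition matrix (stay not-returned with `theta1`, stay returned with
#' `theta2`), from birth to `observation_end_year`.
#'
#' @param config A [sim_config()].
#' @param profiles Profiles for the population; defaults to
#'   [generate_profiles()] on the same config.
#' @return A status panel (class `"status_panel"`).
#' @export
generate_status_paths <- function(config, profiles = generate_profiles(config)) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_preserve_seed()
  set.seed(config$seed + 1L)
  end_year <- config$observation_end_year
  pieces <- purrr::pmap(config$cohorts, function(cohort, size, theta1, theta2, p0) {
    ids <- profiles$child_id[profiles$birth_year == cohort]
    stopifnot(length(ids) == size)
    if (size == 0) return(NULL)
    years <- cohort:end_year
    m <- matrix(0L, nrow = size, ncol = length(years))
    m[, 1] <- rbinom(size, 1L, p0)
    for (t in seq_along(years)[-1]) {
      prev <- m[, t - 1]
      stay1 <- rbinom(size, 1L, theta2)
      move01 <- rbinom(size, 1L, 1 - theta1)
      m[, t] <- ifelse(prev == 1L, stay1, move01)
    }
    tibble::tibble(
      child_id = rep(ids, times = length(years)),
      year = rep(years, each = size),
      status = as.integer(m)
    )
  })
  panel <- dplyr::arrange(dplyr::bind_rows(pieces), .data$child_id, .data$year)
  structure(
    panel,
    class = c("status_panel", class(panel)),
    observation_end_year = end_year,
    night_threshold = config$night_threshold
  )
}

#' Render a status panel as movement events
#'
#' The inverse of the classification: for each returned child-year, emit
#' stays totalling at least the night threshold inside one half-year window
#' (by default one long stay arriving in spring; with `scattered = TRUE`,
#' several non-consecutive short stays); for a not-returned year, emit
#' nothing or a short visit well under the threshold. Consecutive returned
#' years may be rendered as one continuous stay across the year boundary
#' (probability `persist_prob`), exercising open intervals.
#'
#' The construction guarantees the round trip: classifying the rendered
#' events with [build_status_panel()] reproduces `panel` cell for cell.
#'
#' @param panel A status panel.
#' @param config The [sim_config()] that produced it.
#' @return An events tibble in canonical order.
#' @export
render_events <- function(panel, config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_preserve_seed()
  set.seed(config$seed + 2L)
  thr <- config$night_threshold
  rows <- lapply(split(tibble::as_tibble(panel), panel$child_id), function(df) {
    df <- df[order(df$year), ]
    s <- df$status
    yrs <- df$year
    nT <- length(s)
    dates <- as.Date(character())
    dirs <- character()
    present <- FALSE   # carried across the year boundary by a persisting stay
    for (t in seq_len(nT)) {
      y <- yrs[t]
      persist_next <- FALSE
      if (s[t] == 1L) {
        if (present) {
          # stay continues from last year: keep it until the H1 night count
          # reaches the threshold, then depart
          dep <- as.Date(sprintf("%d-01-01", y)) + thr + sample(0:20, 1)
          dates <- c(dates, dep); dirs <- c(dirs, "departure")
          present <- FALSE
        } else if (config$scattered) {
          # several separate stays in H1 summing past the threshold
          k <- 5L
          per <- ceiling((thr + 4L) / k)
          arr0 <- as.Date(sprintf("%d-01-15", y)) + sample(0:6, 1)
          for (i in seq_len(k)) {
            arr <- arr0 + (i - 1L) * (per + 7L)
            dates <- c(dates, arr, arr + per)
            dirs <- c(dirs, "arrival", "departure")
          }
        } else {
          arr <- as.Date(sprintf("%d-02-01", y)) + sample(0:59, 1)
          stay <- thr + 3L + sample(0:19, 1)
          dates <- c(dates, arr); dirs <- c(dirs, "arrival")
          if (t < nT && s[t + 1L] == 1L && runif(1) < config$persist_prob) {
            persist_next <- TRUE      # no departure: stay spans the boundary
          } else {
            dates <- c(dates, arr + stay); dirs <- c(dirs, "departure")
          }
        }
        # a persisting stay may instead start late in the year
        if (!persist_next && !present && !config$scattered &&
            t < nT && s[t + 1L] == 1L && runif(1) < config$persist_prob / 2) {
          arr2 <- as.Date(sprintf("%d-10-01", y)) + sample(0:30, 1)
          dates <- c(dates, arr2); dirs <- c(dirs, "arrival")
          persist_next <- TRUE
        }
      } else if (runif(1) < config$visit_prob) {
        # short leisure visit, at most 7 nights: stays under the threshold
        month <- sample(c(3L, 9L), 1)
        arr <- as.Date(sprintf("%d-%02d-01", y, month)) + sample(0:19, 1)
        dates <- c(dates, arr, arr + sample(1:7, 1))
        dirs <- c(dirs, "arrival", "departure")
      }
      present <- persist_next
    }
    if (length(dates) == 0) return(NULL)
    tibble::tibble(child_id = df$child_id[1], date = dates, direction = dirs)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(child_id = character(), date = as.Date(character()),
                          direction = character())
  }
  canonical_order(out)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: profiles, Markov status paths, and the rendered
#' movement-event stream, all from one seeded configuration.
#'
#' @param config A [sim_config()].
#' @return A list with `profiles`, `panel` (the generating truth) and
#'   `events`.
#' @export
simulate_dataset <- function(config) {
  profiles <- generate_profiles(config)
  panel <- generate_status_paths(config, profiles)
  events <- render_events(panel, config)
  list(profiles = profiles, panel = panel, events = events)
}
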