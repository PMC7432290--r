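#' Load a pipeline run configuration
#'
#' Reads a YAML file of key/value settings for [run_pipeline()]. Recognised
#' keys mirror the [sim_config()] arguments plus `out_dir`, `target_age`,
#' `horizon_year` and `stratify_by`; unknown keys abort. Command-line flags
#' (or function arguments) override file values.
#'
#' @param path Path to a YAML config file.
#' @return A named list of settings.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c(
    "cohort_years", "cohort_sizes", "theta1", "theta2", "p0",
    "type_share_a", "edu_probs_a", "edu_probs_b", "observation_end_year",
    "night_threshold", "persist_prob", "visit_prob", "scattered", "seed",
    "out_dir", "target_age", "horizon_year", "stratify_by",
    "events", "profiles"
  )
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Wires the stages end to end: simulate (or load) movement events and
#' profiles, classify yearly returned status, tabulate return rates, fit
#' cohort-specific transition matrices, project return probabilities to a
#' horizon year, and aggregate expected returnees at a target age. Every
#' intermediate is written to `out_dir` as CSV, and a text summary reports
#' row counts per stage. Deterministic for a fixed seed.
#'
#' @param config A [sim_config()] (synthetic run), or a named list from
#'   [read_run_config()]. A list with `events` and `profiles` paths runs on
#'   supplied data instead of simulating.
#' @param out_dir Output directory (created if needed).
#' @param target_age Age at which aggregate returnees are counted
#'   (default 21).
#' @param horizon_year Last projected calendar year; default 14 years past
#'   the observation end.
#' @param stratify_by Stratification for the education rate tables:
#'   `"none"`, `"mother_edu"` or `"father_edu"`.
#' @return Invisibly, a list with `panel`, `rates`, `fits`, `projections`,
#'   `aggregate` and the paths written.
#' @export
run_pipeline <- function(config, out_dir,
                         target_age = 21L,
                         horizon_year = NULL,
                         stratify_by = "none") {
  if (!inherits(config, "sim_config") && is.list(config) &&
      is.null(config$events)) {
    args <- config[setdiff(names(config),
                           c("out_dir", "target_age", "horizon_year",
                             "stratify_by", "events", "profiles"))]
    config <- do.call(sim_config, args)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  log <- function(...) inform(paste0("[pipeline] ", sprintf(...)))

  if (inherits(config, "sim_config")) {
    sim <- simulate_dataset(config)
    profiles <- sim$profiles
    events <- sim$events
    end_year <- config$observation_end_year
    thr <- config$night_threshold
    paths$events <- file.path(out_dir, "events.csv")
    paths$profiles <- file.path(out_dir, "profiles.csv")
    readr::write_csv(events[, c("child_id", "date", "direction")],
                     paths$events)
    readr::write_csv(profiles, paths$profiles)
    log("simulated %d children, %d movement events",
        nrow(profiles), nrow(events))
  } else {
    events <- read_events(config$events)
    profiles <- read_profiles(config$profiles)
    end_year <- config$observation_end_year %||%
      as.integer(format(max(events$date), "%Y"))
    thr <- config$night_threshold %||% 31L
    log("loaded %d children, %d movement events",
        nrow(profiles), nrow(events))
  }

  panel <- build_status_panel(profiles, events, end_year,
                              night_threshold = thr)
  paths$panel <- file.path(out_dir, "status_panel.csv")
  write_status_panel(panel, paths$panel)
  log("classified %d child-year statuses", nrow(panel))

  rates <- rate_table(panel, profiles, stratify_by = stratify_by)
  paths$rates <- file.path(out_dir, "return_rates.csv")
  readr::write_csv(tibble::as_tibble(rates), paths$rates)
  small <- sum(rates$small_cell)
  if (small > 0) {
    warn(paste0(small, " rate cell(s) have denominators < 30; ",
                "their rates are unstable"))
  }
  log("tabulated %d rate cells", nrow(rates))

  fits <- fit_transitions(panel, profiles, by_type = TRUE)
  paths$fits <- file.path(out_dir, "transitions.csv")
  readr::write_csv(fits, paths$fits)
  log("fitted %d cohort x type transition matrices", nrow(fits))

  horizon_year <- horizon_year %||% (end_year + 14L)
  cohorts <- sort(unique(profiles$birth_year))
  projections <- list()
  proj_rows <- list()
  for (j in cohorts) {
    cnt <- count_transitions(panel, profiles, j)
    th <- estimate_theta(cnt)
    if (!(th$theta1_estimable && th$theta2_estimable)) {
      warn(paste0("cohort ", j, " transition matrix not fully estimable; ",
                  "skipped in projections"))
      next
    }
    p0 <- initial_state(panel, profiles, j, end_year)
    pr <- project_return(th, p0, steps = horizon_year - end_year,
                         from_year = end_year)
    projections[[as.character(j)]] <- pr
    proj_rows[[as.character(j)]] <- tibble::add_column(
      tibble::as_tibble(pr), cohort = j, .before = 1
    )
  }
  paths$projections <- file.path(out_dir, "projections.csv")
  readr::write_csv(dplyr::bind_rows(proj_rows), paths$projections)
  log("projected %d cohorts to %d", length(projections), horizon_year)

  sizes <- table(profiles$birth_year)
  agg_cohorts <- intersect(names(projections), names(sizes))
  agg_cohorts <- agg_cohorts[
    as.integer(agg_cohorts) + target_age <= horizon_year
  ]
  aggregate <- NULL
  if (length(agg_cohorts) > 0) {
    aggregate <- aggregate_returnees(
      setNames(as.numeric(sizes[agg_cohorts]), agg_cohorts),
      projections[agg_cohorts], target_age
    )
    log("expected returnees by age %d: %.0f", target_age, aggregate$total)
  } else {
    log("no cohort reaches age %d by %d; aggregation skipped",
        target_age, horizon_year)
  }

  paths$summary <- file.path(out_dir, "summary.txt")
  writeLines(c(
    sprintf("children: %d", nrow(profiles)),
    sprintf("events: %d", nrow(events)),
    sprintf("child-year statuses: %d", nrow(panel)),
    sprintf("rate cells: %d (small: %d)", nrow(rates), small),
    sprintf("fits: %d", nrow(fits)),
    sprintf("projection horizon: %d", horizon_year),
    if (!is.null(aggregate)) {
      sprintf("expected returnees by age %d: %.1f", target_age,
              aggregate$total)
    } else {
      sprintf("aggregation skipped (no cohort reaches age %d)", target_age)
    }
  ), paths$summary)

  invisible(list(
    panel = panel, rates = rates, fits = fits,
    projections = projections, aggregate = aggregate, paths = paths
  ))
}
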