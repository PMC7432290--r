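#' Read border-crossing movement events
#'
#' Reads a CSV of border-crossing records, one row per crossing, with columns
#' `child_id`, `date` (ISO-8601) and `direction` (`"arrival"` into Hong Kong
#' or `"departure"` out of it). Rows are returned grouped by child and ordered
#' by date, with the original file order retained as `source_order` so that
#' same-day ties can be resolved reproducibly.
#'
#' @param path Path to the events CSV. Must have a header
#'   `child_id,date,direction`.
#' @return A tibble with columns `child_id` (character), `date` (`Date`),
#'   `direction` (factor, levels `arrival`, `departure`) and `source_order`
#'   (integer row rank in the input file), arranged by
#'   `(child_id, date, source_order)`.
#' @details Malformed dates and unknown directions abort with the offending
#'   row numbers. Exact duplicate rows are legal (two crossings can be
#'   recorded identically) and are kept; a data-quality message reports how
#'   many were seen.
#' @seealso [canonical_order()], [build_intervals()]
#' @export
read_events <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("events file not found: ", path))
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      child_id = readr::col_character(),
      date = readr::col_character(),
      direction = readr::col_character()
    )
  )
  if (!all(c("child_id", "date", "direction") %in% names(raw))) {
    abort("events CSV must have columns child_id, date, direction")
  }
  ev <- as_events(raw)
  ev <- dplyr::arrange(ev, .data$child_id, .data$date, .data$source_order)
  dup <- sum(duplicated(raw))
  if (dup > 0) {
    inform(paste0("read_events: ", dup, " exact duplicate row(s) kept"))
  }
  ev
}

#' Validate and normalise a raw events table
#'
#' Accepts a data frame with `child_id`, `date`, `direction` columns (dates as
#' `Date` or ISO-8601 strings), validates them, assigns `source_order` from
#' row position if absent, and arranges by `(child_id, date, source_order)`.
#'
#' @param x A data frame of movement events.
#' @return A validated events tibble (see [read_events()]).
#' @export
as_events <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"source_order" %in% names(x)) {
    x$source_order <- seq_len(nrow(x))
  }
  date <- x$date
  if (!inherits(date, "Date")) {
    parsed <- as.Date(as.character(date), format = "%Y-%m-%d")
    bad <- which(is.na(parsed) & !is.na(date))
    if (length(bad) > 0) {
      abort(paste0(
        "malformed date(s) at row(s): ", paste(head(bad, 10L), collapse = ", ")
      ))
    }
    date <- parsed
  }
  if (anyNA(date)) {
    abort(paste0(
      "missing date(s) at row(s): ",
      paste(head(which(is.na(date)), 10L), collapse = ", ")
    ))
  }
  dir_chr <- as.character(x$direction)
  bad_dir <- which(!dir_chr %in% DIRECTIONS)
  if (length(bad_dir) > 0) {
    abort(paste0(
      "unknown direction(s) at row(s): ",
      paste(head(bad_dir, 10L), collapse = ", "),
      " (values: ",
      paste(unique(dir_chr[head(bad_dir, 10L)]), collapse = ", "), ")"
    ))
  }
  # validation only -- row order is the caller's business (read_events sorts,
  # canonical_order applies the same-day rule)
  tibble::tibble(
    child_id = as.character(x$child_id),
    date = date,
    direction = factor(dir_chr, levels = DIRECTIONS),
    source_order = as.integer(x$source_order)
  )
}

#' Apply the same-day ordering rule
#'
#' When a child has more than one record on the same day, the arrival is
#' assumed to have happened before the departure. This reorders an events
#' table so that, within each `(child_id, date)`, arrivals precede
#' departures; otherwise the original file order (`source_order`) is kept
#' (a stable sort on the direction key).
#'
#' @param events An events tibble (see [read_events()]).
#' @return The events tibble in canonical order.
#' @export
canonical_order <- function(events) {
  events <- as_events(events)
  dplyr::arrange(
    events,
    .data$child_id, .data$date, as.integer(.data$direction), .data$source_order
  )
}

#' Build presence intervals from one child's ordered events
#'
#' Converts a canonically ordered event stream into maximal half-open
#' presence intervals `[start, end)`: an arrival opens a stay, the next
#' departure closes it (the departure date itself is not a night spent in
#' Hong Kong). Two boundary rules implement the "already resident"
#' convention: a leading departure implies presence since `period_start`
#' (flagged `open_start`), and a trailing arrival implies presence until
#' `period_end` inclusive (flagged `open_end`).
#'
#' @param events Events of one or more children, in canonical order
#'   (see [canonical_order()]).
#' @param period_start,period_end First and last calendar date of the
#'   observation period (`Date` or ISO-8601 string). Either a single value
#'   applied to all children, or named vectors keyed by `child_id` (a child
#'   born mid-study is only observable from its birth year on).
#' @return A tibble with columns `child_id`, `start` (inclusive `Date`),
#'   `end` (exclusive `Date`), `open_start`, `open_end`. Intervals of one
#'   child are disjoint, sorted, and clipped to the observation period.
#' @details Consecutive events in the same direction (e.g. two arrivals with
#'   no departure between them) are collapsed to the first; a data-quality
#'   message reports the count. A same-day arrival and departure yields an
#'   empty interval, which contributes zero nights and is dropped. Events out
#'   of canonical order abort.
#' @export
build_intervals <- function(events, period_start, period_end) {
  events <- as_events(events)
  ps <- as.Date(period_start)
  pe <- as.Date(period_end)
  if (anyNA(ps) || anyNA(pe)) abort("period_start/period_end must be dates")
  one_ps <- length(ps) == 1L && is.null(names(ps))
  one_pe <- length(pe) == 1L && is.null(names(pe))
  if (one_ps && one_pe && ps > pe) abort("period_start must be <= period_end")

  check_canonical(events)

  collapsed <- 0L
  pieces <- lapply(split(events, events$child_id), function(ev) {
    cps <- if (one_ps) ps else ps[[ev$child_id[1]]]
    cpe <- if (one_pe) pe else pe[[ev$child_id[1]]]
    dir <- as.integer(ev$direction)  # 1 arrival, 2 departure
    keep <- c(TRUE, dir[-1L] != dir[-length(dir)])
    collapsed <<- collapsed + sum(!keep)
    dt <- ev$date[keep]
    dir <- dir[keep]
    open_start <- FALSE
    open_end <- FALSE
    if (dir[1L] == 2L) {      # leading departure: resident since period start
      dt <- c(cps, dt)
      open_start <- TRUE
    }
    if (dir[length(dir)] == 1L || length(dt) %% 2L == 1L) {
      # trailing arrival: resident until the end of the period
      dt <- c(dt, cpe + 1L)
      open_end <- TRUE
    }
    n <- length(dt) %/% 2L
    start <- dt[2L * seq_len(n) - 1L]
    end <- dt[2L * seq_len(n)]
    # clip to the observation period, drop empty stays
    start <- pmax(start, cps)
    end <- pmin(end, cpe + 1L)
    ok <- start < end
    tibble::tibble(
      child_id = ev$child_id[1L],
      start = start[ok],
      end = end[ok],
      open_start = c(open_start, rep(FALSE, n - 1L))[ok],
      open_end = c(rep(FALSE, n - 1L), open_end)[ok]
    )
  })
  if (collapsed > 0) {
    inform(paste0(
      "build_intervals: collapsed ", collapsed,
      " consecutive same-direction event(s) to the first of each run"
    ))
  }
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      child_id = character(), start = as.Date(character()),
      end = as.Date(character()), open_start = logical(), open_end = logical()
    )
  }
  out
}

check_canonical <- function(events) {
  by_child <- split(seq_len(nrow(events)), events$child_id)
  for (idx in by_child) {
    d <- events$date[idx]
    if (is.unsorted(d)) abort("events out of order: dates must be nondecreasing within child")
    key <- as.numeric(d) * 4 + as.integer(events$direction[idx])
    if (is.unsorted(key)) {
      abort("events out of order: same-day arrivals must precede departures (run canonical_order())")
    }
  }
  invisible(events)
}

#' Half-year window
#'
#' The "returned" definition counts nights within a six-month period before
#' or after mid-year (30 June). `half_year()` constructs the corresponding
#' calendar window: H1 is 1 January to 30 June, H2 is 1 July to 31 December.
#'
#' @param year Calendar year.
#' @param half `"H1"` or `"H2"`.
#' @return A list with `year`, `half`, `start` (first date, inclusive) and
#'   `end` (one past the last date, exclusive), of class `"half_year"`.
#' @export
half_year <- function(year, half = c("H1", "H2")) {
  half <- match.arg(half)
  start <- if (half == "H1") as.Date(sprintf("%d-01-01", year))
           else as.Date(sprintf("%d-07-01", year))
  end <- if (half == "H1") as.Date(sprintf("%d-07-01", year))
         else as.Date(sprintf("%d-01-01", year + 1))
  structure(list(year = year, half = half, start = start, end = end),
            class = "half_year")
}

#' Count nights spent in Hong Kong within a half-year window
#'
#' A night is attributed to the calendar date on which it begins, so a
#' presence interval `[start, end)` contributes `end - start` nights. The
#' count is the number of dates in the window covered by some interval.
#'
#' @param intervals A presence-interval tibble (see [build_intervals()]);
#'   intervals must be disjoint.
#' @param window A [half_year()] window.
#' @return Integer night count in `[0, window length]`.
#' @export
nights_in_window <- function(intervals, window) {
  stopifnot(inherits(window, "half_year"))
  if (nrow(intervals) == 0) return(0L)
  ov <- pmin(as.numeric(intervals$end), as.numeric(window$end)) -
    pmax(as.numeric(intervals$start), as.numeric(window$start))
  as.integer(sum(pmax(0, ov)))
}

#' Classify the yearly "returned" status of one child
#'
#' A child counts as returned in a year if they stayed in Hong Kong at least
#' `threshold` nights (31 by default, not necessarily consecutive) within
#' either calendar half of that year.
#'
#' @param intervals Presence intervals of one child.
#' @param year Calendar year to classify.
#' @param threshold Minimum nights within one half-year window (default 31).
#' @return `1L` (returned) or `0L` (not returned).
#' @export
classify_returned <- function(intervals, year, threshold = 31L) {
  h1 <- nights_in_window(intervals, half_year(year, "H1"))
  if (h1 >= threshold) return(1L)
  h2 <- nights_in_window(intervals, half_year(year, "H2"))
  if (h2 >= threshold) return(1L)
  0L
}

#' Read child profile records
#'
#' Reads the profile CSV: `child_id`, `birth_year`, `child_type` (`A`:
#' father a Hong Kong resident; `B`: father not a resident), and mother's
#' and father's education-level codes (`0` no schooling/kindergarten, `1`
#' primary, `2` secondary/matriculation, `3` tertiary non-degree, `4`
#' tertiary degree, `X` unknown). Missing education fields map to `X`.
#'
#' @param path Path to the profiles CSV.
#' @return A validated profiles tibble.
#' @export
read_profiles <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      child_id = readr::col_character(),
      birth_year = readr::col_integer(),
      child_type = readr::col_character(),
      mother_edu = readr::col_character(),
      father_edu = readr::col_character()
    )
  )
  as_profiles(raw)
}

#' Validate a child-profile table
#'
#' @param x A data frame with columns `child_id`, `birth_year`,
#'   `child_type`, `mother_edu`, `father_edu`.
#' @return A profiles tibble with factor-coded type and education levels.
#' @export
as_profiles <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("child_id", "birth_year", "child_type", "mother_edu", "father_edu")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("profiles missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(x$child_id)) abort("duplicate child_id in profiles")
  ct <- as.character(x$child_type)
  if (!all(ct %in% CHILD_TYPES)) {
    abort("child_type must be 'A' or 'B'")
  }
  fix_edu <- function(e) {
    e <- as.character(e)
    e[is.na(e) | e == ""] <- "X"
    if (!all(e %in% EDU_LEVELS)) {
      abort(paste0(
        "education codes must be one of ", paste(EDU_LEVELS, collapse = ", ")
      ))
    }
    factor(e, levels = EDU_LEVELS)
  }
  tibble::tibble(
    child_id = as.character(x$child_id),
    birth_year = as.integer(x$birth_year),
    child_type = factor(ct, levels = CHILD_TYPES),
    mother_edu = fix_edu(x$mother_edu),
    father_edu = fix_edu(x$father_edu)
  )
}

#' Build the per-child, per-year returned-status panel
#'
#' Runs the full classification for every child: canonical ordering of
#' events, presence-interval construction over the child's observation
#' period (birth year to `observation_end_year`), night counting per
#' half-year window, and thresholding. Children with no movement events are
#' not returned in every year.
#'
#' @param profiles Profiles tibble (see [as_profiles()]).
#' @param events Events tibble (see [read_events()]); every `child_id` must
#'   exist in `profiles`.
#' @param observation_end_year Last calendar year of the panel.
#' @param observation_start_year First year any movement is observable;
#'   defaults to the earliest birth year. A child's own period starts at the
#'   later of this and its birth year.
#' @param night_threshold Minimum nights within one half-year window
#'   (default 31).
#' @return A status panel: tibble with columns `child_id`, `year`, `status`
#'   (0/1), one row per child per year from its birth year to
#'   `observation_end_year`, of class `"status_panel"` with attributes
#'   `observation_end_year` and `night_threshold`.
#' @export
build_status_panel <- function(profiles, events, observation_end_year,
                               observation_start_year = NULL,
                               night_threshold = 31L) {
  profiles <- as_profiles(profiles)
  events <- canonical_order(events)
  orphans <- setdiff(unique(events$child_id), profiles$child_id)
  if (length(orphans) > 0) {
    abort(paste0(
      "events reference unknown child_id(s): ",
      paste(head(orphans, 10L), collapse = ", ")
    ))
  }
  if (any(profiles$birth_year > observation_end_year)) {
    abort("birth_year after observation_end_year")
  }
  obs_start <- observation_start_year %||% min(profiles$birth_year)

  start_year <- pmax(profiles$birth_year, obs_start)
  ps <- setNames(as.Date(sprintf("%d-01-01", start_year)), profiles$child_id)
  pe <- setNames(
    rep(as.Date(sprintf("%d-12-31", observation_end_year)), nrow(profiles)),
    profiles$child_id
  )
  intervals <- build_intervals(events, ps, pe)

  grid <- tidyr::expand_grid(
    profiles[, c("child_id", "birth_year")],
    year = seq(min(profiles$birth_year), observation_end_year)
  )
  grid <- grid[grid$year >= grid$birth_year, c("child_id", "year")]

  status <- rep(0L, nrow(grid))
  if (nrow(intervals) > 0) {
    nights <- nights_by_half_year(
      intervals, seq(min(profiles$birth_year), observation_end_year)
    )
    ret <- nights[nights$nights >= night_threshold,
                  c("child_id", "year")]
    ret <- dplyr::distinct(ret)
    key <- paste(grid$child_id, grid$year)
    status[key %in% paste(ret$child_id, ret$year)] <- 1L
  }
  panel <- tibble::tibble(
    child_id = grid$child_id, year = grid$year, status = status
  )
  panel <- dplyr::arrange(panel, .data$child_id, .data$year)
  structure(
    panel,
    class = c("status_panel", class(panel)),
    observation_end_year = as.integer(observation_end_year),
    night_threshold = as.integer(night_threshold)
  )
}

# Nights per (child_id, year, half) for all intervals, vectorised over
# children; loops only over the (few) year x half windows.
nights_by_half_year <- function(intervals, years) {
  res <- vector("list", 2L * length(years))
  k <- 0L
  s <- as.numeric(intervals$start)
  e <- as.numeric(intervals$end)
  for (y in years) {
    for (h in c("H1", "H2")) {
      w <- half_year(y, h)
      ov <- pmax(0, pmin(e, as.numeric(w$end)) - pmax(s, as.numeric(w$start)))
      nz <- ov > 0
      if (any(nz)) {
        agg <- rowsum(ov[nz], intervals$child_id[nz])
        k <- k + 1L
        res[[k]] <- tibble::tibble(
          child_id = rownames(agg), year = y, half = h,
          nights = as.integer(agg[, 1L])
        )
      }
    }
  }
  if (k == 0L) {
    return(tibble::tibble(
      child_id = character(), year = integer(), half = character(),
      nights = integer()
    ))
  }
  dplyr::bind_rows(res[seq_len(k)])
}

#' Write / read a status panel as a wide CSV
#'
#' One row per child, one column per calendar year, cells 0/1 (empty before
#' the child's birth year).
#'
#' @param panel A status panel (see [build_status_panel()]).
#' @param path Output CSV path.
#' @return `write_status_panel()` returns `path` invisibly;
#'   `read_status_panel()` returns the long status panel.
#' @export
write_status_panel <- function(panel, path) {
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(panel),
    names_from = "year", values_from = "status", names_sort = TRUE
  )
  wide <- dplyr::arrange(wide, .data$child_id)
  readr::write_csv(wide, path, na = "")
  invisible(path)
}

#' @rdname write_status_panel
#' @export
read_status_panel <- function(path) {
  wide <- readr::read_csv(path, col_types = readr::cols(
    child_id = readr::col_character(), .default = readr::col_integer()
  ))
  long <- tidyr::pivot_longer(
    wide, -"child_id", names_to = "year", values_to = "status",
    names_transform = as.integer
  )
  long <- long[!is.na(long$status), ]
  long <- dplyr::arrange(long, .data$child_id, .data$year)
  structure(
    long,
    class = c("status_panel", class(long)),
    observation_end_year = max(long$year),
    night_threshold = NA_integer_
  )
}
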