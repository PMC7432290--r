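test_that("read_events parses, orders and validates the CSV contract", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "child_id,date,direction",
    "c2,2010-05-01,departure",
    "c1,2010-02-01,arrival",
    "c1,2010-03-01,departure"
  ), path)
  ev <- read_events(path)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$child_id, c("c1", "c1", "c2"))
  expect_s3_class(ev$date, "Date")
  expect_equal(as.character(ev$direction),
               c("arrival", "departure", "departure"))

  writeLines("child_id,date,direction", path)
  expect_equal(nrow(read_events(path)), 0)

  writeLines(c(
    "child_id,date,direction",
    "c1,2010-02-01,arrival",
    "c1,2010-03-01,exit"
  ), path)
  expect_error(read_events(path), "direction.*2")

  writeLines(c(
    "child_id,date,direction",
    "c1,2010-13-40,arrival"
  ), path)
  expect_error(read_events(path), "date")

  writeLines(c(
    "child_id,date,direction",
    "c1,2010-02-01,arrival",
    "c1,2010-02-01,arrival"
  ), path)
  expect_message(read_events(path), "duplicate")
})

test_that("same-day events are reordered so the arrival happens first", {
  ev <- make_events(
    c("c1", "c1"), c("2010-05-01", "2010-05-01"),
    c("departure", "arrival")
  )
  out <- canonical_order(ev)
  expect_equal(as.character(out$direction), c("arrival", "departure"))

  # singleton untouched
  one <- canonical_order(make_events("c1", "2010-05-01", "arrival"))
  expect_equal(nrow(one), 1)

  # stable: ties within a direction keep file order
  ev3 <- make_events(
    rep("c1", 3), rep("2010-05-01", 3),
    c("arrival", "arrival", "departure")
  )
  ev3$source_order <- 1:3
  out3 <- canonical_order(ev3)
  expect_equal(as.character(out3$direction),
               c("arrival", "arrival", "departure"))
  expect_equal(out3$source_order, 1:3)
})

test_that("build_intervals pairs arrivals with departures as half-open stays", {
  iv <- build_intervals(
    make_events(c("c1", "c1"), c("2010-02-01", "2010-03-01"),
                c("arrival", "departure")),
    "2010-01-01", "2010-12-31"
  )
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, as.Date("2010-02-01"))
  expect_equal(iv$end, as.Date("2010-03-01"))
  expect_false(iv$open_start)
  expect_false(iv$open_end)
})

test_that("a leading departure means resident since the period start", {
  iv <- build_intervals(
    make_events("c1", "2010-06-01", "departure"),
    "2010-01-01", "2010-12-31"
  )
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, as.Date("2010-01-01"))
  expect_equal(iv$end, as.Date("2010-06-01"))
  expect_true(iv$open_start)
})

test_that("a trailing arrival means resident until the period end", {
  iv <- build_intervals(
    make_events("c1", "2010-12-01", "arrival"),
    "2010-01-01", "2011-12-31"
  )
  expect_equal(iv$end, as.Date("2012-01-01"))
  expect_true(iv$open_end)
  # day-count oracle: 1 Dec 2010 through 31 Dec 2011 inclusive is 396 nights
  expect_equal(as.integer(iv$end - iv$start), 396)
  expect_equal(
    nights_oracle(iv, half_year(2010, "H2")) +
      nights_oracle(iv, half_year(2011, "H1")) +
      nights_oracle(iv, half_year(2011, "H2")),
    396
  )
})

test_that("degenerate event streams are handled per contract", {
  # consecutive arrivals collapse to the first, with a data-quality message
  expect_message(
    iv <- build_intervals(
      make_events(rep("c1", 3),
                  c("2010-02-01", "2010-02-10", "2010-03-01"),
                  c("arrival", "arrival", "departure")),
      "2010-01-01", "2010-12-31"
    ),
    "collapsed"
  )
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, as.Date("2010-02-01"))

  # same-day arrival + departure: an empty stay, zero nights
  iv0 <- build_intervals(
    make_events(c("c1", "c1"), c("2010-02-01", "2010-02-01"),
                c("arrival", "departure")),
    "2010-01-01", "2010-12-31"
  )
  expect_equal(nrow(iv0), 0)

  # a same-day departure-before-arrival that canonical_order would fix aborts
  bad <- make_events(c("c1", "c1"), c("2010-03-01", "2010-03-01"),
                     c("departure", "arrival"))
  bad$source_order <- 1:2
  expect_error(build_intervals(bad, "2010-01-01", "2010-12-31"),
               "canonical_order")
})

test_that("nights_in_window counts nights attributed to their starting date", {
  iv <- build_intervals(
    make_events(c("c1", "c1"), c("2010-01-01", "2010-02-15"),
                c("arrival", "departure")),
    "2010-01-01", "2010-12-31"
  )
  expect_equal(nights_in_window(iv, half_year(2010, "H1")), 45)
  expect_equal(nights_in_window(iv, half_year(2010, "H2")), 0)

  none <- iv[0, ]
  expect_equal(nights_in_window(none, half_year(2010, "H1")), 0)

  full <- build_intervals(
    make_events(c("c1", "c1"), c("2010-01-01", "2011-01-01"),
                c("arrival", "departure")),
    "2010-01-01", "2010-12-31"
  )
  expect_equal(nights_in_window(full, half_year(2010, "H1")), 181)
  expect_equal(nights_in_window(full, half_year(2010, "H2")), 184)
  # leap year first half has one more night
  leap <- build_intervals(
    make_events(c("c1", "c1"), c("2012-01-01", "2013-01-01"),
                c("arrival", "departure")),
    "2012-01-01", "2012-12-31"
  )
  expect_equal(nights_in_window(leap, half_year(2012, "H1")), 182)
})

test_that("night counts match the brute-force oracle and conserve over halves", {
  set.seed(42)
  for (rep in 1:200) {
    ev <- random_event_stream()
    if (nrow(ev) == 0) next
    iv <- suppressMessages(
      build_intervals(canonical_order(ev), "2010-01-01", "2012-12-31")
    )
    for (y in 2010:2012) {
      h1 <- nights_in_window(iv, half_year(y, "H1"))
      h2 <- nights_in_window(iv, half_year(y, "H2"))
      expect_identical(h1, as.integer(nights_oracle(iv, half_year(y, "H1"))))
      expect_identical(h2, as.integer(nights_oracle(iv, half_year(y, "H2"))))
      # conservation: the two halves partition the year's nights
      whole <- structure(
        list(start = as.Date(sprintf("%d-01-01", y)),
             end = as.Date(sprintf("%d-01-01", y + 1))),
        class = "half_year"
      )
      expect_equal(h1 + h2, as.integer(sum(pmax(
        0, pmin(as.numeric(iv$end), as.numeric(whole$end)) -
          pmax(as.numeric(iv$start), as.numeric(whole$start))
      ))))
    }
  }
})

test_that("adding a stay never decreases night counts or flips status to 0", {
  set.seed(99)
  extra <- tibble::tibble(
    child_id = "X",
    start = as.Date("2012-12-20"), end = as.Date("2012-12-31"),
    open_start = FALSE, open_end = FALSE
  )
  for (rep in 1:50) {
    ev <- random_event_stream(max_events = 10)
    iv <- suppressMessages(
      build_intervals(canonical_order(ev), "2010-01-01", "2012-12-31")
    )
    base <- iv[iv$end <= extra$start | iv$start >= extra$end, ]
    aug <- dplyr::bind_rows(base, extra)
    for (y in 2010:2012) {
      for (h in c("H1", "H2")) {
        expect_gte(nights_in_window(aug, half_year(y, h)),
                   nights_in_window(base, half_year(y, h)))
      }
      expect_gte(classify_returned(aug, y), classify_returned(base, y))
    }
  }
})

test_that("the 31-night rule classifies boundary patterns instantly", {
  # 31 nights scattered across H1 (not consecutive) -> returned
  starts <- as.Date("2010-01-05") + seq(0, by = 5, length.out = 16)
  ev <- make_events(
    rep("c1", 32),
    sort(c(starts, starts + 2)),  # 16 separate stays of 2 nights: 32 total
    rep(c("arrival", "departure"), 16)
  )
  iv <- build_intervals(canonical_order(ev), "2010-01-01", "2010-12-31")
  expect_equal(sum(as.integer(iv$end - iv$start)), 32)
  expect_equal(classify_returned(iv, 2010), 1L)

  # 30 nights in each half, 60 in the year -> NOT returned
  ev2 <- make_events(
    rep("c2", 4),
    c("2010-03-01", "2010-03-31", "2010-09-01", "2010-10-01"),
    c("arrival", "departure", "arrival", "departure")
  )
  iv2 <- build_intervals(ev2, "2010-01-01", "2010-12-31")
  expect_equal(nights_in_window(iv2, half_year(2010, "H1")), 30)
  expect_equal(nights_in_window(iv2, half_year(2010, "H2")), 30)
  expect_equal(classify_returned(iv2, 2010), 0L)

  # continuous residence all year: both halves far exceed the threshold
  iv3 <- build_intervals(
    make_events("c3", "2010-01-01", "arrival"), "2010-01-01", "2010-12-31"
  )
  expect_equal(classify_returned(iv3, 2010), 1L)
})

test_that("build_status_panel composes classification over children and years", {
  profiles <- as_profiles(tibble::tibble(
    child_id = "k1", birth_year = 2008L, child_type = "B",
    mother_edu = "2", father_edu = "2"
  ))
  no_events <- make_events(character(), as.Date(character()), character())
  panel <- build_status_panel(profiles, no_events, 2010)
  expect_equal(panel$year, 2008:2010)
  expect_equal(panel$status, c(0L, 0L, 0L))

  # resident from birth onward: only record is a much later departure
  ev <- make_events("k1", "2010-10-01", "departure")
  panel2 <- build_status_panel(profiles, ev, 2010)
  expect_equal(panel2$status, c(1L, 1L, 1L))

  # orphan child ids are rejected with their names
  ev_orphan <- make_events("ghost", "2009-01-01", "arrival")
  expect_error(build_status_panel(profiles, ev_orphan, 2010), "ghost")
})

test_that("panel statuses equal independent per-child day-by-day oracle", {
  set.seed(7)
  n <- 100
  profiles <- as_profiles(tibble::tibble(
    child_id = sprintf("k%03d", 1:n),
    birth_year = sample(2008:2010, n, replace = TRUE),
    child_type = sample(c("A", "B"), n, replace = TRUE),
    mother_edu = "2", father_edu = "2"
  ))
  ev <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    by <- profiles$birth_year[i]
    random_event_stream(
      child_id = profiles$child_id[i],
      period_start = as.Date(sprintf("%d-01-01", by)),
      period_end = as.Date("2012-12-31"),
      max_events = 12
    )
  }))
  panel <- suppressMessages(build_status_panel(profiles, ev, 2012))
  for (i in seq_len(n)) {
    by <- profiles$birth_year[i]
    evi <- ev[ev$child_id == profiles$child_id[i], ]
    for (y in by:2012) {
      expected <- classify_oracle(
        evi, y, sprintf("%d-01-01", by), "2012-12-31"
      )
      got <- panel$status[panel$child_id == profiles$child_id[i] &
                            panel$year == y]
      expect_identical(got, expected)
    }
  }
})
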