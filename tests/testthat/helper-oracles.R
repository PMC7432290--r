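# Independent oracles: deliberately naive day-by-day reimplementations of the
# residence rules, used to cross-check the interval arithmetic.

# Build an events tibble from parallel vectors.
make_events <- function(child_id, date, direction) {
  tibble::tibble(
    child_id = child_id,
    date = as.Date(date),
    direction = direction
  )
}

# Day-by-day presence state machine for ONE child: an arrival makes the child
# present from that date on, a departure absent from that date on; a child
# whose first event is a departure was present from the period start.
# Returns the set of dates (nights) spent in Hong Kong.
presence_dates_oracle <- function(events, period_start, period_end) {
  period_start <- as.Date(period_start)
  period_end <- as.Date(period_end)
  events <- canonical_order(events)
  days <- seq(period_start, period_end, by = "day")
  state <- rep(NA, length(days))
  init <- if (nrow(events) == 0) {
    FALSE
  } else {
    events$direction[1] == "departure"
  }
  for (i in seq_len(nrow(events))) {
    idx <- which(days >= events$date[i])
    state[idx] <- events$direction[i] == "arrival"
  }
  # before the first event the initial state applies
  state[is.na(state)] <- init
  days[state]
}

# Brute-force night count: iterate every date of the window and test interval
# membership.
nights_oracle <- function(intervals, window) {
  days <- seq(window$start, window$end - 1, by = "day")
  sum(vapply(days, function(d) {
    any(intervals$start <= d & d < intervals$end)
  }, logical(1)))
}

# Independent yearly classification for ONE child, via the state machine.
classify_oracle <- function(events, year, period_start, period_end,
                            threshold = 31) {
  nights <- presence_dates_oracle(events, period_start, period_end)
  in_win <- function(a, b) sum(nights >= as.Date(a) & nights <= as.Date(b))
  h1 <- in_win(sprintf("%d-01-01", year), sprintf("%d-06-30", year))
  h2 <- in_win(sprintf("%d-07-01", year), sprintf("%d-12-31", year))
  as.integer(h1 >= threshold || h2 >= threshold)
}

# Random event stream for one child (caller controls the RNG seed).
random_event_stream <- function(child_id = "X",
                                period_start = as.Date("2010-01-01"),
                                period_end = as.Date("2012-12-31"),
                                max_events = 20) {
  n <- sample(0:max_events, 1)
  if (n == 0) {
    return(make_events(character(), as.Date(character()), character()))
  }
  days <- seq(period_start, period_end, by = "day")
  make_events(
    rep(child_id, n),
    sort(sample(days, n, replace = TRUE)),
    sample(c("arrival", "departure"), n, replace = TRUE)
  )
}

# t-step state distribution by explicit matrix powering (independent of the
# package's scalar recursion).
matrix_power_p <- function(theta1, theta2, p0, t) {
  P <- matrix(c(theta1, 1 - theta1, 1 - theta2, theta2), 2, 2, byrow = TRUE)
  v <- c(1 - p0, p0)
  for (i in seq_len(t)) v <- v %*% P
  v[2]
}
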