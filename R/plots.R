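#' Plot noncumulative return rates by birth cohort
#'
#' One line per birth cohort over year of movement; the usual way of
#' reading a cohort rate table.
#'
#' @param rates A [rate_table()] (unstratified).
#' @return A ggplot object.
#' @export
plot_return_rates <- function(rates) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plotting requires the ggplot2 package")
  }
  df <- tibble::as_tibble(rates)
  df$cohort <- factor(df$cohort)
  p <- ggplot2::ggplot(
    df, ggplot2::aes(x = .data$year, y = .data$rate, colour = .data$cohort)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Year of movement", y = "Return rate (%)",
                  colour = "Birth cohort") +
    ggplot2::ylim(0, 100)
  if ("child_type" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~child_type)
  }
  p
}

#' Plot projected return probabilities
#'
#' @param projections A named list of [project_return()] results keyed by
#'   cohort (as produced by [run_pipeline()]), or a single projection.
#' @return A ggplot object.
#' @export
plot_projections <- function(projections) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plotting requires the ggplot2 package")
  }
  if (inherits(projections, "projection")) {
    projections <- list(projections)
    names(projections) <- attr(projections[[1]], "cohort") %||% "1"
  }
  df <- dplyr::bind_rows(
    purrr::imap(projections, function(pr, j) {
      tibble::add_column(tibble::as_tibble(pr), cohort = j, .before = 1)
    })
  )
  x <- if ("year" %in% names(df)) "year" else "step"
  ggplot2::ggplot(
    df, ggplot2::aes(x = .data[[x]], y = 100 * .data$p,
                     colour = factor(.data$cohort))
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = x, y = "Projected return rate (%)",
                  colour = "Birth cohort") +
    ggplot2::ylim(0, 100)
}
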