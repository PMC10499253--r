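#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a two-world comparison
#'
#' @param x An `scd_comparison` from [compare_worlds()].
#' @param ... Unused.
#' @return The comparison tibble: one row per metric with `without`, `with`,
#'   `impact` and `percent` columns.
#' @export
tidy.scd_comparison <- function(x, ...) x$comparison

#' One-row summary of a two-world comparison
#'
#' @param x An `scd_comparison` from [compare_worlds()].
#' @param ... Unused.
#' @return A one-row tibble with the headline quantities: cumulative deaths
#'   per world, their percent reduction, life-years gained, and the
#'   life-expectancy gain in years.
#' @export
glance.scd_comparison <- function(x, ...) {
  cm <- x$comparison
  g <- function(m, col) cm[cm$metric == m, ][[col]]
  tibble(
    deaths_without = g("deaths", "without"),
    deaths_with = g("deaths", "with"),
    deaths_percent = g("deaths", "percent"),
    life_years_gained = g("life_years", "impact"),
    life_expectancy_gain = g("life_expectancy", "impact"),
    strokes_percent = g("strokes", "percent"),
    ph_incident_percent = g("ph_incident", "percent"),
    ckd_incident_percent = g("ckd_incident", "percent")
  )
}

#' Tidy a projection ledger
#'
#' @param x An `scd_ledger` from [run_world()].
#' @param ... Unused.
#' @return The ledger in long format: `year`, `world`, `metric`, `value`.
#' @export
tidy.scd_ledger <- function(x, ...) {
  world <- attr(x, "world")
  as_tibble(x) %>%
    tidyr::pivot_longer(-year, names_to = "metric", values_to = "value") %>%
    mutate(world = world, .after = year)
}

#' Tidy a tornado table
#'
#' @param x An `scd_tornado` from [tornado()].
#' @param ... Unused.
#' @return The underlying tibble with a `rank` column.
#' @export
tidy.scd_tornado <- function(x, ...) {
  as_tibble(x) %>% mutate(rank = row_number(), .before = 1)
}
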