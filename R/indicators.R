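#' Per-capita resource density
#'
#' Resource units per 10,000 persons: `count / population`, with population
#' in 10,000-person units. Returned unrounded; the published tables print
#' these at 2 decimals (national series) or 3 decimals (provincial table),
#' which [display_density()] reproduces.
#'
#' @param count non-negative resource count (vectorized).
#' @param population population in 10,000-person units, strictly positive.
#' @return density per 10,000 persons.
#' @examples
#' density_per_capita(678258, 139538) # 4.8608...
#' @export
density_per_capita <- function(count, population) {
  if (any(!is.finite(population) | population <= 0)) {
    stop_healtheil("population must be > 0", class = "healtheil_domain_error")
  }
  if (any(count < 0, na.rm = TRUE)) {
    stop_healtheil("counts must be >= 0", class = "healtheil_domain_error")
  }
  count / population
}

#' Per-area resource density
#'
#' Resource units per square kilometre.
#'
#' @param count non-negative resource count (vectorized).
#' @param area land area in km², strictly positive.
#' @return density per km².
#' @export
density_per_area <- function(count, area) {
  if (any(!is.finite(area) | area <= 0)) {
    stop_healtheil("area must be > 0", class = "healtheil_domain_error")
  }
  count / area
}

#' Round a density for display
#'
#' @param x density values.
#' @param convention `"per_10k_national"` (2 decimals, the national-series
#'   convention) or `"per_province"` (3 decimals, the provincial-table
#'   convention). Rounding is half away from zero.
#' @return rounded values.
#' @export
display_density <- function(x, convention = c("per_10k_national",
                                              "per_province")) {
  convention <- match.arg(convention)
  round_half_up(x, if (convention == "per_10k_national") 2 else 3)
}

#' Percent change between two densities
#'
#' `100 * (end - start) / start`. In `"table_rounded"` mode (the default)
#' both densities are first rounded half-up to `digits` decimals; this is
#' the convention under which the published percent changes (+8.72, +24.68,
#' +50.28, -43.48 over 2013-2018) are reproduced from the printed 2-decimal
#' densities. `"raw"` mode differences the unrounded densities.
#'
#' @param start,end densities at the start and end of the period.
#' @param mode `"table_rounded"` or `"raw"`.
#' @param digits decimals used in `table_rounded` mode (default 2).
#' @return percent change (scalar or vector), unrounded.
#' @examples
#' percent_change(4.4723, 4.8608)                # table_rounded: 8.7248...
#' percent_change(4.4723, 4.8608, mode = "raw")  # 8.6868...
#' @export
percent_change <- function(start, end, mode = c("table_rounded", "raw"),
                           digits = 2) {
  mode <- match.arg(mode)
  if (mode == "table_rounded") {
    start <- round_half_up(start, digits)
    end <- round_half_up(end, digits)
    if (any(start == 0)) {
      stop_healtheil(
        "start density rounds to 0 in table_rounded mode; use mode = \"raw\"",
        class = "healtheil_domain_error")
    }
  } else if (any(start <= 0)) {
    stop_healtheil("start density must be > 0", class = "healtheil_domain_error")
  }
  100 * (end - start) / start
}

#' Density table for a panel of counts
#'
#' Computes per-10,000-capita and (where area is known) per-km² densities for
#' every (year, province, resource) cell with data, plus national `"TOTAL"`
#' rows formed by summing counts and populations before dividing — i.e. the
#' TOTAL density is the population-weighted mean of province densities.
#'
#' @param panel a `resource_panel` carrying raw counts.
#' @return A tibble of class `density_table` with columns `year`, `province`
#'   (`"TOTAL"` for the national rows), `region` (`NA` for totals),
#'   `resource`, `per_10k`, `per_km2`.
#' @examples
#' density_table(paper_fixture("totals_2013_2018"))
#' @export
density_table <- function(panel) {
  stopifnot(inherits(panel, "resource_panel"))
  if (panel$values_are != "counts") {
    stop_healtheil(paste0(
      "this panel stores pre-computed densities; use as_density_table() ",
      "to access them instead of recomputing from counts"),
      class = "healtheil_density_panel")
  }
  rec <- panel$records
  long <- tidyr::pivot_longer(
    rec, cols = dplyr::all_of(RESOURCES),
    names_to = "resource", values_to = "count")
  long <- dplyr::filter(long, !is.na(.data$count))
  prov <- dplyr::mutate(
    long,
    per_10k = .data$count / .data$population,
    per_km2 = ifelse(is.na(.data$area), NA_real_, .data$count / .data$area))

  totals <- dplyr::summarise(
    dplyr::group_by(long, .data$year, .data$resource),
    per_10k = sum(.data$count) / sum(.data$population),
    per_km2 = if (anyNA(.data$area)) NA_real_
              else sum(.data$count) / sum(.data$area),
    .groups = "drop")
  totals <- dplyr::mutate(totals, province = "TOTAL", region = NA_character_)

  out <- dplyr::bind_rows(
    dplyr::select(prov, "year", "province", "region", "resource",
                  "per_10k", "per_km2"),
    dplyr::select(totals, "year", "province", "region", "resource",
                  "per_10k", "per_km2"))
  out <- dplyr::arrange(out, .data$year, .data$province != "TOTAL",
                        .data$province, .data$resource)
  class(out) <- c("density_table", class(out))
  out
}

#' Stored densities of a density-flagged panel
#'
#' Returns the densities a `values_are = "densities"` panel already holds
#' (e.g. the packaged 2018 provincial table), in the same shape as
#' [density_table()]. No national TOTAL rows are added: they cannot be formed
#' from densities without the underlying counts.
#'
#' @param panel a density-flagged `resource_panel`.
#' @return A `density_table` tibble.
#' @export
as_density_table <- function(panel) {
  stopifnot(inherits(panel, "resource_panel"))
  if (panel$values_are != "densities") {
    return(density_table(panel))
  }
  out <- dplyr::select(panel$records, "year", "province", "region",
                       "resource", "per_10k", "per_km2")
  class(out) <- c("density_table", class(out))
  out
}

#' Extremes of a density indicator across provinces
#'
#' Minimum and maximum province for one (resource, perspective, year) cell,
#' with the max/min ratio computed on the stored values (for the packaged
#' provincial table these are the printed 3-decimal densities, so quoted
#' ratios match the published arithmetic). Ties are broken alphabetically by
#' canonical province name. A zero minimum yields `max_min_ratio = NA`
#' rather than infinity.
#'
#' @param table a `density_table`.
#' @param resource one of `r paste0('"', RESOURCES, '"', collapse = ", ")`.
#' @param perspective `"per_10k"` or `"per_km2"`.
#' @param year calendar year.
#' @return A list of class `extremes_summary` with fields `resource`,
#'   `perspective`, `year`, `min_province`, `min_value`, `max_province`,
#'   `max_value`, `max_min_ratio`.
#' @examples
#' tab <- as_density_table(paper_fixture("provinces_2018"))
#' extremes(tab, "institutions", "per_10k", 2018)
#' @export
extremes <- function(table, resource, perspective = c("per_10k", "per_km2"),
                     year) {
  perspective <- match.arg(perspective)
  resource <- match.arg(resource, RESOURCES)
  rows <- dplyr::filter(table, .data$year == !!year,
                        .data$resource == !!resource,
                        .data$province != "TOTAL",
                        is.finite(.data[[perspective]]))
  if (nrow(rows) < 2) {
    stop_healtheil(sprintf(
      "need >= 2 provinces with finite %s values for %s in %d",
      perspective, resource, as.integer(year)),
      class = "healtheil_domain_error")
  }
  rows <- dplyr::arrange(rows, .data$province)   # alphabetical tie-break
  v <- rows[[perspective]]
  i_min <- which.min(v)
  i_max <- which.max(v)
  structure(
    list(
      resource = resource, perspective = perspective,
      year = as.integer(year),
      min_province = rows$province[i_min], min_value = v[i_min],
      max_province = rows$province[i_max], max_value = v[i_max],
      max_min_ratio = if (v[i_min] > 0) v[i_max] / v[i_min] else NA_real_
    ),
    class = "extremes_summary"
  )
}

#' @export
print.extremes_summary <- function(x, ...) {
  cat(sprintf("<extremes_summary> %s, %s, %d\n", x$resource, x$perspective,
              x$year))
  cat(sprintf("  min %s = %g, max %s = %g, max/min = %s\n",
              x$min_province, x$min_value, x$max_province, x$max_value,
              if (is.na(x$max_min_ratio)) "undefined (min = 0)"
              else format(x$max_min_ratio)))
  invisible(x)
}

#' Ratio of one province's density to another's
#'
#' Pairwise ratio on the stored (printed-precision) values, the arithmetic
#' behind quoted comparisons such as "Shanghai is nearly 1403 times Tibet"
#' for per-km² technical personnel. Note that a quoted pairwise comparison is
#' not always the max/min ratio: the published 2018 narrative compares
#' Hainan (6.301) to Anhui (2.709) for per-capita technical personnel even
#' though the table's actual maximum is Guangxi (7.333) — see [extremes()]
#' for honest extremes.
#'
#' @inheritParams extremes
#' @param numerator,denominator canonical province names.
#' @return the ratio of stored densities.
#' @export
density_ratio <- function(table, resource, perspective, year,
                          numerator, denominator) {
  perspective <- match.arg(perspective, c("per_10k", "per_km2"))
  resource <- match.arg(resource, RESOURCES)
  pick <- function(p) {
    row <- dplyr::filter(table, .data$year == !!year,
                         .data$resource == !!resource, .data$province == p)
    if (nrow(row) != 1 || !is.finite(row[[perspective]])) {
      stop_healtheil(sprintf("no %s value for %s in %d", perspective, p,
                             as.integer(year)),
                     class = "healtheil_domain_error")
    }
    row[[perspective]]
  }
  num <- pick(numerator)
  den <- pick(denominator)
  if (den <= 0) {
    stop_healtheil("denominator density must be > 0",
                   class = "healtheil_domain_error")
  }
  num / den
}

#' National percent-change summary over a year range
#'
#' Percent change of the national TOTAL per-10,000-capita density of every
#' resource between the first and last year of the panel (or an explicit
#' pair of years).
#'
#' @param panel a `resource_panel` carrying counts for >= 2 years.
#' @param from,to start and end years; default the panel's first and last.
#' @param mode passed to [percent_change()].
#' @return A tibble with columns `resource`, `from`, `to`, `start_density`,
#'   `end_density` (unrounded) and `change_pct`.
#' @examples
#' national_percent_changes(paper_fixture("totals_2013_2018"))
#' @export
national_percent_changes <- function(panel, from = NULL, to = NULL,
                                     mode = c("table_rounded", "raw")) {
  mode <- match.arg(mode)
  tab <- density_table(panel)
  tot <- dplyr::filter(tab, .data$province == "TOTAL")
  yrs <- sort(unique(tot$year))
  if (length(yrs) < 2) {
    stop_healtheil("percent changes need >= 2 years",
                   class = "healtheil_domain_error")
  }
  from <- from %||% yrs[1]
  to <- to %||% yrs[length(yrs)]
  wide <- dplyr::inner_join(
    dplyr::select(dplyr::filter(tot, .data$year == from),
                  "resource", start_density = "per_10k"),
    dplyr::select(dplyr::filter(tot, .data$year == to),
                  "resource", end_density = "per_10k"),
    by = "resource")
  dplyr::mutate(wide,
                from = as.integer(from), to = as.integer(to),
                change_pct = percent_change(.data$start_density,
                                            .data$end_density, mode = mode),
                .before = "start_density")
}
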