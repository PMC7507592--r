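#' Packaged reference tables
#'
#' Two small panels shipped with the package, transcribed from the published
#' national yearbook summaries:
#'
#' * `"totals_2013_2018"` — six national-total records (2013–2018) with the
#'   year-end population (10,000-person units) and the raw counts of public
#'   health institutions, technical personnel, beds and equipment. Carries
#'   counts, so the full indicator pipeline applies.
#' * `"provinces_2018"` — the 31 provinces in 2018 with per-10,000-capita and
#'   per-km² densities of institutions, technical personnel and beds, at
#'   printed 3-decimal precision. The source table prints densities, not raw
#'   counts, so this panel is flagged `values_are = "densities"`:
#'   [density_table()] and the Theil operations refuse it, while
#'   [as_density_table()] and [extremes()] work on the stored values.
#'
#' The provincial table spells both Shaanxi (western) and Shanxi (middle) as
#' "Shanxi"; the fixture resolves the collision by region (see
#' [canonicalize_province()]).
#'
#' @param name `"totals_2013_2018"` or `"provinces_2018"`.
#' @return A `resource_panel`.
#' @examples
#' paper_fixture("totals_2013_2018")
#' @export
paper_fixture <- function(name) {
  valid <- c("totals_2013_2018", "provinces_2018")
  if (length(name) != 1 || !name %in% valid) {
    stop_healtheil(sprintf("unknown fixture '%s'; valid names: %s",
                           paste(name, collapse = ","),
                           paste(valid, collapse = ", ")),
                   class = "healtheil_unknown_fixture")
  }
  if (name == "totals_2013_2018") {
    path <- system.file("extdata", "national_totals_2013_2018.csv",
                        package = "healtheil", mustWork = TRUE)
    panel <- read_panel(path)
    panel$provenance <- "packaged national totals 2013-2018"
    return(panel)
  }

  path <- system.file("extdata", "province_densities_2018.csv",
                      package = "healtheil", mustWork = TRUE)
  df <- readr::read_csv(path, col_types = readr::cols(
    year = "i", province = "c", region = "c", .default = "d"),
    progress = FALSE)
  partition <- china_region_partition()
  df$province <- canonicalize_province(df$province, df$region, partition)
  long <- tidyr::pivot_longer(
    df,
    cols = -c("year", "province", "region"),
    names_to = c("resource", "perspective"),
    names_pattern = "(.*)_per_(km2|10k)$",
    values_to = "value")
  records <- tidyr::pivot_wider(
    long, names_from = "perspective", values_from = "value",
    names_prefix = "per_")
  records <- dplyr::arrange(records, .data$year, .data$province, .data$resource)
  new_resource_panel(records, partition,
                     provenance = "packaged provincial densities 2018",
                     values_are = "densities")
}
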