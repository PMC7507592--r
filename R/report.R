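#' Run the full allocation-equality analysis
#'
#' Executes the pipeline stages in order — densities, national percent
#' changes, per-province extremes, per-year Theil decompositions with
#' contribution rates — and collects every table into a single report whose
#' numbers are exactly the direct module-call results (no recomputation).
#'
#' For a density-flagged panel (e.g. the packaged 2018 provincial table) the
#' count-requiring stages (percent changes, Theil) are skipped with an
#' explicit warning recorded in the report.
#'
#' @param panel a `resource_panel`.
#' @param resources resource names to analyse; defaults to those with data.
#' @param zero_policy passed to the Theil stage.
#' @param percent_change_mode passed to [national_percent_changes()].
#' @return A list of class `analysis_report` with fields `metadata`,
#'   `densities`, `percent_changes`, `extremes`, `theil` (tidy series
#'   `trend`, `regions`, `contributions` per resource), `warnings`.
#' @examples
#' rep <- run_report(paper_fixture("totals_2013_2018"))
#' rep$percent_changes
#' @export
run_report <- function(panel, resources = NULL,
                       zero_policy = c("error", "drop"),
                       percent_change_mode = c("table_rounded", "raw")) {
  stopifnot(inherits(panel, "resource_panel"))
  zero_policy <- match.arg(zero_policy)
  percent_change_mode <- match.arg(percent_change_mode)
  warnings <- character()
  note <- function(msg) warnings <<- c(warnings, msg)

  densities_only <- panel$values_are == "densities"
  tab <- as_density_table(panel)
  if (is.null(resources)) {
    resources <- intersect(RESOURCES, unique(tab$resource))
  }
  years <- sort(unique(tab$year))
  latest <- years[length(years)]

  pct <- NULL
  if (densities_only) {
    note("panel stores densities: percent-change and Theil stages skipped")
  } else if (length(years) >= 2) {
    pct <- national_percent_changes(panel, mode = percent_change_mode)
    pct <- pct[pct$resource %in% resources, ]
  } else {
    note("single-year panel: percent-change stage skipped")
  }

  ext <- list()
  multi_prov <- length(setdiff(unique(tab$province), "TOTAL")) >= 2
  if (multi_prov) {
    for (res in resources) {
      for (persp in c("per_10k", "per_km2")) {
        rows <- tab[tab$year == latest & tab$resource == res &
                      tab$province != "TOTAL", ]
        if (sum(is.finite(rows[[persp]])) >= 2) {
          e <- extremes(tab, res, persp, latest)
          ext[[length(ext) + 1]] <- tibble::tibble(
            resource = e$resource, perspective = e$perspective,
            year = e$year, min_province = e$min_province,
            min_value = e$min_value, max_province = e$max_province,
            max_value = e$max_value, max_min_ratio = e$max_min_ratio)
        }
      }
    }
  } else {
    note("fewer than 2 provinces: extremes stage skipped")
  }
  ext <- if (length(ext) > 0) dplyr::bind_rows(ext) else NULL

  theil <- NULL
  can_theil <- !densities_only && multi_prov && length(years) >= 2 &&
    length(unique(stats::na.omit(tab$region))) >= 2
  if (!densities_only && !can_theil) {
    note("panel structure does not support the Theil trend stage")
  }
  if (can_theil) {
    theil <- list(trend = list(), regions = list(), contributions = list())
    for (res in resources) {
      tr <- withCallingHandlers(
        theil_trend(panel, res, zero_policy = zero_policy),
        healtheil_warning = function(w) {
          note(conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      theil$trend[[res]] <- trend_series(tr)
      theil$regions[[res]] <- region_series(tr)
      theil$contributions[[res]] <- contribution_series(tr)
    }
  }

  structure(
    list(
      metadata = list(
        provenance = panel$provenance,
        values_are = panel$values_are,
        resources = resources,
        years = as.integer(years),
        settings = list(zero_policy = zero_policy,
                        percent_change_mode = percent_change_mode)),
      densities = tibble::as_tibble(tab),
      percent_changes = pct,
      extremes = ext,
      theil = theil,
      warnings = warnings
    ),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  source: %s [%s]\n", x$metadata$provenance,
              x$metadata$values_are))
  cat(sprintf("  years: %s; resources: %s\n",
              paste(x$metadata$years, collapse = ", "),
              paste(x$metadata$resources, collapse = ", ")))
  cat(sprintf("  stages present: %s\n", paste(
    c("densities",
      if (!is.null(x$percent_changes)) "percent_changes",
      if (!is.null(x$extremes)) "extremes",
      if (!is.null(x$theil)) "theil"), collapse = ", ")))
  for (w in x$warnings) cat(sprintf("  warning: %s\n", w))
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' JSON is the canonical report representation; it round-trips losslessly
#' through [read_report()] (numbers are written at full precision, no
#' timestamps are included, so identical inputs give byte-identical files).
#'
#' @param report an `analysis_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read an analysis report back from JSON
#'
#' @param path path written by [write_report()].
#' @return An `analysis_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_tbl <- function(df) if (is.null(df)) NULL else tibble::as_tibble(df)
  x$densities <- as_tbl(x$densities)
  x$percent_changes <- as_tbl(x$percent_changes)
  x$extremes <- as_tbl(x$extremes)
  if (!is.null(x$theil)) {
    x$theil <- lapply(x$theil, function(part) lapply(part, as_tbl))
  }
  x$metadata$years <- as.integer(x$metadata$years)
  x$warnings <- as.character(x$warnings %||% character())
  structure(x, class = "analysis_report")
}
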