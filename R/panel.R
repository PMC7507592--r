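#' @title Province-year resource panels
#' @description A `resource_panel` holds one row per (year, province) with the
#'   population (in units of 10,000 persons), land area (km², optional) and
#'   the four public-health resource counts, plus the region partition and a
#'   validation report. Panels normally carry raw counts; the packaged 2018
#'   provincial table carries printed densities instead and is flagged as
#'   such, so count-requiring operations refuse it with a clear message.
#' @name resource_panel
NULL

PANEL_COLUMNS <- c("year", "province", "region", "population", "area", RESOURCES)

new_resource_panel <- function(records, partition, provenance = "unknown",
                               values_are = c("counts", "densities"),
                               validation = NULL) {
  values_are <- match.arg(values_are)
  structure(
    list(
      records = records,
      partition = partition,
      provenance = provenance,
      values_are = values_are,
      validation = validation %||% new_validation_report()
    ),
    class = "resource_panel"
  )
}

new_validation_report <- function(errors = NULL, warnings = NULL) {
  empty <- tibble::tibble(row = character(), message = character())
  structure(
    list(
      errors = errors %||% empty,
      warnings = warnings %||% empty,
      is_valid = is.null(errors) || nrow(errors) == 0
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s: %d error(s), %d warning(s)\n",
              if (x$is_valid) "valid" else "invalid",
              nrow(x$errors), nrow(x$warnings)))
  show <- function(df, tag) {
    for (i in seq_len(min(nrow(df), 10))) {
      cat(sprintf("  %s [%s] %s\n", tag, df$row[i], df$message[i]))
    }
    if (nrow(df) > 10) cat(sprintf("  ... and %d more\n", nrow(df) - 10))
  }
  show(x$errors, "error")
  show(x$warnings, "warning")
  invisible(x)
}

#' @export
print.resource_panel <- function(x, ...) {
  yrs <- sort(unique(x$records$year))
  cat(sprintf(
    "<resource_panel> %d record(s), %d province(s), year(s) %s [%s]\n",
    nrow(x$records), length(unique(x$records$province)),
    paste(range(yrs), collapse = "-"), x$values_are))
  cat(sprintf("  provenance: %s\n", x$provenance))
  if (!x$validation$is_valid) {
    cat(sprintf("  INVALID: %d validation error(s)\n", nrow(x$validation$errors)))
  }
  invisible(x)
}

#' Construct a resource panel from a data frame
#'
#' Validates and normalizes an in-memory table of province-year records.
#' This is the programmatic counterpart of [read_panel()].
#'
#' @param records data frame with columns `year`, `province`, `population`
#'   (10,000-person units) and optionally `region`, `area` (km²) and the
#'   resource counts `institutions`, `technical_personnel`, `beds`,
#'   `equipment`.
#' @param partition region partition tibble (`province`, `region`), or `NULL`
#'   to take regions from the records (if present).
#' @param provenance free-text source tag stored on the panel.
#' @param canonicalize if `TRUE` (default when a partition is supplied),
#'   province names are matched case-insensitively against the partition and
#'   unmatched names are a hard error.
#' @return A `resource_panel`.
#' @export
resource_panel <- function(records, partition = NULL, provenance = "in-memory",
                           canonicalize = !is.null(partition)) {
  records <- tibble::as_tibble(records)
  for (col in c("province", "year", "population")) {
    if (!col %in% names(records)) {
      stop_healtheil(sprintf("panel lacks mandatory column '%s'", col),
                     class = "healtheil_missing_column")
    }
  }
  for (col in setdiff(PANEL_COLUMNS, names(records))) {
    records[[col]] <- if (col == "region") NA_character_ else NA_real_
  }
  records <- records[PANEL_COLUMNS]
  records$province <- trimws(as.character(records$province))
  records$region <- tolower(trimws(as.character(records$region)))
  records$year <- as.integer(records$year)

  errors <- character()
  warnings <- character()
  locator <- sprintf("%s/%s", records$province, records$year)

  if (!is.null(partition) && canonicalize) {
    canon <- canonicalize_province(records$province, records$region, partition)
    bad <- unique(records$province[is.na(canon)])
    if (length(bad) > 0) {
      stop_healtheil(
        paste0("provinces not found in the partition: ",
               paste(bad, collapse = ", ")),
        class = "healtheil_unknown_province")
    }
    records$province <- canon
    expected <- partition$region[match(canon, partition$province)]
    clash <- !is.na(records$region) & records$region != expected
    if (any(clash)) {
      warnings <- c(warnings, setNames(
        sprintf("region '%s' disagrees with partition ('%s'); partition used",
                records$region[clash], expected[clash]),
        locator[clash]))
    }
    records$region <- expected
  }

  keep <- rep(TRUE, nrow(records))
  bad_pop <- is.na(records$population) | records$population <= 0
  if (any(bad_pop)) {
    errors <- c(errors, setNames(rep("population must be a positive number",
                                     sum(bad_pop)), locator[bad_pop]))
    keep <- keep & !bad_pop
  }
  bad_area <- !is.na(records$area) & records$area <= 0
  if (any(bad_area)) {
    errors <- c(errors, setNames(rep("area must be positive when present",
                                     sum(bad_area)), locator[bad_area]))
    keep <- keep & !bad_area
  }
  for (res in RESOURCES) {
    neg <- !is.na(records[[res]]) & records[[res]] < 0
    if (any(neg)) {
      errors <- c(errors, setNames(rep(sprintf("%s count must be >= 0", res),
                                       sum(neg)), locator[neg]))
      keep <- keep & !neg
    }
  }
  dup <- duplicated(records[c("province", "year")])
  if (any(dup)) {
    errors <- c(errors, setNames(rep("duplicate (province, year) record",
                                     sum(dup)), locator[dup]))
    keep <- keep & !dup
  }
  records <- records[keep, ]

  # rectangularity: every year should cover the same province set
  if (nrow(records) > 0) {
    by_year <- split(records$province, records$year)
    all_prov <- sort(unique(records$province))
    ragged <- names(by_year)[vapply(by_year, function(p)
      !setequal(p, all_prov), logical(1))]
    if (length(ragged) > 0) {
      warnings <- c(warnings, setNames(
        sprintf("year %s does not cover the full province set", ragged),
        paste0("year:", ragged)))
    }
  }

  report <- new_validation_report(
    errors = tibble::tibble(row = names(errors) %||% character(),
                            message = unname(errors)),
    warnings = tibble::tibble(row = names(warnings) %||% character(),
                              message = unname(warnings))
  )
  records <- dplyr::arrange(records, .data$year, .data$province)
  new_resource_panel(records, partition, provenance,
                     values_are = "counts", validation = report)
}

#' Read a province-year panel from CSV
#'
#' Reads a long-format CSV with header columns
#' `year,province,region,population_10k,area_km2,institutions,
#' technical_personnel,beds,equipment` (region, area and resource columns
#' optional; `population` is accepted for `population_10k`). Numeric cells
#' may contain thousands separators ("139,538"). Rows that fail to parse are
#' dropped and recorded in the attached validation report; missing mandatory
#' columns and provinces that cannot be mapped to the partition are hard
#' errors.
#'
#' If the file has a `population_unit` column with value `"persons"`, raw
#' person counts are converted to the canonical 10,000-person unit.
#'
#' @param path path to a CSV file.
#' @param partition a partition tibble (`province`, `region`), the string
#'   `"from-file"` to build the partition from the file's own `region`
#'   column, or `NULL` (default) to use [china_region_partition()] when all
#'   provinces match it and otherwise fall back to the file's regions.
#' @return A `resource_panel` with a `validation` report attached.
#' @examples
#' panel <- paper_fixture("totals_2013_2018")
#' panel$validation$is_valid
#' @export
read_panel <- function(path, partition = NULL) {
  if (!file.exists(path)) {
    stop_healtheil(sprintf("file not found: %s", path))
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  names(df) <- tolower(trimws(names(df)))
  renames <- c(population_10k = "population", area_km2 = "area",
               personnel = "technical_personnel")
  for (nm in names(renames)) {
    if (nm %in% names(df) && !renames[[nm]] %in% names(df)) {
      names(df)[names(df) == nm] <- renames[[nm]]
    }
  }
  for (col in c("province", "year", "population")) {
    if (!col %in% names(df)) {
      stop_healtheil(sprintf("input lacks mandatory column '%s'", col),
                     class = "healtheil_missing_column")
    }
  }

  numeric_cols <- intersect(c("year", "population", "area", RESOURCES),
                            names(df))
  errors <- character()
  locator <- sprintf("%s:%d", basename(path), seq_len(nrow(df)) + 1L)
  keep <- rep(TRUE, nrow(df))
  for (col in numeric_cols) {
    raw <- df[[col]]
    parsed <- parse_panel_number(raw)
    bad <- !is.na(raw) & trimws(raw) != "" & is.na(parsed)
    if (any(bad)) {
      errors <- c(errors, setNames(
        sprintf("non-numeric value '%s' in column '%s'", raw[bad], col),
        locator[bad]))
      if (col %in% c("year", "population")) keep <- keep & !bad
    }
    df[[col]] <- parsed
  }
  if ("population_unit" %in% names(df)) {
    persons <- !is.na(df$population_unit) &
      tolower(trimws(df$population_unit)) %in% c("persons", "person")
    df$population[persons] <- df$population[persons] / 1e4
  }
  df <- df[keep, ]

  from_file <- identical(partition, "from-file")
  if (from_file || is.null(partition)) {
    file_partition <- NULL
    if ("region" %in% names(df) && !all(is.na(df$region))) {
      file_partition <- dplyr::distinct(
        tibble::tibble(province = trimws(df$province),
                       region = tolower(trimws(df$region))))
    }
    if (from_file) {
      if (is.null(file_partition)) {
        stop_healtheil("partition = \"from-file\" requires a 'region' column")
      }
      partition <- file_partition
    } else {
      canon <- canonicalize_province(
        df$province, if ("region" %in% names(df)) df$region)
      partition <- if (all(!is.na(canon))) china_region_partition()
                   else file_partition
    }
  }

  panel <- resource_panel(df[intersect(PANEL_COLUMNS, names(df))],
                          partition = partition, provenance = path)
  if (length(errors) > 0) {
    panel$validation$errors <- dplyr::bind_rows(
      tibble::tibble(row = names(errors), message = unname(errors)),
      panel$validation$errors)
    panel$validation$is_valid <- FALSE
  }
  panel
}

#' Write a panel back to CSV
#'
#' Emits the canonical column order
#' `year,province,region,population_10k,area_km2,institutions,
#' technical_personnel,beds,equipment`; empty cells denote missing values.
#' Numeric fields round-trip exactly through [read_panel()].
#'
#' @param panel a `resource_panel` carrying counts.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "resource_panel"))
  if (panel$values_are != "counts") {
    stop_healtheil(
      "this panel stores densities, not counts; densities are written via as_density_table()",
      class = "healtheil_density_panel")
  }
  out <- panel$records
  names(out)[names(out) == "population"] <- "population_10k"
  names(out)[names(out) == "area"] <- "area_km2"
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
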