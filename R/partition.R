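#' The western/middle/eastern partition of the 31 mainland provinces
#'
#' Returns the standard three-group partition of the 31 mainland Chinese
#' provinces, autonomous regions and municipalities by geographical position
#' and GDP per capita: 12 western, 8 middle and 11 eastern provinces.
#'
#' A note on romanization: the source tables use the spelling "Shanxi" for two
#' distinct provinces — Shaanxi (western; shared border with Sichuan and
#' Ningxia) and Shanxi (middle). This package keeps the unambiguous canonical
#' names `"Shaanxi"` and `"Shanxi"`; [canonicalize_province()] resolves the
#' spelling "Shanxi" using the region label when one is available.
#'
#' @return A tibble with columns `province` and `region`
#'   (`"western"`, `"middle"` or `"eastern"`), one row per province, 31 rows.
#' @examples
#' table(china_region_partition()$region)
#' @export
china_region_partition <- function() {
  tibble::tibble(
    province = c(
      "Inner Mongolia", "Guangxi", "Chongqing", "Sichuan", "Yunnan", "Tibet",
      "Gansu", "Shaanxi", "Guizhou", "Ningxia", "Qinghai", "Xinjiang",
      "Jilin", "Anhui", "Heilongjiang", "Henan", "Hubei", "Hunan", "Jiangxi",
      "Shanxi",
      "Tianjin", "Beijing", "Guangdong", "Liaoning", "Hebei", "Shanghai",
      "Jiangsu", "Zhejiang", "Shandong", "Hainan", "Fujian"
    ),
    region = rep(REGIONS, times = c(12, 8, 11))
  )
}

# Alternate spellings seen in the yearbooks and in secondary sources,
# mapped to canonical province names. Matching is case-insensitive.
PROVINCE_ALIASES <- c(
  "xinjiang uyghur autonomous region" = "Xinjiang",
  "xinjiang uygur autonomous region"  = "Xinjiang",
  "inner mongolian"                   = "Inner Mongolia",
  "nei mongol"                        = "Inner Mongolia",
  "xizang"                            = "Tibet",
  "ningxia hui autonomous region"     = "Ningxia",
  "guangxi zhuang autonomous region"  = "Guangxi"
)

#' Canonicalize province names
#'
#' Matches names case-insensitively and whitespace-insensitively against the
#' packaged province list (plus common alternate spellings). The ambiguous
#' spelling "Shanxi" is resolved to Shaanxi when the supplied region is
#' western, and to Shanxi (middle) otherwise. Unmatched names yield `NA`;
#' callers decide whether that is an error.
#'
#' @param name character vector of province names.
#' @param region optional character vector of region labels, recycled,
#'   used only to disambiguate the Shaanxi/Shanxi spelling collision.
#' @param partition partition tibble as from [china_region_partition()].
#' @return character vector of canonical names, `NA` where unmatched.
#' @examples
#' canonicalize_province(c("  gansu ", "Shanxi"), region = c(NA, "western"))
#' @export
canonicalize_province <- function(name, region = NULL,
                                  partition = china_region_partition()) {
  key <- tolower(gsub("\\s+", " ", trimws(name)))
  aliased <- unname(PROVINCE_ALIASES[key])
  key[!is.na(aliased)] <- tolower(aliased[!is.na(aliased)])

  canon <- partition$province[match(key, tolower(partition$province))]

  # "shanxi" matched the middle-region province above; redirect to Shaanxi
  # when the caller says the row is western.
  if (!is.null(region)) {
    region <- rep_len(tolower(trimws(as.character(region))), length(key))
    shaanxi <- key == "shanxi" & !is.na(region) & region == "western" &
      "Shaanxi" %in% partition$province
    canon[shaanxi] <- "Shaanxi"
  }
  canon
}

#' Read a region partition from a CSV file
#'
#' Expects a header with at least `province` and `region` columns, and
#' exactly three distinct region labels.
#'
#' @param path path to a CSV file.
#' @return A tibble with columns `province` and `region`.
#' @export
read_partition <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  for (col in c("province", "region")) {
    if (!col %in% names(df)) {
      stop_healtheil(sprintf("partition file lacks mandatory column '%s'", col),
                     class = "healtheil_missing_column")
    }
  }
  out <- tibble::tibble(
    province = trimws(df$province),
    region = tolower(trimws(df$region))
  )
  labels <- unique(out$region)
  if (length(labels) != 3) {
    stop_healtheil(sprintf(
      "a region partition must have exactly 3 region labels, found %d (%s)",
      length(labels), paste(labels, collapse = ", ")))
  }
  if (anyDuplicated(out$province)) {
    dups <- unique(out$province[duplicated(out$province)])
    stop_healtheil(paste0("duplicated provinces in partition: ",
                          paste(dups, collapse = ", ")))
  }
  out
}
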