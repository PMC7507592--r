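#' Share vectors for inequality computation
#'
#' A share vector pairs each unit (province or region) with its population
#' share `p` and its resource share `y`. Both must sum to 1 (tolerance
#' `tol`), `p` must be strictly positive, and `y` non-negative. Zero resource
#' shares with positive population make the Theil index infinite; they are
#' admitted here and handled by the `zero_policy` of [theil_total()].
#'
#' @param labels unit labels (unique character vector).
#' @param p population shares.
#' @param y resource shares.
#' @param tol tolerance on the sum-to-one checks (default 1e-9).
#' @return A tibble of class `share_vector` with columns `unit`, `p`, `y`.
#' @examples
#' share_vector(c("A", "B"), p = c(0.5, 0.5), y = c(0.8, 0.2))
#' @export
share_vector <- function(labels, p, y, tol = 1e-9) {
  if (length(labels) != length(p) || length(p) != length(y)) {
    stop_healtheil("labels, p and y must have equal length",
                   class = "healtheil_domain_error")
  }
  if (anyDuplicated(labels)) {
    stop_healtheil("unit labels must be unique",
                   class = "healtheil_domain_error")
  }
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop_healtheil("population shares must be strictly positive",
                   class = "healtheil_domain_error")
  }
  if (any(!is.finite(y)) || any(y < 0)) {
    stop_healtheil("resource shares must be non-negative",
                   class = "healtheil_domain_error")
  }
  if (abs(sum(p) - 1) > tol || abs(sum(y) - 1) > tol) {
    stop_healtheil(sprintf(
      "shares must sum to 1 (got sum(p) = %.12f, sum(y) = %.12f)",
      sum(p), sum(y)), class = "healtheil_domain_error")
  }
  out <- tibble::tibble(unit = as.character(labels), p = p, y = y)
  class(out) <- c("share_vector", class(out))
  out
}

shares_from_counts <- function(labels, population, count, tol = 1e-9) {
  share_vector(labels, population / sum(population), count / sum(count),
               tol = tol)
}

# Apply the zero-resource-share policy; returns possibly reduced shares
# (renormalized) plus the units dropped.
apply_zero_policy <- function(shares, zero_policy = c("error", "drop")) {
  zero_policy <- match.arg(zero_policy)
  zero <- shares$y == 0 & shares$p > 0
  if (!any(zero)) {
    return(list(shares = shares, dropped = character()))
  }
  offenders <- shares$unit[zero]
  if (zero_policy == "error") {
    stop_healtheil(paste0(
      "zero resource share with positive population for unit(s): ",
      paste(offenders, collapse = ", "),
      "; the Theil index is infinite there. Use zero_policy = \"drop\" to ",
      "exclude and renormalize."), class = "healtheil_zero_share")
  }
  warn_healtheil(paste0("dropping unit(s) with zero resource share: ",
                        paste(offenders, collapse = ", ")),
                 class = "healtheil_zero_share_warning")
  kept <- shares[!zero, ]
  list(
    shares = share_vector(kept$unit, kept$p / sum(kept$p),
                          kept$y / sum(kept$y)),
    dropped = offenders
  )
}

#' Total Theil index of a share vector
#'
#' The population-weighted mean-log-deviation form
#' \deqn{T = \sum_i p_i \ln(p_i / y_i)}
#' in natural-log units (nats), where \eqn{p_i} is unit \eqn{i}'s share of
#' total population and \eqn{y_i} its share of the total resource. This is a
#' relative entropy (Kullback–Leibler divergence) of the population share
#' distribution from the resource share distribution: it is 0 exactly when
#' resources are proportional to population, grows with inequality, and is
#' unbounded above (it is not confined to \[0, 1\]).
#'
#' @param shares a [share_vector()], or anything coercible via
#'   `share_vector()` when `p` and `y` are given instead.
#' @param p,y alternative to `shares`: raw share vectors (labels generated).
#' @param zero_policy what to do when a unit has `y = 0` with `p > 0`:
#'   `"error"` (default) or `"drop"` (exclude the unit, renormalize, warn).
#' @return the Theil value in nats (non-negative scalar).
#' @examples
#' theil_total(p = c(0.5, 0.5), y = c(0.8, 0.2)) # 0.2231...
#' @export
theil_total <- function(shares = NULL, p = NULL, y = NULL,
                        zero_policy = c("error", "drop")) {
  if (is.null(shares)) {
    shares <- share_vector(paste0("unit", seq_along(p)), p, y)
  }
  stopifnot(inherits(shares, "share_vector"))
  shares <- apply_zero_policy(shares, zero_policy)$shares
  sum(shares$p * log(shares$p / shares$y))
}

#' Within/between-region Theil decomposition for one (resource, year)
#'
#' Decomposes the total Theil index of a province panel exactly into a
#' within-group and a between-group component:
#' \deqn{T_T = T_\omega + T_B = \sum_j P_j T_j + \sum_j P_j \ln(P_j / Y_j)}
#' where \eqn{P_j}, \eqn{Y_j} are region \eqn{j}'s shares of total population
#' and of the total resource, and \eqn{T_j} is the Theil index of the
#' provinces inside region \eqn{j} (province shares renormalized by the
#' region totals). The identity is exact (the mean-log-deviation is additively
#' decomposable), so `total` always equals the ungrouped province-level Theil
#' value.
#'
#' Contribution rates are not filled in here; see [contribution_rates()].
#'
#' @param panel a `resource_panel` carrying counts and region labels.
#' @param resource resource name.
#' @param year calendar year present in the panel.
#' @param zero_policy passed to the share computation at both province and
#'   region level; see [theil_total()].
#' @return A list of class `theil_decomposition` with fields `resource`,
#'   `year`, `total`, `between`, `within`, `groups` (tibble: `group`, `P`,
#'   `Y`, `T_j`, `weighted_within`, `contribution_rate`),
#'   `between_contribution_rate`, `n_units`, `dropped`.
#' @examples
#' panel <- simulate_panel(simulation_config(seed = 1))
#' theil_decompose(panel, "beds", 2018)
#' @export
theil_decompose <- function(panel, resource, year,
                            zero_policy = c("error", "drop")) {
  stopifnot(inherits(panel, "resource_panel"))
  zero_policy <- match.arg(zero_policy)
  resource <- match.arg(resource, RESOURCES)
  if (panel$values_are != "counts") {
    stop_healtheil(
      "Theil decomposition needs raw counts; this panel stores densities",
      class = "healtheil_density_panel")
  }
  rec <- dplyr::filter(panel$records, .data$year == !!year,
                       !is.na(.data[[resource]]))
  if (nrow(rec) < 2 || length(unique(rec$region[!is.na(rec$region)])) < 2) {
    stop_healtheil(sprintf(
      "need counts for >= 2 provinces in >= 2 regions for %s in %s",
      resource, as.character(year)), class = "healtheil_domain_error")
  }
  shares <- shares_from_counts(rec$province, rec$population, rec[[resource]])
  shares$group <- rec$region
  zp <- apply_zero_policy(shares[c("unit", "p", "y")], zero_policy)
  dropped <- zp$dropped
  shares <- dplyr::semi_join(shares, zp$shares, by = "unit")
  shares$p <- shares$p / sum(shares$p)
  shares$y <- shares$y / sum(shares$y)

  groups <- dplyr::summarise(
    dplyr::group_by(shares, group = .data$group),
    P = sum(.data$p), Y = sum(.data$y),
    T_j = {
      pj <- .data$p / sum(.data$p)
      yj <- .data$y / sum(.data$y)
      sum(pj * log(pj / yj))
    },
    .groups = "drop")
  groups <- dplyr::mutate(groups,
                          weighted_within = .data$P * .data$T_j,
                          contribution_rate = NA_real_)
  groups <- dplyr::arrange(groups, factor(.data$group, levels = REGIONS),
                           .data$group)

  between <- sum(groups$P * log(groups$P / groups$Y))
  within <- sum(groups$weighted_within)

  structure(
    list(
      resource = resource, year = as.integer(year),
      total = within + between, between = between, within = within,
      groups = groups, between_contribution_rate = NA_real_,
      n_units = nrow(shares), dropped = dropped,
      zero_policy = zero_policy
    ),
    class = "theil_decomposition"
  )
}

#' @export
print.theil_decomposition <- function(x, digits = 4, ...) {
  cat(sprintf("<theil_decomposition> %s, %d (n = %d provinces)\n",
              x$resource, x$year, x$n_units))
  cat(sprintf("  T_total = %.*f  (within %.*f + between %.*f)\n",
              digits, x$total, digits, x$within, digits, x$between))
  print(x$groups)
  if (!is.na(x$between_contribution_rate)) {
    cat(sprintf("  between-group contribution rate = %.*f\n",
                digits, x$between_contribution_rate))
  }
  invisible(x)
}

#' Fill contribution rates into a Theil decomposition
#'
#' Each region's contribution rate is its weighted within-group component
#' divided by the total, \eqn{P_j T_j / T_T}; the between-group rate is
#' \eqn{T_B / T_T}. The rates sum to 1. When the total index is (numerically)
#' zero there is no inequality to attribute and all rates are returned as
#' `NA` with a warning.
#'
#' @param decomp a `theil_decomposition` from [theil_decompose()].
#' @param tol totals below `tol` are treated as zero (default 1e-12).
#' @return the decomposition with `groups$contribution_rate` and
#'   `between_contribution_rate` filled.
#' @export
contribution_rates <- function(decomp, tol = 1e-12) {
  stopifnot(inherits(decomp, "theil_decomposition"))
  if (decomp$total < tol) {
    warn_healtheil(
      "total Theil index is 0; contribution rates are undefined",
      class = "healtheil_zero_total_warning")
    decomp$groups$contribution_rate <- NA_real_
    decomp$between_contribution_rate <- NA_real_
    return(decomp)
  }
  decomp$groups$contribution_rate <-
    decomp$groups$weighted_within / decomp$total
  decomp$between_contribution_rate <- decomp$between / decomp$total
  decomp
}

#' Theil trend over the years of a panel
#'
#' One decomposition (with contribution rates) per year in ascending order,
#' for one resource. Years lacking counts for the resource are skipped with
#' a warning.
#'
#' @inheritParams theil_decompose
#' @return A list of class `theil_trend`: fields `resource`, `years`,
#'   `decompositions` (named by year). Use [trend_series()],
#'   [region_series()] and [contribution_series()] for tidy plotting frames.
#' @export
theil_trend <- function(panel, resource, zero_policy = c("error", "drop")) {
  stopifnot(inherits(panel, "resource_panel"))
  zero_policy <- match.arg(zero_policy)
  resource <- match.arg(resource, RESOURCES)
  years <- sort(unique(panel$records$year))
  if (length(years) < 2) {
    stop_healtheil("a trend needs >= 2 years", class = "healtheil_domain_error")
  }
  decomps <- list()
  for (yr in years) {
    rows <- dplyr::filter(panel$records, .data$year == yr)
    if (all(is.na(rows[[resource]]))) {
      warn_healtheil(sprintf("no %s counts in %d; year skipped", resource, yr))
      next
    }
    d <- theil_decompose(panel, resource, yr, zero_policy = zero_policy)
    decomps[[as.character(yr)]] <- contribution_rates(d)
  }
  structure(
    list(resource = resource,
         years = as.integer(names(decomps)),
         decompositions = decomps),
    class = "theil_trend"
  )
}

#' Tidy component series of a Theil trend
#'
#' @param trend a `theil_trend`.
#' @return A tibble `(year, component, value)` with components `T_total`,
#'   `T_within`, `T_between` — the shape of a total-index-by-year figure.
#' @export
trend_series <- function(trend) {
  stopifnot(inherits(trend, "theil_trend"))
  dplyr::bind_rows(lapply(trend$decompositions, function(d) {
    tibble::tibble(
      year = d$year,
      component = c("T_total", "T_within", "T_between"),
      value = c(d$total, d$within, d$between))
  }))
}

#' Tidy per-region within-group Theil series
#'
#' @param trend a `theil_trend`.
#' @return A tibble `(year, group, T_j)` — each region's internal Theil
#'   index by year, the shape of a per-region trend figure.
#' @export
region_series <- function(trend) {
  stopifnot(inherits(trend, "theil_trend"))
  dplyr::bind_rows(lapply(trend$decompositions, function(d) {
    tibble::tibble(year = d$year, group = d$groups$group, T_j = d$groups$T_j)
  }))
}

#' Tidy contribution-rate series
#'
#' @param trend a `theil_trend`.
#' @return A tibble `(year, component, rate)` where `component` is each
#'   region plus `"between"`; rates sum to 1 within a year (when the total
#'   index is nonzero).
#' @export
contribution_series <- function(trend) {
  stopifnot(inherits(trend, "theil_trend"))
  dplyr::bind_rows(lapply(trend$decompositions, function(d) {
    tibble::tibble(
      year = d$year,
      component = c(d$groups$group, "between"),
      rate = c(d$groups$contribution_rate, d$between_contribution_rate))
  }))
}
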