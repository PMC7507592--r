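#' Configuration for synthetic provincial panels
#'
#' Describes a 3-region provincial panel generator that mimics the structure
#' of the national yearbook panels: region-specific log-normal population,
#' area and per-capita density levels, and a deterministic multiplicative
#' annual drift per resource.
#'
#' Default parameter choices (all on the 10,000-person / km² scales):
#' * 12 western, 8 middle, 11 eastern provinces over 2013–2018, matching the
#'   standard partition of the 31 mainland provinces.
#' * Population and area log-normals set to yearbook magnitudes (western
#'   provinces fewer people and far larger areas).
#' * Density log-means per resource taken from the 2018 provincial medians
#'   (institutions ~0.13 per 10k, technical personnel ~4.8, beds ~1.7,
#'   equipment ~5.3), equal across regions by default.
#' * Density log-scales larger in the west (0.45 vs 0.30/0.35), reflecting
#'   the wider western dispersion visible in the provincial table.
#' * Drift factors equal to the 5-year geometric mean change of the national
#'   per-capita series: institutions 0.896 (the post-2015 institutional
#'   consolidation), personnel 1.022, beds 1.050, equipment 1.091.
#'
#' @param n_provinces named integer triple: provinces per region.
#' @param years integer vector of calendar years.
#' @param population_meanlog,population_sdlog per-region log-normal
#'   parameters of province population (10,000-person units).
#' @param area_meanlog,area_sdlog per-region log-normal parameters of
#'   province land area (km²).
#' @param density_meanlog matrix (region x resource) of log-mean per-10k
#'   densities; a named per-resource vector is recycled across regions.
#' @param density_sdlog matrix (region x resource) of log-scales; a named
#'   per-region vector is recycled across resources.
#' @param drift named per-resource multiplicative annual trend applied to
#'   densities after the first year.
#' @param zero_floor if `TRUE` (default), rounded counts of 0 are bumped to
#'   1 so panels satisfy the default `zero_policy = "error"`; set `FALSE` to
#'   produce true zeros for exercising the `"drop"` policy.
#' @param seed integer seed; [simulate_panel()] draws are fully determined
#'   by it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_provinces = c(western = 12L, middle = 8L, eastern = 11L),
    years = 2013:2018,
    population_meanlog = c(western = log(2000), middle = log(4200),
                           eastern = log(4500)),
    population_sdlog = c(western = 0.8, middle = 0.4, eastern = 0.7),
    area_meanlog = c(western = log(420000), middle = log(180000),
                     eastern = log(110000)),
    area_sdlog = c(western = 0.9, middle = 0.3, eastern = 0.7),
    density_meanlog = c(institutions = log(0.13),
                        technical_personnel = log(4.8),
                        beds = log(1.7), equipment = log(5.3)),
    density_sdlog = c(western = 0.45, middle = 0.30, eastern = 0.35),
    drift = c(institutions = 0.896, technical_personnel = 1.022,
              beds = 1.050, equipment = 1.091),
    zero_floor = TRUE,
    seed = 20130101L) {

  n_provinces <- as.integer(n_provinces)
  if (length(n_provinces) != 3 || any(is.na(n_provinces)) ||
      any(n_provinces < 1)) {
    stop_healtheil("n_provinces must be three positive integers",
                   class = "healtheil_config_error")
  }
  names(n_provinces) <- REGIONS
  years <- sort(unique(as.integer(years)))
  if (length(years) < 1) {
    stop_healtheil("years must be non-empty", class = "healtheil_config_error")
  }

  expand_regions <- function(x, what) {
    if (is.matrix(x)) {
      stopifnot(nrow(x) == 3, ncol(x) == 4)
      dimnames(x) <- list(REGIONS, RESOURCES)
      return(x)
    }
    if (!is.null(names(x)) && all(names(x) %in% RESOURCES)) {
      return(matrix(rep(x[RESOURCES], each = 3), nrow = 3,
                    dimnames = list(REGIONS, RESOURCES)))
    }
    if (!is.null(names(x)) && all(names(x) %in% REGIONS)) {
      return(matrix(rep(x[REGIONS], times = 4), nrow = 3,
                    dimnames = list(REGIONS, RESOURCES)))
    }
    stop_healtheil(sprintf(
      "%s must be a 3x4 matrix or a vector named by region or resource", what),
      class = "healtheil_config_error")
  }
  density_meanlog <- expand_regions(density_meanlog, "density_meanlog")
  density_sdlog <- expand_regions(density_sdlog, "density_sdlog")
  if (any(density_sdlog < 0) || any(population_sdlog < 0) ||
      any(area_sdlog < 0)) {
    stop_healtheil("log-scales must be >= 0", class = "healtheil_config_error")
  }
  drift <- drift[RESOURCES]
  if (anyNA(drift) || any(drift <= 0)) {
    stop_healtheil("drift must give a positive factor for every resource",
                   class = "healtheil_config_error")
  }

  structure(
    list(n_provinces = n_provinces, years = years,
         population_meanlog = population_meanlog[REGIONS],
         population_sdlog = population_sdlog[REGIONS],
         area_meanlog = area_meanlog[REGIONS],
         area_sdlog = area_sdlog[REGIONS],
         density_meanlog = density_meanlog, density_sdlog = density_sdlog,
         drift = drift, zero_floor = isTRUE(zero_floor),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a provincial resource panel
#'
#' Draws, from one seeded generator in a fixed order (populations, then
#' areas, then per-resource base densities, region by region):
#' * one population and one area per province, held fixed across years;
#' * one base per-10k density per (province, resource), evolved by the
#'   deterministic per-resource drift factor over the years;
#' * counts as `round(density x population)`, bumped to 1 where a zero would
#'   violate the default zero-share policy (see `zero_floor`).
#'
#' The result is a standard `resource_panel` (synthetic provenance) that
#' passes panel validation, with provinces named `W01..`, `M01..`, `E01..`.
#'
#' @param config a [simulation_config()].
#' @param seed optional override of `config$seed`.
#' @return A `resource_panel`.
#' @examples
#' panel <- simulate_panel(simulation_config(seed = 42))
#' theil_decompose(panel, "technical_personnel", 2018)
#' @export
simulate_panel <- function(config = simulation_config(), seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- as.integer(seed %||% config$seed)

  prefix <- c(western = "W", middle = "M", eastern = "E")
  provinces <- unlist(lapply(REGIONS, function(r) {
    sprintf("%s%02d", prefix[[r]], seq_len(config$n_provinces[[r]]))
  }))
  regions <- rep(REGIONS, times = config$n_provinces)
  n <- length(provinces)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  population <- rlnorm(n, config$population_meanlog[regions],
                       config$population_sdlog[regions])
  area <- rlnorm(n, config$area_meanlog[regions],
                 config$area_sdlog[regions])
  base_density <- sapply(RESOURCES, function(res) {
    rlnorm(n, config$density_meanlog[regions, res],
           config$density_sdlog[regions, res])
  })

  rows <- lapply(seq_along(config$years), function(k) {
    growth <- config$drift^(k - 1)
    counts <- round(base_density * population *
                    rep(growth, each = n))
    if (config$zero_floor) counts[counts == 0] <- 1
    tibble::tibble(
      year = config$years[k], province = provinces, region = regions,
      population = population, area = area,
      institutions = counts[, "institutions"],
      technical_personnel = counts[, "technical_personnel"],
      beds = counts[, "beds"],
      equipment = counts[, "equipment"])
  })
  records <- dplyr::bind_rows(rows)
  partition <- tibble::tibble(province = provinces, region = regions)
  panel <- resource_panel(records, partition = partition,
                          provenance = sprintf("synthetic (seed %d)", seed),
                          canonicalize = FALSE)
  panel
}

#' Analytic share-vector test cases
#'
#' Factory for share vectors with known Theil values:
#' * `"uniform"`: `n` units with `p = y = 1/n`, Theil value exactly 0.
#' * `"two_block"`: two units with population split `(pi, 1 - pi)` and
#'   resource split `(rho, 1 - rho)`; the Theil value has the closed form
#'   \deqn{\pi \ln(\pi/\rho) + (1-\pi)\ln((1-\pi)/(1-\rho)).}
#' * `"custom"`: shares passed through `p` and `y`.
#'
#' @param target `"uniform"`, `"two_block"` or `"custom"`.
#' @param n number of units (uniform).
#' @param pi,rho population and resource share of the first block
#'   (two_block), both strictly inside (0, 1).
#' @param p,y explicit shares (custom).
#' @return A [share_vector()].
#' @examples
#' theil_total(construct_shares("two_block", pi = 0.5, rho = 0.8)) # 0.2231...
#' @export
construct_shares <- function(target = c("uniform", "two_block", "custom"),
                             n = 31, pi = NULL, rho = NULL,
                             p = NULL, y = NULL) {
  target <- match.arg(target)
  switch(target,
    uniform = share_vector(sprintf("unit%02d", seq_len(n)),
                           rep(1 / n, n), rep(1 / n, n)),
    two_block = {
      if (is.null(pi) || is.null(rho) ||
          pi <= 0 || pi >= 1 || rho <= 0 || rho >= 1) {
        stop_healtheil("two_block needs pi and rho strictly inside (0, 1)",
                       class = "healtheil_domain_error")
      }
      share_vector(c("block_A", "block_B"), c(pi, 1 - pi), c(rho, 1 - rho))
    },
    custom = share_vector(paste0("unit", seq_along(p)), p, y)
  )
}
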