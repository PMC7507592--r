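test_that("per-capita densities reproduce the printed national series", {
  counts <- table1_counts()
  printed <- table1_printed_per10k()
  for (res in c("institutions", "technical_personnel", "beds", "equipment")) {
    got <- round_half_up(density_per_capita(counts[[res]],
                                            counts$population), 2)
    expect_equal(got, printed[[res]], info = res)
  }
})

test_that("density helpers enforce their domains", {
  expect_error(density_per_capita(10, 0), class = "healtheil_domain_error")
  expect_error(density_per_capita(-1, 10), class = "healtheil_domain_error")
  expect_error(density_per_area(10, -5), class = "healtheil_domain_error")
  expect_equal(density_per_capita(0, 100), 0)
})

test_that("round_half_up rounds ties away from zero", {
  expect_equal(round_half_up(c(0.125, -0.125, 2.5), c(2, 2, 0)),
               c(0.13, -0.13, 3))
})

test_that("percent_change reproduces printed changes in table_rounded mode", {
  # unrounded start/end densities from the national counts
  counts <- table1_counts()
  d <- function(res) density_per_capita(counts[[res]], counts$population)
  cases <- list(
    technical_personnel = 8.72, beds = 24.68, equipment = 50.28,
    institutions = -43.48)
  for (res in names(cases)) {
    v <- d(res)
    expect_equal(round_half_up(percent_change(v[1], v[6]), 2), cases[[res]],
                 info = res)
  }
  # raw mode differences the unrounded densities
  v <- d("institutions")
  expect_equal(round_half_up(percent_change(v[1], v[6], mode = "raw"), 2),
               -43.56)
  expect_equal(percent_change(3.3, 3.3), 0)
  expect_equal(percent_change(3.3, 3.3, mode = "raw"), 0)
})

test_that("percent_change rejects starts that round to zero", {
  expect_error(percent_change(0.001, 0.5), "raw",
               class = "healtheil_domain_error")
  expect_error(percent_change(0, 0.5, mode = "raw"),
               class = "healtheil_domain_error")
})

test_that("density_table aggregates TOTAL rows by summing before dividing", {
  panel <- paper_fixture("totals_2013_2018")
  tab <- density_table(panel)
  tot <- dplyr::filter(tab, province == "TOTAL")
  pick <- function(yr, res) tot$per_10k[tot$year == yr & tot$resource == res]
  expect_equal(round_half_up(pick(2018, "beds"), 2), 1.97)
  expect_equal(round_half_up(pick(2013, "equipment"), 2), 3.54)

  # single-province panel: TOTAL equals the province row
  one <- resource_panel(tibble::tibble(
    year = 2018, province = "A", population = 100, area = 50, beds = 30))
  t1 <- density_table(one)
  expect_equal(t1$per_10k[t1$province == "TOTAL"],
               t1$per_10k[t1$province == "A"])
  expect_equal(t1$per_km2[t1$province == "TOTAL"],
               t1$per_km2[t1$province == "A"])
})

test_that("TOTAL density is the population-weighted mean of province densities", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    pop <- runif(n, 10, 5000)
    beds <- sample.int(10000, n)
    panel <- resource_panel(tibble::tibble(
      year = 2015, province = sprintf("p%02d", 1:n), population = pop,
      beds = beds))
    tab <- density_table(panel)
    tot <- tab$per_10k[tab$province == "TOTAL"]
    prov <- dplyr::filter(tab, province != "TOTAL")
    expect_equal(tot, sum(prov$per_10k * pop[match(prov$province,
                                                   sprintf("p%02d", 1:n))]) /
                   sum(pop),
                 tolerance = 1e-9)
  }
})

test_that("monotonicity: raising one province's count raises its and the national density", {
  base <- tibble::tibble(
    year = 2015, province = c("A", "B", "C"),
    population = c(100, 200, 300), beds = c(10, 20, 30))
  t0 <- density_table(resource_panel(base))
  bumped <- base
  bumped$beds[2] <- bumped$beds[2] + 5
  t1 <- density_table(resource_panel(bumped))
  expect_gt(t1$per_10k[t1$province == "B"], t0$per_10k[t0$province == "B"])
  expect_gt(t1$per_10k[t1$province == "TOTAL"],
            t0$per_10k[t0$province == "TOTAL"])
  expect_equal(t1$per_10k[t1$province == "A"], t0$per_10k[t0$province == "A"])
})

test_that("extremes find min/max with alphabetical tie-breaks and safe ratios", {
  tab <- as_density_table(paper_fixture("provinces_2018"))
  e <- extremes(tab, "institutions", "per_10k", 2018)
  expect_equal(e$min_province, "Shanghai")
  expect_equal(e$min_value, 0.045)
  expect_equal(e$max_province, "Gansu")
  expect_equal(e$max_value, 0.529)

  # per-capita personnel: the table's true maximum is Guangxi, not the
  # narrative's Hainan (see density_ratio for the printed comparison)
  e2 <- extremes(tab, "technical_personnel", "per_10k", 2018)
  expect_equal(e2$max_province, "Guangxi")
  expect_equal(e2$max_value, 7.333)
  expect_equal(e2$min_province, "Anhui")
  expect_equal(e2$min_value, 2.709)

  # zero minimum: ratio is an undefined marker, not Inf
  e3 <- extremes(tab, "beds", "per_km2", 2018)
  expect_equal(e3$min_province, "Tibet")
  expect_equal(e3$min_value, 0)
  expect_true(is.na(e3$max_min_ratio))

  # ties break alphabetically
  flat <- tibble::tibble(year = 2018, province = c("B", "A", "C"),
                         region = NA_character_, resource = "beds",
                         per_10k = 1, per_km2 = NA_real_)
  class(flat) <- c("density_table", class(flat))
  ef <- extremes(flat, "beds", "per_10k", 2018)
  expect_equal(ef$min_province, "A")
  expect_equal(ef$max_province, "A")
  expect_equal(ef$max_min_ratio, 1)

  expect_error(extremes(tab, "equipment", "per_10k", 2018),
               class = "healtheil_domain_error")
})

test_that("scale invariance: rescaling counts preserves ratios and raw changes", {
  set.seed(42)
  n <- 12
  pop <- runif(n, 100, 5000)
  beds <- sample.int(5000, n)
  mk <- function(c_) {
    tab <- density_table(resource_panel(tibble::tibble(
      year = 2015, province = sprintf("p%02d", 1:n), population = pop,
      beds = beds * c_)))
    extremes(tab, "beds", "per_10k", 2015)$max_min_ratio
  }
  expect_equal(mk(1), mk(7.3), tolerance = 1e-12)
  expect_equal(percent_change(1.23, 4.56, mode = "raw"),
               percent_change(1.23 * 3, 4.56 * 3, mode = "raw"),
               tolerance = 1e-12)
})

test_that("pairwise density ratios reproduce printed comparisons", {
  tab <- as_density_table(paper_fixture("provinces_2018"))
  expect_equal(density_ratio(tab, "technical_personnel", "per_km2", 2018,
                             "Shanghai", "Tibet"), 1403)
  expect_equal(round_half_up(
    density_ratio(tab, "technical_personnel", "per_10k", 2018,
                  "Hainan", "Anhui"), 1), 2.3)
  expect_error(density_ratio(tab, "beds", "per_km2", 2018, "Gansu", "Tibet"),
               class = "healtheil_domain_error") # zero denominator
})
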