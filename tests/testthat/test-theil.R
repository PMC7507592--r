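test_that("theil_total matches hand-computed and closed-form values", {
  # perfect equality
  expect_equal(theil_total(p = rep(0.25, 4), y = rep(0.25, 4)), 0)
  # direct evaluation: 0.5 ln(0.5/0.8) + 0.5 ln(0.5/0.2) = 0.22314...
  expect_equal(round(theil_total(p = c(0.5, 0.5), y = c(0.8, 0.2)), 4),
               0.2231)
  expect_equal(theil_total(p = c(0.5, 0.5), y = c(0.8, 0.2)),
               0.5 * log(0.5 / 0.8) + 0.5 * log(0.5 / 0.2),
               tolerance = 1e-15)
  # permutation symmetry
  set.seed(7)
  p <- runif(6, 0.05, 1); p <- p / sum(p)
  y <- runif(6, 0.05, 1); y <- y / sum(y)
  o <- sample(6)
  expect_equal(theil_total(p = p, y = y), theil_total(p = p[o], y = y[o]),
               tolerance = 1e-15)
})

test_that("share_vector enforces its invariants", {
  expect_error(share_vector(c("a", "b"), c(0.6, 0.6), c(0.5, 0.5)),
               "sum to 1", class = "healtheil_domain_error")
  expect_error(share_vector(c("a", "b"), c(0, 1), c(0.5, 0.5)),
               "strictly positive", class = "healtheil_domain_error")
  expect_error(share_vector(c("a", "a"), c(0.5, 0.5), c(0.5, 0.5)),
               "unique", class = "healtheil_domain_error")
  expect_silent(share_vector(c("a", "b"), c(0.5, 0.5), c(1, 0)))
})

test_that("zero resource shares follow the configured policy", {
  expect_error(theil_total(p = c(0.5, 0.5), y = c(1, 0)), "unit2",
               class = "healtheil_zero_share")
  expect_warning(
    v <- theil_total(p = c(0.25, 0.25, 0.5), y = c(0.5, 0.5, 0),
                     zero_policy = "drop"),
    class = "healtheil_zero_share_warning")
  # after dropping unit 3 and renormalizing, p = y = (0.5, 0.5)
  expect_equal(v, 0)
})

test_that("4-province/2-group decomposition matches the hand-worked oracle", {
  d <- theil_decompose(four_province_panel(), "beds", 2018)
  expect_equal(round(d$total, 4), 0.1218)
  expect_equal(round(d$between, 4), 0.0204)
  expect_equal(round(d$within, 4), 0.1014)
  # identity against the independent ungrouped oracle
  expect_equal(d$total, oracle_theil(rep(250, 4), c(400, 200, 300, 100)),
               tolerance = 1e-15)

  d <- contribution_rates(d)
  expect_equal(round(d$between_contribution_rate, 4), 0.1676)
  expect_equal(round(sort(d$groups$contribution_rate), 4), c(0.2418, 0.5906))
  expect_equal(d$between_contribution_rate + sum(d$groups$contribution_rate),
               1, tolerance = 1e-12)
})

test_that("contribution rates are undefined (NA) at zero total inequality", {
  panel <- resource_panel(tibble::tibble(
    year = 2018, province = c("A", "B", "C", "D"),
    region = c("g1", "g1", "g2", "g2"),
    population = c(100, 200, 300, 400),
    beds = c(10, 20, 30, 40)), canonicalize = FALSE)
  d <- theil_decompose(panel, "beds", 2018)
  expect_lt(d$total, 1e-12)
  expect_warning(d <- contribution_rates(d),
                 class = "healtheil_zero_total_warning")
  expect_true(all(is.na(d$groups$contribution_rate)))
  expect_true(is.na(d$between_contribution_rate))
})

test_that("decomposition identity and oracle equivalence hold on random panels", {
  set.seed(20180101)
  for (i in 1:300) {
    n <- sample(4:40, 1)
    panel <- random_counts_panel(n)
    d <- theil_decompose(panel, "beds", 2000)
    expect_lt(abs(d$total - d$within - d$between), 1e-12)
    expect_equal(d$total,
                 oracle_theil(panel$records$population, panel$records$beds),
                 tolerance = 1e-12)
    expect_gte(d$between, 0)
    expect_gte(d$within, -1e-15)
    expect_true(all(d$groups$T_j >= -1e-15))
  }
})

test_that("Theil is zero iff resource shares are proportional to population", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    pop <- runif(n, 10, 1000)
    prop <- pop / sum(pop)
    expect_lt(theil_total(p = prop, y = prop), 1e-12)
    y <- runif(n, 0.05, 1); y <- y / sum(y)
    t <- theil_total(p = prop, y = y)
    if (max(abs(prop - y)) > 1e-3) expect_gt(t, 1e-12)
    if (t < 1e-12) expect_lt(max(abs(prop - y)), 1e-9)
  }
})

test_that("decompositions are invariant to rescaling all counts", {
  set.seed(5)
  panel <- random_counts_panel(15)
  d1 <- contribution_rates(theil_decompose(panel, "beds", 2000))
  scaled <- panel
  scaled$records$beds <- scaled$records$beds * 17
  d2 <- contribution_rates(theil_decompose(scaled, "beds", 2000))
  expect_equal(d1$total, d2$total, tolerance = 1e-12)
  expect_equal(d1$groups$contribution_rate, d2$groups$contribution_rate,
               tolerance = 1e-12)
})

test_that("singleton groups put all inequality between groups", {
  panel <- resource_panel(tibble::tibble(
    year = 2018, province = c("A", "B", "C"),
    region = c("g1", "g2", "g3"),
    population = c(100, 200, 300),
    beds = c(90, 10, 200)), canonicalize = FALSE)
  d <- theil_decompose(panel, "beds", 2018)
  expect_equal(d$within, 0)
  expect_equal(d$between, d$total)
})

test_that("merging groups never increases the between component", {
  set.seed(123)
  for (i in 1:40) {
    n <- sample(6:30, 1)
    panel <- random_counts_panel(n, k = 4)
    d_fine <- theil_decompose(panel, "beds", 2000)
    merged <- panel
    labs <- unique(merged$records$region)
    merged$records$region[merged$records$region == labs[2]] <- labs[1]
    if (length(unique(merged$records$region)) < 2) next
    d_coarse <- theil_decompose(merged, "beds", 2000)
    expect_lte(d_coarse$between, d_fine$between + 1e-12)
    expect_equal(d_coarse$total, d_fine$total, tolerance = 1e-12)
  }
})

test_that("group-level zero resources follow the zero policy", {
  panel <- resource_panel(tibble::tibble(
    year = 2018, province = c("A", "B", "C", "D"),
    region = c("g1", "g1", "g2", "g2"),
    population = c(100, 100, 100, 100),
    beds = c(10, 20, 0, 0)), canonicalize = FALSE)
  expect_error(theil_decompose(panel, "beds", 2018),
               class = "healtheil_zero_share")
  expect_warning(d <- theil_decompose(panel, "beds", 2018,
                                      zero_policy = "drop"),
                 class = "healtheil_zero_share_warning")
  expect_equal(d$groups$group, "g1")
})

test_that("theil_trend orders years, skips missing ones, and emits tidy series", {
  rec <- dplyr::bind_rows(
    tibble::tibble(year = 2014, province = c("A", "B", "C", "D"),
                   region = c("g1", "g1", "g2", "g2"),
                   population = c(100, 200, 300, 400),
                   beds = c(40, 20, 30, 10)),
    tibble::tibble(year = 2013, province = c("A", "B", "C", "D"),
                   region = c("g1", "g1", "g2", "g2"),
                   population = c(100, 200, 300, 400),
                   beds = c(35, 25, 25, 15)),
    tibble::tibble(year = 2015, province = c("A", "B", "C", "D"),
                   region = c("g1", "g1", "g2", "g2"),
                   population = c(100, 200, 300, 400),
                   beds = NA_real_))
  panel <- resource_panel(rec, canonicalize = FALSE)
  expect_warning(tr <- theil_trend(panel, "beds"), "skipped")
  expect_equal(tr$years, c(2013L, 2014L))

  ts <- trend_series(tr)
  expect_equal(sort(unique(ts$component)),
               c("T_between", "T_total", "T_within"))
  expect_equal(sort(unique(ts$year)), c(2013, 2014))
  rs <- region_series(tr)
  expect_equal(sort(unique(rs$group)), c("g1", "g2"))
  cs <- contribution_series(tr)
  sums <- tapply(cs$rate, cs$year, sum)
  expect_equal(as.vector(sums), c(1, 1), tolerance = 1e-12)
})

test_that("constant shares give a flat trend; growing divergence a rising one", {
  base <- tibble::tibble(province = c("A", "B", "C", "D"),
                         region = c("g1", "g1", "g2", "g2"),
                         population = c(100, 200, 300, 400))
  flat <- dplyr::bind_rows(lapply(2013:2018, function(yr) {
    dplyr::mutate(base, year = yr, beds = population * 2)
  }))
  # rates are undefined at zero total inequality, so the trend warns per year
  w <- capture_warnings(
    tr <- theil_trend(resource_panel(flat, canonicalize = FALSE), "beds"))
  expect_length(w, 6)
  expect_true(all(grepl("undefined", w)))
  totals <- vapply(tr$decompositions, `[[`, numeric(1), "total")
  expect_true(all(totals < 1e-12))

  # divergence grows each year -> per-year oracle says T rises monotonically
  growing <- dplyr::bind_rows(lapply(0:5, function(k) {
    beds <- c(100 + 60 * k, 200, 300, 400 - 60 * k)
    dplyr::mutate(base, year = 2013 + k, beds = beds)
  }))
  # first year is exactly proportional, so its rates are undefined (warns)
  w2 <- capture_warnings(
    tr2 <- theil_trend(resource_panel(growing, canonicalize = FALSE), "beds"))
  expect_length(w2, 1)
  totals2 <- vapply(tr2$decompositions, `[[`, numeric(1), "total")
  expect_true(all(diff(totals2) > 0))
  oracle <- vapply(0:5, function(k) {
    oracle_theil(base$population, c(100 + 60 * k, 200, 300, 400 - 60 * k))
  }, numeric(1))
  expect_equal(unname(totals2), oracle, tolerance = 1e-12)
})
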