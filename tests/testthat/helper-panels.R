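# Shared fixture builders. Everything is generated in code; random draws
# always sit inside the test's own set.seed() scope.

table1_counts <- function() {
  tibble::tibble(
    year = 2013:2018,
    province = "National total",
    population = c(136072, 136782, 137462, 138271, 139008, 139538),
    institutions = c(31155, 35029, 31927, 24866, 19896, 18033),
    technical_personnel = c(608560, 631558, 639189, 646425, 661616, 678258),
    beds = c(214870, 223033, 236342, 247228, 262570, 274394),
    equipment = c(481148, 530587, 572371, 618857, 686572, 742759)
  )
}

# The published 2-decimal per-10,000-capita densities of the national series.
table1_printed_per10k <- function() {
  tibble::tibble(
    year = 2013:2018,
    institutions = c(0.23, 0.26, 0.23, 0.18, 0.14, 0.13),
    technical_personnel = c(4.47, 4.62, 4.65, 4.68, 4.76, 4.86),
    beds = c(1.58, 1.63, 1.72, 1.79, 1.89, 1.97),
    equipment = c(3.54, 3.88, 4.16, 4.48, 4.94, 5.32)
  )
}

# A small hand-built 4-province, 2-group counts panel with equal populations
# and resource shares (0.4, 0.2 | 0.3, 0.1) of a total of 1000 beds.
four_province_panel <- function() {
  resource_panel(
    tibble::tibble(
      year = 2018,
      province = c("P1", "P2", "P3", "P4"),
      region = c("g1", "g1", "g2", "g2"),
      population = rep(250, 4),
      beds = c(400, 200, 300, 100)),
    canonicalize = FALSE)
}

# Random counts panel: n provinces in k groups, one year. Counts >= 1.
random_counts_panel <- function(n, k = sample(2:4, 1), year = 2000) {
  groups <- paste0("g", sample.int(k, n, replace = TRUE))
  while (length(unique(groups)) < 2) {
    groups <- paste0("g", sample.int(k, n, replace = TRUE))
  }
  resource_panel(
    tibble::tibble(
      year = year,
      province = sprintf("p%03d", seq_len(n)),
      region = groups,
      population = stats::runif(n, 50, 12000),
      beds = sample.int(50000, n)),
    canonicalize = FALSE)
}

# Independent brute-force oracle: ungrouped mean-log-deviation Theil from
# raw population and count vectors, plain base R.
oracle_theil <- function(population, count) {
  p <- population / sum(population)
  y <- count / sum(count)
  sum(p * log(p / y))
}
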