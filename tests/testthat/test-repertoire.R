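# Cohort statistics: occupancy-based frequencies, ratios, heat maps and
# the two-sample test.

test_that("frequencies follow the lambda counting rule", {
  f <- screen_frequencies(30000, 0.1, n_igg_sc = 90, n_igm_sc = 60)
  expect_equal(f$n_cells, 3000)
  expect_equal(f$freq_igg, 3.0)
  expect_equal(f$freq_igm, 2.0)
  expect_equal(f$freq_ig_total, f$freq_igg + f$freq_igm)

  z <- screen_frequencies(30000, 0.1, 0, 0)
  expect_equal(z$freq_ig_total, 0)
  expect_warning(sr <- switch_ratio(z$freq_igg, z$freq_igm), "undefined")
  expect_true(is.na(sr))
})

test_that("frequency estimates land inside the binomial confidence band", {
  set.seed(606)
  n_cells <- 3000
  p_true <- 0.03
  for (i in 1:5) {
    k <- rbinom(1, n_cells, p_true)
    f <- screen_frequencies(n_cells / 0.1, 0.1, n_igg_sc = k, n_igm_sc = 0)
    half <- 100 * qnorm(0.975) * sqrt(p_true * (1 - p_true) / n_cells)
    expect_lt(abs(f$freq_igg - 100 * p_true), half + 1e-9)
  }
})

test_that("cohort summaries use the reporting conventions", {
  s <- cohort_summary(c(2.5, 2.5, 2.5))
  expect_equal(s$sd, 0)
  expect_equal(s$center, 2.5)

  ## adjuvant-only preset: 1.6 % IgM + 0.15 % IgG = 1.75, printed as 1.8
  expect_warning(alum1 <- cohort_summary(1.6 + 0.15), "single mouse")
  expect_equal(round_half_up(alum1$center, 1), 1.8)
  expect_true(is.na(alum1$sd))

  rates <- cohort_summary(c(240, 250, 900), type = "secretion")
  expect_equal(rates$center, 250)  # median, robust to the outlier
})

test_that("ratios and fractions reproduce the worked cohort arithmetic", {
  expect_equal(switch_ratio(3.12, 3.2), 0.975)
  expect_equal(round_half_up(switch_ratio(3.12, 3.2), 1), 1.0)
  expect_equal(switch_ratio(0, 2), 0)

  expect_equal(specific_fraction(0.68, 3.12), 0.218, tolerance = 1e-3)
  expect_equal(specific_fraction(0.40, 2.17), 0.184, tolerance = 5e-3)
  expect_equal(specific_fraction(0, 3), 0)
  expect_warning(sf <- specific_fraction(0.5, 0), "undefined")
  expect_true(is.na(sf))

  expect_equal(crossreactivity(1.2, 1.2), 1.0)
  expect_warning(cr <- crossreactivity(0.5, 0), "undefined")
  expect_true(is.na(cr))
})

fake_records <- function(kd_class, epitope_class) {
  data.frame(droplet_id = seq_along(kd_class), kd_class = kd_class,
             epitope_class = epitope_class, stringsAsFactors = FALSE)
}

test_that("heat maps normalise, carry marginals and flag emptiness", {
  one <- fake_records(rep("high", 5), rep("high", 5))
  hm <- repertoire_heatmap(one)
  expect_equal(unname(unclass(hm)["high", "high"]), 1)
  expect_equal(sum(unclass(hm)), 1, tolerance = 1e-12)
  expect_equal(unname(attr(hm, "row_marginals")["high"]), 1)

  empty <- repertoire_heatmap(fake_records(character(0), character(0)))
  expect_true(attr(empty, "empty"))
  expect_true(all(unclass(empty) == 0))

  set.seed(707)
  n <- 3000
  unif <- fake_records(sample(c("high", "intermediate", "low"), n, TRUE),
                       sample(c("low", "intermediate", "high"), n, TRUE))
  hmu <- repertoire_heatmap(unif)
  ## multinomial CI around 1/9 at n = 3000
  half <- qnorm(0.995) * sqrt((1 / 9) * (8 / 9) / n)
  expect_true(all(abs(unclass(hmu) - 1 / 9) < half + 0.005))
  expect_equal(sum(unclass(hmu)), 1, tolerance = 1e-12)
  ## marginals consistent with the cells
  expect_equal(attr(hmu, "row_marginals"), rowSums(unclass(hmu)))
})

test_that("heat-map differences are signed and sum to zero", {
  a <- repertoire_heatmap(fake_records(c("high", "high", "low"),
                                       c("high", "high", "low")))
  b <- repertoire_heatmap(fake_records(c("high", "low", "low"),
                                       c("high", "low", "low")))
  expect_true(all(heatmap_difference(a, a) == 0))
  d <- heatmap_difference(a, b)
  expect_equal(sum(d), 0, tolerance = 1e-12)
  expect_equal(d["high", "high"], 2 / 3 - 1 / 3, tolerance = 1e-12)
})

test_that("the pooled t-test matches the incomplete-beta oracle", {
  set.seed(808)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1), mean = runif(1, 0, 3))
    b <- rnorm(sample(3:8, 1), mean = runif(1, 0, 3))
    got <- ttest_two_tailed(a, b)
    want <- pooled_t_oracle(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$df, want$df)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  expect_equal(ttest_two_tailed(c(1, 2, 3), c(1, 2, 3))$p, 1)
  ## tiny variance, clear separation: p collapses toward zero
  expect_lt(ttest_two_tailed(c(1, 1 + 1e-9, 1 - 1e-9),
                             c(2, 2 + 1e-9, 2 - 1e-9))$p, 1e-12)
  ## Welch flag reaches the unequal-variance test
  w <- ttest_two_tailed(c(1, 2, 3, 4), c(2, 4, 9, 12), welch = TRUE)
  expect_lt(w$df, 6)
})

test_that("printed-precision rounding is half away from zero", {
  expect_equal(round_half_up(1.75, 1), 1.8)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(10.19, 0), 10)
})
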