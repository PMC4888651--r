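test_that("t-test matches the closed-form pooled formula", {
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    got <- ttest_two_sample(a, b)
    ref <- brute_ttest(a, b)
    expect_equal(got$t_statistic, ref$t, tolerance = 1e-12)
    expect_equal(got$p_value, ref$p, tolerance = 1e-12)
  }
})

test_that("t-test conventions: identity, strong shifts, degenerate variance", {
  tt0 <- ttest_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt0$t_statistic, 0)
  expect_equal(tt0$p_value, 1)
  tt <- ttest_two_sample(c(1, 2, 3), c(11, 12, 13))
  expect_lt(tt$p_value, 0.001)
  expect_equal(tt$df, 4)
  # zero variance, equal means -> p = 1 by convention
  ttc <- ttest_two_sample(c(5, 5, 5), c(5, 5))
  expect_equal(ttc$p_value, 1)
  expect_error(ttest_two_sample(c(5, 5), c(6, 6)), class = "oct_degenerate_variance")
  expect_error(ttest_two_sample(1, c(1, 2)), class = "oct_validation_error")
})

test_that("t-test is symmetric in group order", {
  set.seed(11)
  a <- rnorm(6); b <- rnorm(8, 1)
  t1 <- ttest_two_sample(a, b)
  t2 <- ttest_two_sample(b, a)
  expect_equal(t1$p_value, t2$p_value)
  expect_equal(t1$t_statistic, -t2$t_statistic)
  expect_named(tidy(t1), c("estimate", "t_statistic", "df", "p_value", "n_a", "n_b"))
})

test_that("group summaries match brute-force quantiles for the documented convention", {
  v <- 1:8
  s7 <- summarize_group(v) # type 7: h = (n-1)p + 1
  brute_q7 <- function(p) { h <- (8 - 1) * p + 1; lo <- floor(h); v[lo] + (h - lo) * (v[min(lo + 1, 8)] - v[lo]) }
  expect_equal(s7$q1, brute_q7(0.25))
  expect_equal(s7$median, brute_q7(0.5))
  expect_equal(s7$q3, brute_q7(0.75))
  # the classical halves convention is available as type 2
  s2 <- summarize_group(v, quantile_type = 2)
  expect_equal(c(s2$q1, s2$median, s2$q3), c(2.5, 4.5, 6.5))
})

test_that("whiskers clamp to extreme non-outlier points and list outliers", {
  v <- c(1:10, 100)
  s <- summarize_group(v)
  iqr <- s$q3 - s$q1
  expect_lte(s$whisker_high, s$q3 + 1.5 * iqr)
  expect_equal(s$whisker_high, 10) # clamped to the data
  expect_equal(s$whisker_low, 1)
  expect_equal(s$outliers[[1]], 100)
  # degenerate summaries
  sc <- summarize_group(rep(4, 5))
  expect_equal(c(sc$whisker_low, sc$whisker_high, sc$q1, sc$q3), rep(4, 4))
  s1 <- summarize_group(42)
  expect_equal(c(s1$mean, s1$median, s1$whisker_low, s1$whisker_high), rep(42, 4))
  expect_error(summarize_group(numeric()), class = "oct_validation_error")
})

test_that("synergy table flags only real exceedance of both monotherapies", {
  set.seed(3)
  mk <- function(tr, day, mu) tibble::tibble(
    well_id = paste0(tr, day, 1:4), treatment = tr, day = day,
    disruption_index = mu + rnorm(4, sd = 0.01))
  # combination identical in distribution to the best monotherapy
  rec <- dplyr::bind_rows(
    mk("A", 1, 0.5), mk("B", 1, 0.3), mk("combination", 1, 0.5),
    mk("A", 2, 0.5), mk("B", 2, 0.3), mk("combination", 2, 1.0))
  syn <- synergy_table(rec, metrics = "disruption_index",
                       combination = "combination", monotherapies = c("A", "B"))
  expect_false(syn$synergy[syn$day == 1])
  expect_true(syn$synergy[syn$day == 2])
  expect_equal(syn$mono_best, c("A", "A"))
  # additive construction flags every day
  rec2 <- dplyr::bind_rows(lapply(1:3, function(d) dplyr::bind_rows(
    mk("A", d, 0.4), mk("B", d, 0.3), mk("combination", d, 0.7))))
  syn2 <- synergy_table(rec2, metrics = "disruption_index",
                        combination = "combination", monotherapies = c("A", "B"))
  expect_true(all(syn2$synergy))
  # missing arm is a hard error naming it
  expect_error(synergy_table(dplyr::filter(rec, treatment != "B"),
                             metrics = "disruption_index",
                             combination = "combination", monotherapies = c("A", "B")),
               "B", class = "oct_validation_error")
})

test_that("bonferroni option only rescales p-values", {
  set.seed(5)
  mk <- function(tr, day, mu) tibble::tibble(
    well_id = paste0(tr, day, 1:3), treatment = tr, day = day,
    m = mu + rnorm(3, sd = 0.05))
  rec <- dplyr::bind_rows(lapply(1:2, function(d) dplyr::bind_rows(
    mk("A", d, 0.4), mk("B", d, 0.3), mk("combination", d, 0.9))))
  s0 <- synergy_table(rec, metrics = "m", combination = "combination",
                      monotherapies = c("A", "B"))
  s1 <- synergy_table(rec, metrics = "m", combination = "combination",
                      monotherapies = c("A", "B"), p_adjust = "bonferroni")
  expect_equal(s1$p_value, pmin(s0$p_value * nrow(s0), 1))
})

test_that("summarize_arms produces one row per arm and day", {
  rec <- tibble::tibble(treatment = rep(c("NT", "PDT"), each = 6),
                        day = rep(c(0, 2, 4), 4),
                        sa_to_v = runif(12, 0.05, 0.2))
  s <- summarize_arms(rec, "sa_to_v")
  expect_equal(nrow(s), 6L)
  expect_true(all(s$q1 <= s$median & s$median <= s$q3))
})
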