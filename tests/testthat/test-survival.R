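test_that("product-limit estimate matches hand computation and empirical survival", {
  # one death each at days 1..4, no censoring
  tab <- death_table(1:4)
  km <- km_estimate(tab, by = "regime")
  expect_equal(km$surv[km$time == 2], 0.5)
  expect_equal(km$surv[km$time == 4], 0)
  expect_equal(km$greenwood_var[km$time == 4], 0)

  # censoring keeps individuals at risk through their census day
  tab2 <- tibble::tibble(regime = "G", day = 1, n_dead = 1L, n_censored = 1L)
  km2 <- km_estimate(tab2, by = "regime")
  expect_equal(km2$surv[km2$time == 1], 0.5)

  # 10-row mixed table against the brute-force product over intervals
  set.seed(42)
  tab3 <- tibble::tibble(
    regime = "G",
    day = sort(sample(1:20, 10)),
    n_dead = rpois(10, 3),
    n_censored = rbinom(10, 2, 0.4)
  )
  km3 <- km_estimate(tab3, by = "regime")
  oracle <- hand_km(tab3$day, tab3$n_dead, tab3$n_censored)
  expect_equal(km3$time, oracle$time)
  expect_equal(km3$surv, oracle$surv, tolerance = 1e-12)
  expect_equal(km3$n_risk, oracle$n_risk)

  # without censoring the estimate is the empirical survival function
  set.seed(43)
  for (rep in 1:5) {
    days <- sample(1:30, 12)
    dead <- rpois(12, 2) + 1L
    tabr <- tibble::tibble(regime = "G", day = days, n_dead = dead, n_censored = 0L)
    kmr <- km_estimate(tabr, by = "regime")
    n <- sum(dead)
    emp <- vapply(kmr$time, function(t) sum(dead[days > t]) / n, numeric(1))
    expect_equal(kmr$surv, emp, tolerance = 1e-12)
  }
})

test_that("fully censored groups warn and leave percentiles undefined", {
  tab <- tibble::tibble(regime = "G", day = c(2, 4), n_dead = 0L, n_censored = c(3L, 2L))
  expect_warning(km <- km_estimate(tab, by = "regime"), "fully censored")
  expect_true(all(km$surv == 1))
  pct <- km_percentile(km, 0.5)
  expect_false(pct$defined)
  expect_true(is.na(pct$day))
})

test_that("percentile lifespans invert the curve at each level", {
  tab <- death_table(1:4)
  km <- km_estimate(tab, by = "regime")
  expect_equal(km_percentile(km, 0.5)$day, 2)

  # S never reaches 0.1 -> undefined with flag, not imputed
  tab2 <- tibble::tibble(regime = "G", day = c(1, 2, 3),
                         n_dead = c(1L, 1L, 1L), n_censored = c(0L, 0L, 1L))
  km2 <- km_estimate(tab2, by = "regime") # S_min = 0.25
  p <- km_percentile(km2, 0.1)
  expect_false(p$defined)
  expect_true(is.na(p$day))

  # non-increasing in level, ci_low <= day <= ci_high where defined
  set.seed(9)
  tab3 <- death_table(round(rgompertz(400, 0.004, 0.09), 1))
  km3 <- km_estimate(tab3, by = "regime")
  pct <- km_percentile(km3, c(0.9, 0.5, 0.1))
  expect_true(all(diff(pct$day) >= 0)) # levels descend, days ascend
  expect_true(all(pct$ci_low <= pct$day & pct$day <= pct$ci_high))
})

test_that("log-rank test matches its sampling distribution and structure", {
  # identical groups: statistic 0, p 1
  tab <- death_table(1:6)
  both <- dplyr::bind_rows(
    dplyr::mutate(tab, regime = "A"),
    dplyr::mutate(tab, regime = "B")
  )
  lr <- logrank(both, by = "regime")
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  # four groups -> 3 degrees of freedom
  four <- dplyr::bind_rows(lapply(c("A", "B", "C", "D"), function(g) {
    set.seed(match(g, LETTERS))
    death_table(round(rgompertz(30, 0.01, 0.08), 1), group = g)
  }))
  expect_equal(logrank(four, by = "regime")$df, 3)

  expect_error(logrank(tab, by = "regime"), "two groups")

  # p-value close to a 20,000-rep permutation null for two small groups
  set.seed(7)
  da <- round(rgompertz(8, 0.01, 0.08), 1)
  db <- round(rgompertz(8, 0.02, 0.08), 1)
  small <- dplyr::bind_rows(death_table(da, "A"), death_table(db, "B"))
  lr2 <- logrank(small, by = "regime")
  day <- c(da, db)
  set.seed(8)
  perm <- replicate(20000, {
    g <- sample(rep(c("A", "B"), each = 8))
    survival::survdiff(survival::Surv(day, rep(1, 16)) ~ g)$chisq
  })
  p_perm <- mean(perm >= lr2$chisq - 1e-12)
  expect_lt(abs(lr2$p - p_perm), 0.05)
})

test_that("pairwise log-rank applies Benjamini-Hochberg step-up correctly", {
  set.seed(31)
  tabs <- dplyr::bind_rows(lapply(1:4, function(i) {
    death_table(round(rgompertz(40, 0.002 * i, 0.08), 1), group = LETTERS[i])
  }))
  pw <- pairwise_logrank(tabs, by = "regime")
  expect_equal(nrow(pw), choose(4, 2))
  expect_equal(pw$p_adj, hand_bh(pw$p), tolerance = 1e-12)
  # BH never shrinks below raw and preserves the p-value ordering
  expect_true(all(pw$p_adj >= pw$p))
  expect_true(all(diff(pw$p_adj[order(pw$p)]) >= -1e-12))

  # a single pair is returned unadjusted
  pw2 <- pairwise_logrank(tabs[tabs$regime %in% c("A", "B"), ], by = "regime")
  expect_equal(pw2$p_adj, pw2$p)

  # 8 groups -> 28 comparisons
  set.seed(32)
  tabs8 <- dplyr::bind_rows(lapply(1:8, function(i) {
    death_table(round(rgompertz(25, 0.004, 0.05 + 0.01 * i), 1),
                group = LETTERS[i])
  }))
  expect_equal(nrow(pairwise_logrank(tabs8, by = "regime")), 28)
})

test_that("midpoint timing places grouped deaths at interval midpoints", {
  tab <- tibble::tibble(regime = "G", day = c(2, 4, 7),
                        n_dead = c(1L, 1L, 2L), n_censored = 0L)
  km <- km_estimate(tab, by = "regime", timing = "midpoint")
  expect_equal(km$time, c(1, 3, 5.5))
  expect_equal(km$surv, c(0.75, 0.5, 0))
})
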