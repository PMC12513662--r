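test_that("Gompertz sampler matches closed-form behaviour", {
  cfg_exp <- regime_config("E",
    gompertz_a = c(female = 0.05, male = 0.05),
    gompertz_b = c(female = 0, male = 0),
    fecundity_segments = data.frame(start_day = 0, rate = 1),
    n_flies = 2000, censor_prob = 0
  )
  cohort <- simulate_cohort(cfg_exp, n_cages = 1, seed = 11)
  # b = 0: exponential with mean 1/a = 20
  se <- 20 / sqrt(nrow(cohort))
  expect_lt(abs(mean(cohort$death_day) - 20), 3 * se)

  # higher hazard growth shortens the median; compare to the closed-form
  # Gompertz median obtained by numerical root-finding on the CDF
  set.seed(21)
  t1 <- rgompertz(5000, a = 0.001, b = 0.1)
  t2 <- rgompertz(5000, a = 0.001, b = 0.2)
  med <- function(a, b) {
    stats::uniroot(function(t) exp(-(a / b) * expm1(b * t)) - 0.5,
                   c(1e-6, 500), tol = 1e-10)$root
  }
  m1 <- med(0.001, 0.1)
  m2 <- med(0.001, 0.2)
  expect_lt(m2, m1)
  expect_lt(stats::median(t2), stats::median(t1))
  expect_lt(abs(stats::median(t1) - m1), 1.5)
  expect_lt(abs(stats::median(t2) - m2), 1.5)

  expect_error(rgompertz(5, a = -1, b = 0.1), "must be > 0")
})

test_that("simulated lifespans follow the generating Gompertz distribution", {
  set.seed(2024)
  a <- 0.004; b <- 0.08
  x <- rgompertz(2000, a, b)
  ks <- suppressWarnings(
    stats::ks.test(x, function(t) 1 - exp(-(a / b) * expm1(b * t))))
  expect_gt(ks$p.value, 0.01)
})

test_that("same configuration and seed reproduce cohorts and censuses exactly", {
  cfg <- default_regime_configs()$HH
  cfg$n_flies <- 50L
  c1 <- simulate_cohort(cfg, n_cages = 2, seed = 99)
  c2 <- simulate_cohort(cfg, n_cages = 2, seed = 99)
  expect_identical(c1, c2)
  # per-cage substreams: adding a cage does not perturb existing cages
  c3 <- simulate_cohort(cfg, n_cages = 3, seed = 99)
  expect_identical(c1, c3[c3$cage_id %in% unique(c1$cage_id), ])

  st1 <- simulate_study(tiny_configs(25)[c("HH", "LL")], n_cages = 2, seed = 7)
  st2 <- simulate_study(tiny_configs(25)[c("HH", "LL")], n_cages = 2, seed = 7)
  expect_identical(st1$deaths, st2$deaths)
  expect_identical(st1$eggs, st2$eggs)
  # byte-identical files on disk
  d1 <- file.path(tempdir(), "cagedemog_det1")
  d2 <- file.path(tempdir(), "cagedemog_det2")
  write_census(st1, d1)
  write_census(st2, d2)
  for (f in c("deaths.csv", "eggs.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("death censusing bins events to the next census and conserves totals", {
  cohort <- tibble::tibble(
    id = c("a", "b"), cage_id = "X_c1", regime = "X", sex = "female",
    death_day = c(1.5, 2.9), censor_day = NA_real_
  )
  obs <- observe_deaths(cohort, schedule = c(2, 5))
  expect_equal(obs$day, c(2, 5))
  expect_equal(obs$n_dead, c(1, 1))

  expect_equal(nrow(observe_deaths(cohort[0, ], schedule = c(2, 5))), 0)

  cfg <- default_regime_configs()$LH
  cfg$n_flies <- 250L
  cohort <- simulate_cohort(cfg, n_cages = 2, seed = 5)
  obs <- observe_deaths(cohort, schedule = census_schedule(10))
  # schedule far too short: events beyond it are binned, never dropped
  expect_equal(sum(obs$n_dead) + sum(obs$n_censored), nrow(cohort))
  # every individual contributes exactly one terminal event
  expect_equal(sum(obs$n_dead), sum(is.na(cohort$censor_day)))
  expect_equal(sum(obs$n_censored), sum(!is.na(cohort$censor_day)))
})

test_that("census schedules follow the Mon/Wed/Fri cadence", {
  s <- census_schedule(30)
  expect_true(all(diff(s) %in% c(2L, 3L)))
  expect_equal(s[1:4], c(2L, 4L, 6L, 9L))
  ext <- cagedemog:::extend_schedule(s, 60)
  expect_true(all(diff(ext) %in% c(2L, 3L)))
  expect_gte(max(ext), 60)
})

test_that("egg censusing draws Poisson counts scaled by females alive", {
  # 50 females all dying late, constant rate 2 -> mean eggs 100 per census
  cohort <- tibble::tibble(
    id = sprintf("f%02d", 1:50), cage_id = "X_c1", regime = "X",
    sex = "female", death_day = 100, censor_day = NA_real_
  )
  cfg <- regime_config("X",
    gompertz_a = c(female = 0.01, male = 0.01),
    gompertz_b = c(female = 0, male = 0),
    fecundity_segments = data.frame(start_day = 0, rate = 2),
    n_flies = 25, censor_prob = 0
  )
  eggs <- observe_eggs(cohort, cfg, schedule = c(2, 4, 7), seed = 3)
  # all deaths are binned at the final (extended) census; before it kx = 50
  live <- eggs$day < 100
  expect_true(all(abs(eggs$eggs[live] - 100) <= 4 * sqrt(100)))
  expect_true(all(eggs$eggs[!live] == 0))

  # all females already dead: zero eggs, deterministically
  dead <- dplyr::mutate(cohort, death_day = 1)
  eggs0 <- observe_eggs(dead, cfg, schedule = c(2, 4, 7), seed = 3)
  expect_true(all(eggs0$eggs == 0))
})

test_that("peak delay shifts the planted segment boundaries verbatim", {
  cfgs <- tiny_configs(20)
  st <- simulate_study(cfgs[c("HH", "HL")], n_cages = 1, seed = 13)
  expect_equal(st$truth$planted_breaks$HL,
               st$truth$planted_breaks$HH + 14)
  # before the shifted onset the delayed regime lays nothing
  expect_equal(cagedemog:::fecundity_rate(cfgs$HL, c(0, 7, 13)), c(0, 0, 0))
  expect_gt(cagedemog:::fecundity_rate(cfgs$HL, 14), 0)
})

test_that("regime configuration validation rejects bad inputs", {
  seg <- data.frame(start_day = c(0, 5), rate = c(1, 2))
  good <- list(gompertz_a = c(female = 0.01, male = 0.01),
               gompertz_b = c(female = 0.1, male = 0.1))
  expect_error(regime_config("X", c(female = -1, male = 1), good$gompertz_b, seg),
               "> 0")
  expect_error(regime_config("X", good$gompertz_a, good$gompertz_b,
                             data.frame(start_day = c(5, 5), rate = c(1, 2))),
               "strictly increasing")
  expect_error(regime_config("X", good$gompertz_a, good$gompertz_b, seg,
                             censor_prob = 1), "censor_prob")
  expect_error(regime_config("X", good$gompertz_a, good$gompertz_b, seg,
                             n_flies = 0), "n_flies")
})
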