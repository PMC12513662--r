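test_that("life table survivorship, trapezoid nLx and mx follow the censuses", {
  # two flies: one dies by day 2, one by day 4 -> l = (1, 0.5, 0)
  deaths <- tibble::tibble(regime = "G", sex = "female", day = c(2, 4),
                           n_dead = c(1L, 1L), n_censored = 0L)
  eggs <- tibble::tibble(regime = "G", day = c(2, 4), eggs = c(3L, 0L))
  lt <- build_life_table(deaths, eggs, by = "regime")
  expect_equal(lt$x, c(0, 2))
  expect_equal(lt$lx, c(1, 0.5))
  expect_equal(lt$nLx, c(0.75, 0.25))
  expect_equal(lt$kx, c(2, 1))
  expect_equal(lt$mx, c(0, 3))

  # no deaths over three censuses: cohort fully alive, lx = nLx = 1
  deaths0 <- tibble::tibble(regime = "G", sex = "female", day = c(2, 4, 7),
                            n_dead = 0L, n_censored = 0L)
  eggs0 <- tibble::tibble(regime = "G", day = c(2, 4, 7), eggs = 0L)
  expect_warning(lt0 <- build_life_table(deaths0, eggs0, by = "regime"),
                 "fully alive")
  expect_true(all(lt0$lx == 1))
  expect_true(all(lt0$nLx == 1))

  # noiseless discrete cohort: lx reproduces the generating schedule exactly
  fx <- noiseless_fixture()
  ns <- noiseless_study(fx$lx, fx$mx, fx$n0, fx$schedule)
  lt2 <- build_life_table(ns$deaths, ns$eggs, by = "regime")
  keep <- fx$lx > 0
  expect_equal(lt2$lx, fx$lx[keep], tolerance = 1e-12)
  expect_equal(lt2$mx, fx$mx[keep], tolerance = 1e-12)
})

test_that("Leslie matrices put fecundity on the top row and survival on the subdiagonal", {
  lt <- tibble::tibble(x = c(0, 2), nLx = c(1, 0.5), mx = c(0, 2))
  A <- build_leslie(lt)
  expect_equal(unname(A), matrix(c(0, 0.5, 2, 0), 2, 2))

  # fertile first class: characteristic polynomial x^2 - x - 1 = 0
  ltg <- tibble::tibble(x = c(0, 2), nLx = c(1, 0.5), mx = c(1, 2))
  expect_equal(eigen_analysis(build_leslie(ltg))$lambda, (1 + sqrt(5)) / 2,
               tolerance = 1e-10)

  # survival ratios capped at 1, zero fertility allowed
  ltz <- tibble::tibble(x = c(0, 2, 4), nLx = c(0.8, 0.9, 0.3), mx = c(0, 0, 0))
  Az <- build_leslie(ltz)
  expect_equal(Az[2, 1], 1)
  expect_warning(ez <- eigen_analysis(Az), "nilpotent")
  expect_equal(ez$lambda, 0)

  expect_error(build_leslie(tibble::tibble(x = 0, nLx = 1, mx = 2)),
               "two intervals")
  expect_error(build_leslie(tibble::tibble(x = c(0, 2, 4), nLx = c(1, 0, 0.2),
                                           mx = c(0, 1, 1))),
               "non-finite")
})

test_that("eigen analysis returns lambda, stable structure, Vx and damping ratio", {
  # periodic matrix: eigenvalues +-1, real tie-break picks +1, no damping
  A1 <- matrix(c(0, 0.5, 2, 0), 2, 2)
  e1 <- eigen_analysis(A1)
  expect_equal(e1$lambda, 1, tolerance = 1e-10)
  expect_equal(e1$rho, 1, tolerance = 1e-10)

  # quadratic formula: lambda = (1 + sqrt(3))/2, rho = (1+sqrt(3))/(sqrt(3)-1)
  A2 <- matrix(c(1, 0.5, 1, 0), 2, 2)
  e2 <- eigen_analysis(A2)
  expect_equal(e2$lambda, (1 + sqrt(3)) / 2, tolerance = 1e-10)
  expect_equal(e2$rho, (1 + sqrt(3)) / (sqrt(3) - 1), tolerance = 1e-10)

  # 1x1: lambda is the single entry, damping undefined
  expect_warning(e3 <- eigen_analysis(matrix(2.5, 1, 1)), "undefined")
  expect_equal(e3$lambda, 2.5)
  expect_true(is.na(e3$rho))

  expect_error(eigen_analysis(matrix(1:6, 2, 3)), "square")
  expect_error(eigen_analysis(matrix(c(1, -0.1, 1, 0), 2, 2)), "non-negative")
})

test_that("eigen analysis agrees with characteristic-polynomial root search", {
  fixtures <- list(
    matrix(c(0, 0.5, 2, 0), 2, 2),
    matrix(c(1, 0.5, 1, 0), 2, 2),
    matrix(c(0.2, 0.9, 0, 1.5, 0, 0.8, 3, 0, 0.1), 3, 3, byrow = TRUE),
    matrix(c(0, 2, 4, 1,
             0.9, 0, 0, 0,
             0, 0.7, 0, 0,
             0, 0, 0.4, 0), 4, 4, byrow = TRUE),
    matrix(c(0.5, 1, 0, 0,
             0.6, 0, 0, 0,
             0, 0.8, 0.2, 0,
             0, 0, 0.5, 0.1), 4, 4, byrow = TRUE)
  )
  for (A in fixtures) {
    expect_equal(eigen_analysis(A)$lambda, charpoly_lambda(A), tolerance = 1e-8)
  }
})

test_that("Perron-Frobenius structure holds for primitive Leslie matrices", {
  set.seed(77)
  for (r in 1:20) {
    k <- sample(2:6, 1)
    mx <- c(runif(k - 1, 0, 3), runif(1, 0.5, 3))
    mx[1] <- runif(1, 0.1, 1) # fertile first class -> primitive
    P <- runif(k - 1, 0.2, 0.95)
    A <- matrix(0, k, k)
    A[1, ] <- mx
    A[cbind(2:k, 1:(k - 1))] <- P
    ea <- eigen_analysis(A)
    # strictly positive stable age distribution and reproductive values
    expect_true(all(ea$stable_age > 0))
    expect_true(all(ea$repro_value > 0))
    expect_equal(sum(ea$stable_age), 1, tolerance = 1e-12)
    expect_equal(ea$repro_value[1], 1)
    # eigenpair residuals
    expect_lt(max(abs(A %*% ea$stable_age - ea$lambda * ea$stable_age)), 1e-8)
    expect_lt(max(abs(t(ea$repro_value) %*% A - ea$lambda * t(ea$repro_value))), 1e-8)
    expect_gte(ea$rho, 1)
    # scaling all fertilities up strictly increases lambda
    A2 <- A
    A2[1, ] <- A[1, ] * 1.5
    expect_gt(eigen_analysis(A2)$lambda, ea$lambda)
  }
})

test_that("reproductive value summaries report max, min and range", {
  expect_equal(vx_summary(c(6.384, 1.5, 0.200))$range_vx, 6.184)
  expect_equal(vx_summary(c(7.515, 2, 0.325))$range_vx, 7.190)
  expect_equal(vx_summary(rep(1.3, 5))$range_vx, 0)
  ea <- eigen_analysis(matrix(c(1, 0.5, 1, 0), 2, 2))
  vs <- vx_summary(ea)
  expect_equal(vs$max_vx - vs$min_vx, vs$range_vx)
})

test_that("end-to-end lambda recovery through the observation path is exact", {
  fx <- noiseless_fixture()
  ns <- noiseless_study(fx$lx, fx$mx, fx$n0, fx$schedule)
  ds <- demography_summary(ns$deaths, ns$eggs, by = "regime")
  expect_equal(ds$lambda, ns$truth$lambda, tolerance = 1e-8)
  # and the recovered matrix itself matches the generating one
  lt <- build_life_table(ns$deaths, ns$eggs, by = "regime")
  expect_equal(unname(build_leslie(lt)), unname(ns$truth$matrix), tolerance = 1e-12)
})

test_that("group demographic summaries run per regime", {
  cfgs <- tiny_configs(60)[c("HH", "LH")]
  st <- simulate_study(cfgs, n_cages = 2, seed = 23)
  ds <- demography_summary(st$deaths, st$eggs, by = "regime")
  expect_equal(sort(ds$regime), c("HH", "LH"))
  expect_true(all(ds$lambda > 0))
  expect_true(all(ds$rho >= 1))
  expect_equal(ds$range_vx, ds$max_vx - ds$min_vx)
})
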