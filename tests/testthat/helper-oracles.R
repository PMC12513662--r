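# Independent oracles and small fixture builders shared across test files.
# These deliberately avoid the package's own computation paths.

# Brute-force product-limit estimator from grouped counts:
# walks distinct days in order, S *= (1 - d/n) with censors leaving the risk
# set after their day.
hand_km <- function(day, n_dead, n_censored) {
  ord <- order(day)
  day <- day[ord]; n_dead <- n_dead[ord]; n_censored <- n_censored[ord]
  days <- sort(unique(day))
  at_risk <- sum(n_dead) + sum(n_censored)
  s <- 1
  out <- data.frame(time = days, surv = NA_real_, n_risk = NA_real_)
  for (i in seq_along(days)) {
    d <- sum(n_dead[day == days[i]])
    c_ <- sum(n_censored[day == days[i]])
    out$n_risk[i] <- at_risk
    if (d > 0) s <- s * (1 - d / at_risk)
    out$surv[i] <- s
    at_risk <- at_risk - d - c_
  }
  out
}

# Characteristic polynomial coefficients by Faddeev-LeVerrier; dominant
# real root by polyroot. Independent check of eigen_analysis for k <= 4.
charpoly_lambda <- function(A) {
  k <- nrow(A)
  cs <- numeric(k + 1) # coefficients of lambda^k ... lambda^0
  cs[1] <- 1
  M <- diag(k)
  for (i in seq_len(k)) {
    M <- A %*% M
    c_i <- -sum(diag(M)) / i
    cs[i + 1] <- c_i
    M <- M + diag(c_i, k)
  }
  roots <- polyroot(rev(cs))
  mods <- Mod(roots)
  cand <- which(mods >= max(mods) - 1e-8)
  Re(roots[cand[which.max(Re(roots[cand]))]])
}

# One-death-per-row census table from continuous event days.
death_table <- function(days, group = "G", sex = "female", censored = logical(length(days))) {
  tibble::tibble(
    regime = group, sex = sex, day = days,
    n_dead = as.integer(!censored), n_censored = as.integer(censored)
  )
}

# Benjamini-Hochberg step-up by definition.
hand_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(ord)]
}

# Discrete noiseless generating model used by recovery tests: survivorship
# steps on an 8-census Mon/Wed/Fri axis with whole-number death counts.
noiseless_fixture <- function() {
  schedule <- census_schedule(19) # 2 4 6 9 11 13 16 18 20
  lx <- c(1, 0.95, 0.85, 0.70, 0.50, 0.30, 0.15, 0.05, 0.025, 0)
  mx <- c(0, 0.5, 2, 4, 3, 2, 1, 0.5, 0.2, 0)
  list(schedule = schedule, lx = lx, mx = mx, n0 = 400)
}

# Small stochastic study used by pipeline-level tests (scaled down from the
# study's cage sizes to keep the suite fast).
tiny_configs <- function(n_flies = 40) {
  cfgs <- default_regime_configs()
  lapply(cfgs, function(cfg) {
    cfg$n_flies <- as.integer(n_flies)
    cfg
  })
}
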