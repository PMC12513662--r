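#' Configuration for one diet regime
#'
#' Bundles everything needed to simulate one experimental regime of a
#' larval x adult diet factorial: sex-specific Gompertz mortality, a
#' piecewise-constant per-female egg-laying rate observed in 3-hour windows,
#' an optional shift of the laying schedule (low adult protein delays the
#' fecundity peak), the number of flies released per cage and sex, and a
#' small per-census probability of censoring (escapes, accidental deaths).
#'
#' @param regime Regime label, conventionally one of `"HH"`, `"HL"`, `"LH"`,
#'   `"LL"` (first letter larval protein level, second adult).
#' @param gompertz_a Named numeric vector `c(female =, male =)` of baseline
#'   hazards (per day, > 0).
#' @param gompertz_b Named numeric vector of hazard growth rates (per day,
#'   >= 0; 0 gives exponential lifespans).
#' @param fecundity_segments Data frame with columns `start_day` (strictly
#'   increasing) and `rate` (eggs per female per 3-hour window, >= 0),
#'   defining a piecewise-constant laying rate. Days before the first
#'   segment have rate 0.
#' @param peak_delay_days Shift (days) applied to every segment boundary;
#'   models the delayed egg-laying peak under low adult protein.
#' @param n_flies Initial flies per cage per sex.
#' @param censor_prob Per-census, per-fly censoring probability in `[0, 1)`.
#' @param sex_ratio Proportion of females among `2 * n_flies` flies released
#'   per cage. The default 0.5 splits the sexes evenly; the study did not
#'   report cage sex ratios.
#' @return An object of class `regime_config`.
#' @examples
#' cfg <- regime_config("HH",
#'   gompertz_a = c(female = 0.004, male = 0.002),
#'   gompertz_b = c(female = 0.08, male = 0.09),
#'   fecundity_segments = data.frame(start_day = c(0, 10, 40), rate = c(2, 5, 0.5))
#' )
#' @export
regime_config <- function(regime,
                          gompertz_a,
                          gompertz_b,
                          fecundity_segments,
                          peak_delay_days = 0,
                          n_flies = 160,
                          censor_prob = 0.001,
                          sex_ratio = 0.5) {
  gompertz_a <- unlist(gompertz_a)
  gompertz_b <- unlist(gompertz_b)
  for (sx in c("female", "male")) {
    if (!sx %in% names(gompertz_a) || !sx %in% names(gompertz_b)) {
      abort("gompertz_a and gompertz_b must be named vectors with 'female' and 'male' entries")
    }
  }
  if (any(gompertz_a <= 0)) abort("gompertz_a must be > 0 for both sexes")
  if (any(gompertz_b < 0)) abort("gompertz_b must be >= 0 for both sexes")
  fecundity_segments <- tibble::as_tibble(fecundity_segments)
  check_count_columns(fecundity_segments, c("start_day", "rate"), "fecundity_segments")
  if (nrow(fecundity_segments) < 1) abort("fecundity_segments needs at least one segment")
  if (any(diff(fecundity_segments$start_day) <= 0)) {
    abort("fecundity_segments start_day must be strictly increasing")
  }
  if (any(fecundity_segments$rate < 0)) abort("fecundity rates must be >= 0")
  if (n_flies < 1) abort("n_flies must be >= 1")
  if (censor_prob < 0 || censor_prob >= 1) abort("censor_prob must be in [0, 1)")
  if (sex_ratio <= 0 || sex_ratio >= 1) abort("sex_ratio must be in (0, 1)")
  structure(
    list(
      regime = as.character(regime),
      gompertz_a = gompertz_a[c("female", "male")],
      gompertz_b = gompertz_b[c("female", "male")],
      fecundity_segments = fecundity_segments,
      peak_delay_days = peak_delay_days,
      n_flies = as.integer(n_flies),
      censor_prob = censor_prob,
      sex_ratio = sex_ratio
    ),
    class = "regime_config"
  )
}

#' @export
print.regime_config <- function(x, ...) {
  cat("<regime_config> ", x$regime, "\n", sep = "")
  cat("  flies/cage/sex: ", x$n_flies, ", censor_prob: ", x$censor_prob, "\n", sep = "")
  cat("  Gompertz a (F/M): ", paste(signif(x$gompertz_a, 3), collapse = " / "),
      ";  b (F/M): ", paste(signif(x$gompertz_b, 3), collapse = " / "), "\n", sep = "")
  cat("  fecundity segments (delay ", x$peak_delay_days, " d): ",
      paste(sprintf("%g d: %g", x$fecundity_segments$start_day + x$peak_delay_days,
                    x$fecundity_segments$rate), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Gompertz lifespan sampler
#'
#' Draws lifespans by inverse-CDF from the Gompertz distribution with
#' survival \eqn{S(t) = \exp(-(a/b)(e^{bt} - 1))}:
#' \eqn{T = (1/b)\log(1 - (b/a)\log U)}. With `b = 0` lifespans are
#' exponential with rate `a`.
#'
#' @param n Number of draws.
#' @param a Baseline hazard (> 0).
#' @param b Hazard growth rate (>= 0).
#' @return Numeric vector of lifespans in days.
#' @export
rgompertz <- function(n, a, b) {
  if (a <= 0) abort("Gompertz baseline hazard a must be > 0")
  if (b < 0) abort("Gompertz growth rate b must be >= 0")
  if (b == 0) {
    return(stats::rexp(n, rate = a))
  }
  u <- stats::runif(n)
  (1 / b) * log1p(-(b / a) * log(u))
}

#' Gompertz quantile function
#'
#' Day at which survival falls to `p` under Gompertz(`a`, `b`).
#'
#' @inheritParams rgompertz
#' @param p Survival fraction in (0, 1).
#' @export
qgompertz_surv <- function(p, a, b) {
  stopifnot(all(p > 0 & p < 1), a > 0, b >= 0)
  if (b == 0) {
    return(-log(p) / a)
  }
  (1 / b) * log1p(-(b / a) * log(p))
}

#' Solve Gompertz parameters from two survival quantiles
#'
#' Finds `(a, b)` such that survival reaches `p1` at day `t1` and `p2` at
#' day `t2` (numerical root-finding on the quantile ratio). Used to encode
#' observed median and maximal lifespans into generating hazards.
#'
#' @param t1,t2 Days (t2 > t1 > 0).
#' @param p1,p2 Survival fractions at `t1` and `t2` (p2 < p1).
#' @return Named vector `c(a =, b =)`.
#' @export
gompertz_from_quantiles <- function(t1, t2, p1 = 0.5, p2 = 0.1) {
  stopifnot(t2 > t1, t1 > 0, p2 < p1, p1 < 1, p2 > 0)
  r <- log(p2) / log(p1)
  # b = 0 limit corresponds to t2/t1 == r exactly
  f <- function(b) (exp(b * t2) - 1) / (exp(b * t1) - 1) - r
  if (abs(t2 / t1 - r) < 1e-10) {
    b <- 0
  } else if (t2 / t1 > r) {
    abort("quantiles imply a decreasing hazard; not representable by Gompertz")
  } else {
    b <- stats::uniroot(f, lower = 1e-9, upper = 2, tol = 1e-12)$root
  }
  a <- if (b == 0) -log(p1) / t1 else b * (-log(p1)) / (exp(b * t1) - 1)
  c(a = a, b = b)
}

#' Monday/Wednesday/Friday census schedule
#'
#' Integer census days post-eclosion with the thrice-weekly cadence of the
#' assay: repeating +2, +2, +3 day gaps (Mon -> Wed -> Fri -> Mon).
#'
#' @param last_day Schedule covers at least this day.
#' @param first_day First census day (default 2: the first observation after
#'   release at day 0).
#' @return Integer vector of census days.
#' @examples
#' census_schedule(16) # 2 4 7 9 11 14 16
#' @export
census_schedule <- function(last_day, first_day = 2) {
  stopifnot(last_day >= first_day, first_day >= 0)
  gaps <- rep(c(2L, 2L, 3L), length.out = ceiling((last_day - first_day) / 2) + 3)
  days <- as.integer(first_day) + c(0L, cumsum(gaps))
  days[seq_len(which(days >= last_day)[1])]
}

# Extend a census schedule (gaps in {2, 3}) past `last_day` by continuing the
# repeating +2,+2,+3 cycle. Events beyond the last census are never dropped.
extend_schedule <- function(schedule, last_day) {
  schedule <- sort(unique(as.integer(schedule)))
  while (max(schedule) < last_day) {
    tail_days <- utils::tail(schedule, 3)
    gaps <- diff(tail_days)
    next_gap <- if (length(gaps) >= 2 && gaps[length(gaps)] == 2 && gaps[length(gaps) - 1] == 2) 3L else 2L
    if (length(gaps) >= 1 && gaps[length(gaps)] == 3) next_gap <- 2L
    schedule <- c(schedule, max(schedule) + next_gap)
  }
  schedule
}

# Per-female laying rate at integer day(s) `day` under a config (segment
# boundaries shifted by peak_delay_days; rate 0 before the first boundary).
fecundity_rate <- function(config, day) {
  starts <- config$fecundity_segments$start_day + config$peak_delay_days
  rates <- config$fecundity_segments$rate
  idx <- findInterval(day, starts)
  out <- numeric(length(day))
  out[idx > 0] <- rates[idx[idx > 0]]
  out
}

#' Simulate individual-level cohorts for one regime
#'
#' Draws continuous lifespans per fly from the regime's sex-specific Gompertz
#' model and applies independent per-census censoring. Each cage gets its own
#' RNG substream derived from the master seed, so cages are statistically
#' independent and adding a cage never perturbs earlier ones.
#'
#' @param config A [regime_config()].
#' @param n_cages Number of replicate cages.
#' @param seed Master integer seed.
#' @param schedule Optional census days used for censoring opportunities;
#'   defaults to a Mon/Wed/Fri schedule covering the longest lifespan drawn.
#' @return A tibble of individuals: `id`, `cage_id`, `regime`, `sex`,
#'   `death_day` (continuous), `censor_day` (integer census day or `NA`;
#'   always `< death_day` when present).
#' @export
simulate_cohort <- function(config, n_cages, seed, schedule = NULL) {
  stopifnot(inherits(config, "regime_config"), n_cages >= 1)
  cage_seeds <- spawn_seeds(seed, n_cages)
  cages <- lapply(seq_len(n_cages), function(ci) {
    set.seed(cage_seeds[ci])
    n_f <- round(2 * config$n_flies * config$sex_ratio)
    n_m <- 2 * config$n_flies - n_f
    sex <- rep(c("female", "male"), c(n_f, n_m))
    death <- c(
      rgompertz(n_f, config$gompertz_a[["female"]], config$gompertz_b[["female"]]),
      rgompertz(n_m, config$gompertz_a[["male"]], config$gompertz_b[["male"]])
    )
    sched <- schedule %||% census_schedule(max(ceiling(death)) + 1)
    sched <- extend_schedule(sched, max(ceiling(death)))
    # number of census opportunities strictly before death
    k <- findInterval(death, sched, left.open = TRUE)
    censor_day <- rep(NA_integer_, length(death))
    if (config$censor_prob > 0) {
      g <- stats::rgeom(length(death), prob = config$censor_prob)
      hit <- g < k
      censor_day[hit] <- sched[g[hit] + 1L]
    }
    tibble::tibble(
      id = sprintf("%s_c%d_%04d", config$regime, ci, seq_along(death)),
      cage_id = sprintf("%s_c%d", config$regime, ci),
      regime = config$regime,
      sex = sex,
      death_day = death,
      censor_day = as.numeric(censor_day)
    )
  })
  dplyr::bind_rows(cages)
}

#' Degrade a cohort to the death-census observation format
#'
#' Assigns every death or censoring event to the first census day at or after
#' its event time and tallies counts per cage, sex and day. Totals are
#' conserved: every individual contributes exactly one terminal event.
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @param schedule Integer census days. Extended (never truncated) if any
#'   event falls beyond the last census.
#' @return Tibble with columns `cage_id`, `regime`, `sex`, `day`, `n_dead`,
#'   `n_censored` (only days with events appear).
#' @export
observe_deaths <- function(cohort, schedule) {
  cohort <- tibble::as_tibble(cohort)
  if (nrow(cohort) == 0) {
    return(tibble::tibble(
      cage_id = character(), regime = character(), sex = character(),
      day = integer(), n_dead = integer(), n_censored = integer()
    ))
  }
  event_time <- ifelse(is.na(cohort$censor_day), cohort$death_day, cohort$censor_day)
  is_censor <- !is.na(cohort$censor_day)
  schedule <- extend_schedule(schedule, max(ceiling(event_time)))
  # first census day >= event time
  idx <- findInterval(event_time, schedule, left.open = TRUE) + 1L
  tibble::tibble(
    cage_id = cohort$cage_id, regime = cohort$regime, sex = cohort$sex,
    day = schedule[idx], censored = is_censor
  ) |>
    dplyr::group_by(.data$cage_id, .data$regime, .data$sex, .data$day) |>
    dplyr::summarise(
      n_dead = sum(!.data$censored),
      n_censored = sum(.data$censored),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cage_id, .data$sex, .data$day)
}

#' Observe cage-level egg counts
#'
#' For every census day, the number of eggs laid in the 3-hour window is
#' drawn as Poisson with mean (per-female rate at that day) x (females
#' counted alive at the window). A female counts as alive at day `d` if her
#' terminal event has not been recorded at a census day `<= d` - the same
#' post-census convention the life-table stage uses for `kx`, so generator
#' and analysis agree exactly in noiseless settings.
#'
#' @inheritParams observe_deaths
#' @param config The generating [regime_config()].
#' @param seed Integer seed (per-cage substreams derived from it).
#' @param poisson If `FALSE`, returns the expected (deterministic) counts,
#'   rounded to integers - the noiseless observation mode.
#' @return Tibble with columns `cage_id`, `regime`, `day`, `eggs`.
#' @export
observe_eggs <- function(cohort, config, schedule, seed, poisson = TRUE) {
  cohort <- tibble::as_tibble(cohort)
  females <- cohort[cohort$sex == "female", , drop = FALSE]
  cages <- sort(unique(cohort$cage_id))
  if (length(cages) == 0) {
    return(tibble::tibble(cage_id = character(), regime = character(),
                          day = integer(), eggs = integer()))
  }
  event_time <- ifelse(is.na(females$censor_day), females$death_day, females$censor_day)
  schedule <- extend_schedule(schedule, max(ceiling(c(event_time, 0))))
  binned <- schedule[findInterval(event_time, schedule, left.open = TRUE) + 1L]
  cage_seeds <- spawn_seeds(seed, length(cages))
  out <- lapply(seq_along(cages), function(ci) {
    cg <- cages[ci]
    bd <- binned[females$cage_id == cg]
    kx <- vapply(schedule, function(d) sum(bd > d), numeric(1))
    mu <- fecundity_rate(config, schedule) * kx
    set.seed(cage_seeds[ci])
    eggs <- if (poisson) stats::rpois(length(mu), mu) else as.integer(round(mu))
    tibble::tibble(cage_id = cg, regime = config$regime,
                   day = as.integer(schedule), eggs = as.integer(eggs))
  })
  dplyr::bind_rows(out)
}

#' Default regime configurations for the 2 x 2 diet factorial
#'
#' Generating parameters chosen to emulate the published study's design and
#' summary patterns: four regimes (HH, HL, LH, LL) with two replicate cages,
#' cage sizes matching the reported final counts (638, 676, 856, 742 flies
#' over two cages each), Gompertz hazards solved from the reported median and
#' maximal (10% survival) lifespans per sex, a piecewise-constant laying rate
#' with an early peak, and a two-week shift of the laying schedule in the low
#' adult protein regimes (HL, LL).
#'
#' @return Named list of four [regime_config()] objects.
#' @export
default_regime_configs <- function() {
  # per-sex (median day, 10%-survival day) from the study's summary table
  q <- list(
    HH = list(female = c(26, 57), male = c(38, 68), n = 160),
    HL = list(female = c(36, 64), male = c(38, 87), n = 169),
    LH = list(female = c(31, 64), male = c(38, 78), n = 214),
    LL = list(female = c(36, 64), male = c(43, 87), n = 186)
  )
  segs <- list(
    HH = tibble::tibble(start_day = c(0, 7, 30, 55), rate = c(2.0, 5.0, 1.5, 0.3)),
    HL = tibble::tibble(start_day = c(0, 7, 30, 55), rate = c(2.0, 5.5, 2.0, 0.4)),
    LH = tibble::tibble(start_day = c(0, 7, 30, 55), rate = c(3.0, 8.0, 2.0, 0.4)),
    LL = tibble::tibble(start_day = c(0, 7, 30, 55), rate = c(2.5, 6.5, 2.0, 0.5))
  )
  delay <- c(HH = 0, HL = 14, LH = 0, LL = 14)
  out <- lapply(names(q), function(rg) {
    gf <- gompertz_from_quantiles(q[[rg]]$female[1], q[[rg]]$female[2])
    gm <- gompertz_from_quantiles(q[[rg]]$male[1], q[[rg]]$male[2])
    regime_config(
      regime = rg,
      gompertz_a = c(female = unname(gf["a"]), male = unname(gm["a"])),
      gompertz_b = c(female = unname(gf["b"]), male = unname(gm["b"])),
      fecundity_segments = segs[[rg]],
      peak_delay_days = delay[[rg]],
      n_flies = q[[rg]]$n,
      censor_prob = 0.001
    )
  })
  names(out) <- names(q)
  out
}

#' Simulate a full cage study
#'
#' Runs [simulate_cohort()], [observe_deaths()] and [observe_eggs()] for every
#' regime and bundles the census tables with a ground-truth sidecar (the
#' individual table, the planted fecundity-segment boundaries, and the
#' expected life-table lambda per regime) for recovery tests.
#'
#' @param configs Named list of [regime_config()]s (default
#'   [default_regime_configs()]).
#' @param n_cages Replicate cages per regime (default 2).
#' @param seed Master integer seed.
#' @return An object of class `cage_study`: list with tibbles `deaths`,
#'   `eggs`, the integer `schedule`, and a `truth` list.
#' @export
simulate_study <- function(configs = default_regime_configs(), n_cages = 2, seed = 42) {
  stopifnot(length(configs) >= 1)
  regime_seeds <- spawn_seeds(seed, 2 * length(configs))
  cohorts <- purrr::imap(configs, function(cfg, i) {
    simulate_cohort(cfg, n_cages, seed = regime_seeds[match(i, names(configs))])
  })
  max_day <- max(purrr::map_dbl(cohorts, ~ max(.x$death_day)))
  schedule <- census_schedule(ceiling(max_day))
  deaths <- purrr::map(cohorts, observe_deaths, schedule = schedule) |> dplyr::bind_rows()
  eggs <- purrr::imap(configs, function(cfg, nm) {
    observe_eggs(cohorts[[nm]], cfg, schedule,
                 seed = regime_seeds[length(configs) + match(nm, names(configs))])
  }) |> dplyr::bind_rows()
  truth <- list(
    configs = configs,
    individuals = dplyr::bind_rows(cohorts),
    planted_breaks = purrr::map(configs, function(cfg) {
      cfg$fecundity_segments$start_day + cfg$peak_delay_days
    }),
    lambda = purrr::map_dbl(configs, expected_lambda, schedule = schedule),
    seed = seed
  )
  structure(list(deaths = deaths, eggs = eggs, schedule = schedule, truth = truth),
            class = "cage_study")
}

#' @export
print.cage_study <- function(x, ...) {
  cat("<cage_study> ", dplyr::n_distinct(x$deaths$regime), " regime(s), ",
      dplyr::n_distinct(x$deaths$cage_id), " cage(s), censuses to day ",
      max(x$schedule), "\n", sep = "")
  cat("  deaths table: ", nrow(x$deaths), " rows; eggs table: ", nrow(x$eggs),
      " rows\n", sep = "")
  invisible(x)
}

# Expected (deterministic) life-table lambda implied by a config on a given
# schedule: female Gompertz survivorship at census days, per-female rates as
# mx, trapezoid nLx, Leslie matrix, dominant eigenvalue.
expected_lambda <- function(config, schedule) {
  a <- config$gompertz_a[["female"]]
  b <- config$gompertz_b[["female"]]
  surv <- function(t) if (b == 0) exp(-a * t) else exp(-(a / b) * expm1(b * t))
  days <- c(0, schedule)
  lx <- vapply(days, surv, numeric(1))
  mx <- c(0, fecundity_rate(config, schedule))
  lt <- tibble::tibble(
    x = days,
    lx = lx,
    lx_next = c(lx[-1], 0),
    nLx = (lx + c(lx[-1], 0)) / 2,
    mx = mx
  )
  keep <- lt$lx > 1e-12
  lt <- lt[keep, , drop = FALSE]
  A <- leslie_from_vectors(lt$mx, lt$nLx)
  eigen_analysis(A)$lambda
}

#' Construct a noiseless study from a discrete generating model
#'
#' Places deaths for a single female cohort exactly on census days according
#' to a known discrete survival schedule and emits exact (expectation) egg
#' counts, routing both through the same observation path as stochastic
#' simulations. The returned truth carries the generating Leslie matrix and
#' its dominant eigenvalue, so end-to-end lambda recovery can be asserted to
#' numerical precision.
#'
#' @param lx Survivorship proportions at `c(0, schedule)`, starting at 1,
#'   non-increasing, ending at 0. `n0 * diff(lx)` must be whole numbers.
#' @param mx Per-female egg rates at `c(0, schedule)` (first entry is day 0,
#'   conventionally 0).
#' @param n0 Cohort size.
#' @param schedule Integer census days.
#' @param regime Label for the output tables.
#' @return List with `deaths`, `eggs` tibbles and `truth` (generating matrix
#'   and lambda).
#' @export
noiseless_study <- function(lx, mx, n0, schedule, regime = "SYN") {
  days <- c(0, schedule)
  stopifnot(length(lx) == length(days), length(mx) == length(days),
            lx[1] == 1, all(diff(lx) <= 0), lx[length(lx)] == 0)
  counts <- round(n0 * lx)
  if (max(abs(counts - n0 * lx)) > 1e-9) {
    abort("n0 * lx must be whole numbers for an exact discrete cohort")
  }
  d_counts <- -diff(counts) # deaths recorded at each census day
  death_day <- rep(schedule, d_counts)
  cohort <- tibble::tibble(
    id = sprintf("%s_c1_%04d", regime, seq_len(n0)),
    cage_id = paste0(regime, "_c1"),
    regime = regime,
    sex = "female",
    death_day = as.numeric(death_day),
    censor_day = NA_real_
  )
  deaths <- observe_deaths(cohort, schedule)
  kx <- counts # survivors after the census at each day (day 0 first)
  eggs <- tibble::tibble(
    cage_id = paste0(regime, "_c1"), regime = regime,
    day = as.integer(schedule),
    eggs = as.integer(round(mx[-1] * kx[-1]))
  )
  if (max(abs(mx[-1] * kx[-1] - eggs$eggs)) > 1e-9) {
    abort("mx * kx must be whole numbers for an exact egg census")
  }
  nLx <- (lx + c(lx[-1], 0)) / 2
  A <- leslie_from_vectors(mx[lx > 0], nLx[lx > 0])
  truth <- list(matrix = A, lambda = eigen_analysis(A)$lambda, lx = lx, mx = mx)
  list(deaths = deaths, eggs = eggs, truth = truth, schedule = schedule)
}

#' Write census tables and ground truth to disk
#'
#' Emits `deaths.csv`, `eggs.csv` and `truth.json` (config echo, individual
#' lifespans, planted segment boundaries, generating lambdas) in `dir`.
#'
#' @param study A `cage_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_census <- function(study, dir) {
  stopifnot(inherits(study, "cage_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$deaths, file.path(dir, "deaths.csv"))
  readr::write_csv(study$eggs, file.path(dir, "eggs.csv"))
  truth <- study$truth
  truth$configs <- lapply(truth$configs, function(cfg) {
    cfg$fecundity_segments <- as.data.frame(cfg$fecundity_segments)
    unclass(cfg)
  })
  truth$individuals <- as.data.frame(truth$individuals)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
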