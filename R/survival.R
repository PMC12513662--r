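#' Product-limit survival curves from death censuses
#'
#' Computes the Kaplan-Meier estimate per group from grouped census counts
#' (deaths and censorings tallied at integer census days). Cages within a
#' group are pooled. Greenwood variance and log(-log) confidence limits are
#' attached.
#'
#' Grouped deaths are treated as occurring at their census day (the
#' right-endpoint convention under which the cage was tallied); pass
#' `timing = "midpoint"` to place deaths at interval midpoints instead.
#' Censored individuals remain at risk through their census day.
#'
#' @param deaths Tibble with columns `day`, `n_dead`, `n_censored` plus any
#'   grouping columns (e.g. from [observe_deaths()] or `deaths.csv`).
#' @param by Character vector of grouping column names (default `"regime"`).
#' @param conf_level Confidence level for the Greenwood log(-log) interval.
#' @param timing `"census"` (default) or `"midpoint"` death-day convention.
#' @return A tibble of class `km_curve`: one row per group x event day with
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`, `greenwood_var`,
#'   `lower`, `upper`, and a dot-joined `group` label.
#' @examples
#' deaths <- tibble::tibble(regime = "HH", sex = "female",
#'   day = c(2, 4, 7), n_dead = c(1, 2, 1), n_censored = c(0, 0, 0))
#' km_estimate(deaths, by = "regime")
#' @export
km_estimate <- function(deaths, by = "regime", conf_level = 0.95,
                        timing = c("census", "midpoint")) {
  timing <- match.arg(timing)
  deaths <- tibble::as_tibble(deaths)
  check_count_columns(deaths, c("day", "n_dead", "n_censored"), "deaths")
  if (any(deaths$day < 0) || any(deaths$n_dead < 0) || any(deaths$n_censored < 0)) {
    abort("days and counts must be non-negative")
  }
  groups <- split_by(deaths, by)
  out <- purrr::imap(groups, function(g, label) {
    if (timing == "midpoint") {
      days <- sort(unique(g$day))
      prev <- c(0, days[-length(days)])
      mid <- (days + prev) / 2
      g$day <- mid[match(g$day, days)]
    }
    long <- dplyr::bind_rows(
      tibble::tibble(day = g$day, status = 1, w = g$n_dead),
      tibble::tibble(day = g$day, status = 0, w = g$n_censored)
    )
    long <- long[long$w > 0, , drop = FALSE]
    if (nrow(long) == 0) {
      abort(paste0("group '", label, "' has no events or censorings"))
    }
    if (sum(long$w[long$status == 1]) == 0) {
      warn(paste0("group '", label, "' is fully censored; S(t) is identically 1 ",
                  "and percentile lifespans are undefined"))
    }
    fit <- survival::survfit(survival::Surv(day, status) ~ 1, data = long,
                             weights = long$w, conf.type = "log-log",
                             conf.int = conf_level)
    key <- g[1, intersect(by, names(g)), drop = FALSE]
    dplyr::bind_cols(
      key[rep(1, length(fit$time)), , drop = FALSE],
      tibble::tibble(
        group = label,
        time = fit$time,
        n_risk = fit$n.risk,
        n_event = fit$n.event,
        n_censor = fit$n.censor,
        surv = fit$surv,
        greenwood_var = ifelse(fit$surv == 0, 0, (fit$surv * fit$std.err)^2),
        lower = ifelse(is.na(fit$lower), NA_real_, fit$lower),
        upper = ifelse(is.na(fit$upper), NA_real_, fit$upper)
      )
    )
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("km_curve", class(res))
  attr(res, "by") <- by
  attr(res, "conf_level") <- conf_level
  res
}

#' Percentile lifespans from a survival curve
#'
#' The day at which the survival curve first drops to or below each level
#' (0.9 captures early mortality, 0.5 the median, 0.1 maximal longevity).
#' Confidence limits invert the log(-log) Greenwood band
#' (Brookmeyer-Crowley): the interval is the set of days whose band contains
#' the level. When the curve never reaches a level the estimate is returned
#' as `NA` with `defined = FALSE` - never silently imputed.
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @param levels Survival fractions in (0, 1); default `c(0.9, 0.5, 0.1)`.
#' @return Tibble with group columns, `level`, `day`, `ci_low`, `ci_high`,
#'   `defined`.
#' @export
km_percentile <- function(curve, levels = c(0.9, 0.5, 0.1)) {
  stopifnot(inherits(curve, "km_curve"))
  if (any(levels <= 0 | levels >= 1)) abort("levels must lie in (0, 1)")
  by <- attr(curve, "by")
  eps <- 1e-9
  out <- purrr::map(split_by(tibble::as_tibble(curve), "group"), function(g) {
    g <- dplyr::arrange(g, .data$time)
    purrr::map(levels, function(lv) {
      first_at <- function(v) {
        i <- which(!is.na(v) & v <= lv + eps)
        if (length(i) == 0) NA_real_ else g$time[min(i)]
      }
      day <- first_at(g$surv)
      key <- g[1, intersect(c(by, "group"), names(g)), drop = FALSE]
      dplyr::bind_cols(key, tibble::tibble(
        level = lv,
        day = day,
        ci_low = first_at(g$lower),
        ci_high = first_at(g$upper),
        defined = !is.na(day)
      ))
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(out)
}

# Expand grouped census counts into one row per individual for survdiff.
expand_events <- function(deaths, by) {
  long <- dplyr::bind_rows(
    dplyr::mutate(deaths, status = 1, w = .data$n_dead),
    dplyr::mutate(deaths, status = 0, w = .data$n_censored)
  )
  long <- long[long$w > 0, , drop = FALSE]
  long <- tidyr::uncount(long, weights = .data$w)
  long$group <- group_label(long, by)
  long
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected log-rank statistic with hypergeometric
#' variance at each distinct event day, on `k - 1` degrees of freedom.
#' Backed by [survival::survdiff()] on the expanded event table.
#'
#' @inheritParams km_estimate
#' @return An object of class `logrank_test` with elements `chisq`, `df`,
#'   `p` (floored at 1e-16), `n`, `observed`, `expected`, `groups`.
#' @export
logrank <- function(deaths, by = "regime") {
  deaths <- tibble::as_tibble(deaths)
  check_count_columns(deaths, c("day", "n_dead", "n_censored"), "deaths")
  long <- expand_events(deaths, by)
  k <- dplyr::n_distinct(long$group)
  if (k < 2) abort("log-rank test needs at least two groups")
  if (sum(long$status) < 1) abort("log-rank test needs at least one event")
  fit <- survival::survdiff(survival::Surv(day, status) ~ group, data = long)
  df <- k - 1
  p <- max(stats::pchisq(fit$chisq, df, lower.tail = FALSE), 1e-16)
  structure(
    list(chisq = unname(fit$chisq), df = df, p = p,
         n = as.vector(fit$n), observed = as.vector(fit$obs),
         expected = as.vector(fit$exp), groups = sort(unique(long$group))),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Log-rank test: chisq = ", format(x$chisq, digits = 4),
      ", df = ", x$df, ", p = ", format.pval(x$p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Pairwise log-rank tests with multiplicity correction
#'
#' Runs the log-rank test for every pair of groups and adjusts the p-values,
#' by default with the Benjamini-Hochberg step-up procedure.
#'
#' @inheritParams km_estimate
#' @param adjust Method passed to [stats::p.adjust()] (default `"BH"`).
#' @return Tibble with `group1`, `group2`, `chisq`, `df`, `p`, `p_adj`.
#' @export
pairwise_logrank <- function(deaths, by = "regime", adjust = "BH") {
  deaths <- tibble::as_tibble(deaths)
  deaths$group <- group_label(deaths, by)
  groups <- sort(unique(deaths$group))
  if (length(groups) < 2) abort("need at least two groups for pairwise comparisons")
  pairs <- utils::combn(groups, 2)
  res <- purrr::map(seq_len(ncol(pairs)), function(j) {
    sub <- deaths[deaths$group %in% pairs[, j], , drop = FALSE]
    lr <- logrank(sub, by = "group")
    tibble::tibble(group1 = pairs[1, j], group2 = pairs[2, j],
                   chisq = lr$chisq, df = lr$df, p = lr$p)
  }) |> dplyr::bind_rows()
  res$p_adj <- stats::p.adjust(res$p, method = adjust)
  res
}
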