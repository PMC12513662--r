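#' Per-female fecundity series
#'
#' Joins the egg and death censuses on the day axis and computes, per group
#' and census day, the number of females alive at the laying window (`kx`),
#' the eggs laid in the 3-hour window (`bx`), and per-female fecundity
#' `mx = bx / kx`. Cages within a group are pooled.
#'
#' `kx` counts females alive at the start of the laying window: a female
#' whose terminal event was recorded at a census day `<= x` is excluded from
#' `kx` at `x` (the window follows the census). `convention = "midpoint"`
#' instead credits half of the events recorded at `x`.
#'
#' Rates are per 3-hour window throughout; nothing is rescaled to daily
#' totals.
#'
#' @param eggs Tibble with columns `day`, `eggs` plus grouping columns.
#' @param deaths Death census tibble (`day`, `n_dead`, `n_censored`, `sex`
#'   if present; only female rows are used).
#' @param by Character vector of grouping columns shared by both tables.
#' @param convention `"start"` (default) or `"midpoint"` for `kx`.
#' @return Tibble of class `fecundity_series` with group columns, `day`,
#'   `eggs`, `kx`, `per_female`, and `flagged` marking inconsistent records
#'   (eggs observed with no females alive).
#' @export
per_female_series <- function(eggs, deaths, by = "regime",
                              convention = c("start", "midpoint")) {
  convention <- match.arg(convention)
  eggs <- tibble::as_tibble(eggs)
  deaths <- tibble::as_tibble(deaths)
  check_count_columns(eggs, c("day", "eggs"), "eggs")
  check_count_columns(deaths, c("day", "n_dead", "n_censored"), "deaths")
  if ("sex" %in% names(deaths)) {
    deaths <- deaths[deaths$sex == "female", , drop = FALSE]
  }
  egg_groups <- split_by(eggs, by)
  death_groups <- split_by(deaths, by)
  out <- purrr::imap(egg_groups, function(ge, label) {
    gd <- death_groups[[label]]
    if (is.null(gd)) {
      abort(paste0("no female death census for group '", label, "'"))
    }
    ev <- gd |>
      dplyr::group_by(.data$day) |>
      dplyr::summarise(events = sum(.data$n_dead + .data$n_censored), .groups = "drop")
    n0 <- sum(ev$events)
    series <- ge |>
      dplyr::group_by(across(all_of(c(by, "day")))) |>
      dplyr::summarise(eggs = sum(.data$eggs), .groups = "drop") |>
      dplyr::arrange(.data$day)
    cum_at <- function(d) sum(ev$events[ev$day <= d])
    cum_before <- function(d) sum(ev$events[ev$day < d])
    series$kx <- vapply(series$day, function(d) {
      if (convention == "start") n0 - cum_at(d)
      else n0 - (cum_before(d) + cum_at(d)) / 2
    }, numeric(1))
    series$per_female <- ifelse(series$kx > 0, series$eggs / series$kx, NA_real_)
    series$flagged <- series$eggs > 0 & series$kx <= 0
    if (any(series$flagged)) {
      warn(paste0("group '", label, "': eggs recorded on ", sum(series$flagged),
                  " day(s) with no females alive; records flagged"))
    }
    series
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("fecundity_series", class(res))
  attr(res, "by") <- by
  res
}

#' Lifetime fecundity totals
#'
#' Total eggs laid over the whole series per group, and the per-cage mean
#' (the study's `ltf` summaries: group totals over two replicate cages and
#' their means).
#'
#' @param eggs Egg census tibble with columns `day`, `eggs`, and `cage_id`
#'   unless `n_cages` is supplied.
#' @param by Grouping columns (default `"regime"`).
#' @param n_cages Number of cages per group; defaults to the number of
#'   distinct `cage_id` values within each group.
#' @return Tibble with group columns, `total`, `n_cages`, `mean_per_cage`.
#' @export
lifetime_fecundity <- function(eggs, by = "regime", n_cages = NULL) {
  eggs <- tibble::as_tibble(eggs)
  check_count_columns(eggs, "eggs", "eggs")
  if (is.null(n_cages) && !"cage_id" %in% names(eggs)) {
    abort("supply n_cages or include a cage_id column")
  }
  out <- purrr::imap(split_by(eggs, by), function(g, label) {
    key <- g[1, intersect(by, names(g)), drop = FALSE]
    nc <- n_cages %||% dplyr::n_distinct(g$cage_id)
    dplyr::bind_cols(key, tibble::tibble(
      total = sum(g$eggs),
      n_cages = nc,
      mean_per_cage = sum(g$eggs) / nc
    ))
  })
  dplyr::bind_rows(out)
}

#' Effect-size band for a standardized mean difference
#'
#' Interprets `|d|` with the conventional thresholds: `< 0.2` small,
#' `[0.2, 0.5)` medium, `[0.5, 0.8)` large, `>= 0.8` very large. The sign
#' carries the direction and is reported separately.
#'
#' @param d Numeric vector of standardized mean differences.
#' @return Character vector of bands.
#' @export
effect_size_band <- function(d) {
  as.character(cut(abs(d), breaks = c(0, 0.2, 0.5, 0.8, Inf),
                   labels = c("small", "medium", "large", "very large"),
                   right = FALSE))
}

#' Hedges' d standardized mean difference
#'
#' `d = J * (mean(a) - mean(b)) / s_pooled` with the small-sample correction
#' `J = 1 - 3 / (4 (n_a + n_b) - 9)`. Positive values mean the first sample
#' has the larger mean. Zero pooled variance yields `NA` with a warning,
#' never a silent value.
#'
#' @param a,b Numeric samples, each of size >= 2.
#' @return One-row tibble with `d`, `band`, `n_a`, `n_b`, `j`.
#' @examples
#' hedges_d(c(10, 12, 14), c(4, 6, 8))
#' @export
hedges_d <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) abort("hedges_d needs at least 2 observations per sample")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  j <- 1 - 3 / (4 * (na + nb) - 9)
  if (sp2 <= 0) {
    warn("zero pooled variance; Hedges' d is undefined")
    return(tibble::tibble(d = NA_real_, band = NA_character_, n_a = na, n_b = nb, j = j))
  }
  d <- j * (mean(a) - mean(b)) / sqrt(sp2)
  tibble::tibble(d = d, band = effect_size_band(d), n_a = na, n_b = nb, j = j)
}

#' Pairwise Hedges' d between groups
#'
#' Computes [hedges_d()] for every pair of groups in a data frame of
#' replicate-level values (e.g. per-cage lifetime fecundity).
#'
#' @param data Data frame with a value column and grouping column(s).
#' @param value Name of the value column.
#' @param by Grouping column(s) (default `"regime"`).
#' @return Tibble with `group1`, `group2`, `d`, `band`, `n_a`, `n_b`.
#' @export
pairwise_hedges_d <- function(data, value, by = "regime") {
  data <- tibble::as_tibble(data)
  if (!value %in% names(data)) abort(paste0("no column '", value, "'"))
  data$group <- group_label(data, by)
  groups <- sort(unique(data$group))
  if (length(groups) < 2) abort("need at least two groups")
  pairs <- utils::combn(groups, 2)
  purrr::map(seq_len(ncol(pairs)), function(jj) {
    va <- data[[value]][data$group == pairs[1, jj]]
    vb <- data[[value]][data$group == pairs[2, jj]]
    hd <- hedges_d(va, vb)
    tibble::tibble(group1 = pairs[1, jj], group2 = pairs[2, jj],
                   d = hd$d, band = hd$band, n_a = hd$n_a, n_b = hd$n_b)
  }) |> dplyr::bind_rows()
}

#' Percent change between two values
#'
#' `100 * (comparison - reference) / reference`; e.g. a median lifespan
#' moving from 26 to 36 days is a 38.5% increase. Report-layer rounding to
#' one decimal is left to the caller.
#'
#' @param reference Baseline value(s), strictly positive.
#' @param comparison New value(s).
#' @return Numeric vector of percent changes.
#' @export
percent_change <- function(reference, comparison) {
  if (any(reference <= 0)) abort("reference must be > 0")
  100 * (comparison - reference) / reference
}
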