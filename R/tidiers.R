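#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Kaplan-Meier curve
#'
#' The `km_curve` object is already a tidy tibble; `tidy()` strips the class
#' and returns it as a plain tibble.
#'
#' @param x A `km_curve` from [km_estimate()].
#' @param ... Unused.
#' @export
tidy.km_curve <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' Glance at a Kaplan-Meier curve
#'
#' One row per group: size, events, censorings.
#'
#' @inheritParams tidy.km_curve
#' @export
glance.km_curve <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = max(.data$n_risk),
      events = sum(.data$n_event),
      censored = sum(.data$n_censor),
      final_surv = min(.data$surv),
      .groups = "drop"
    )
}

#' Tidy a log-rank test
#'
#' One row per group with observed and expected event counts.
#'
#' @param x A `logrank_test` from [logrank()].
#' @param ... Unused.
#' @export
tidy.logrank_test <- function(x, ...) {
  tibble::tibble(group = x$groups, n = x$n,
                 observed = x$observed, expected = x$expected)
}

#' Glance at a log-rank test
#'
#' @inheritParams tidy.logrank_test
#' @export
glance.logrank_test <- function(x, ...) {
  tibble::tibble(statistic = x$chisq, df = x$df, p.value = x$p)
}

#' Tidy a Leslie eigen analysis
#'
#' One row per age class: stable age proportion and reproductive value.
#'
#' @param x A `leslie_eigen` from [eigen_analysis()].
#' @param ... Unused.
#' @export
tidy.leslie_eigen <- function(x, ...) {
  k <- nrow(x$matrix)
  age <- rownames(x$matrix) %||% as.character(seq_len(k) - 1L)
  tibble::tibble(
    age_class = seq_len(k),
    age = suppressWarnings(as.numeric(age)),
    stable_age = as.numeric(x$stable_age),
    repro_value = as.numeric(x$repro_value)
  )
}

#' Glance at a Leslie eigen analysis
#'
#' @inheritParams tidy.leslie_eigen
#' @export
glance.leslie_eigen <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(lambda = x$lambda, rho = x$rho,
                   n_age_classes = nrow(x$matrix)),
    vx_summary(x)
  )
}

#' Tidy a changepoint segmentation
#'
#' One row per segment with index bounds and the segment mean.
#'
#' @param x A `mean_cpt` from [segment_mean()].
#' @param ... Unused.
#' @export
tidy.mean_cpt <- function(x, ...) {
  bps <- x$breakpoints
  starts <- c(1L, bps + 1L)
  ends <- c(bps, x$n)
  tibble::tibble(segment = seq_along(starts), start = starts, end = ends,
                 length = ends - starts + 1L, mean = x$segment_means)
}

#' Glance at a changepoint segmentation
#'
#' @inheritParams tidy.mean_cpt
#' @export
glance.mean_cpt <- function(x, ...) {
  tibble::tibble(n_changepoints = length(x$breakpoints), n = x$n,
                 penalty = x$penalty_value, method = x$method)
}

#' Plot survival curves
#'
#' Step plot of the product-limit estimate per group with the Greenwood
#' log(-log) confidence band.
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param conf_band Draw the confidence ribbon (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, conf_band = TRUE, ...) {
  df <- tidy.km_curve(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                        colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "day post-eclosion", y = "survival S(t)", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (conf_band) {
    p <- p + ggplot2::geom_step(ggplot2::aes(y = .data$lower),
                                linetype = "dotted", na.rm = TRUE) +
      ggplot2::geom_step(ggplot2::aes(y = .data$upper),
                         linetype = "dotted", na.rm = TRUE)
  }
  p
}

#' Plot a per-female fecundity series
#'
#' Per-female eggs per 3-hour window against census day, one line per group.
#'
#' @param object A `fecundity_series` from [per_female_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fecundity_series <- function(object, ...) {
  df <- tibble::as_tibble(object)
  by <- attr(object, "by") %||% "regime"
  df$group <- group_label(df, intersect(by, names(df)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$per_female,
                                   colour = .data$group)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::labs(x = "day post-eclosion",
                  y = "eggs per female per 3-h window", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a changepoint segmentation
#'
#' The series with fitted segment means overlaid.
#'
#' @param object A `mean_cpt` from [segment_mean()].
#' @param days Optional census-day axis (defaults to indices).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mean_cpt <- function(object, days = NULL, ...) {
  days <- days %||% seq_len(object$n)
  segs <- segment_durations(object, days)
  df <- tibble::tibble(day = days, value = object$x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$start_day, xend = .data$end_day,
                   y = .data$mean, yend = .data$mean),
      colour = "firebrick", linewidth = 1
    ) +
    ggplot2::labs(x = "day", y = "eggs per 3-h window") +
    ggplot2::theme_minimal()
}

#' Plot reproductive values by age
#'
#' Reproductive value `Vx` against age class from an eigen analysis.
#'
#' @param object A `leslie_eigen` from [eigen_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.leslie_eigen <- function(object, ...) {
  df <- tidy.leslie_eigen(object)
  xvar <- if (all(is.finite(df$age))) "age" else "age_class"
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data$repro_value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = if (xvar == "age") "day post-eclosion" else "age class",
                  y = "reproductive value Vx") +
    ggplot2::theme_minimal()
}
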