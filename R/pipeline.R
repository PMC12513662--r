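#' Run the full demographic pipeline
#'
#' Orchestrates simulate -> survival -> fecundity -> demography ->
#' changepoint for a configured study and returns a report bundle of tidy
#' tables shaped like the study's summary tables: percentile lifespans per
#' regime and sex, overall and pairwise log-rank tests, the per-female
#' fecundity series, pairwise Hedges' d on per-cage lifetime fecundity, the
#' lambda/rho/Vx fitness summary, and changepoint segments of each regime's
#' egg series.
#'
#' The run is deterministic for a fixed `(configs, n_cages, seed)`; the
#' manifest records enough to reproduce every table. If `out_dir` is given,
#' the tables are written as UTF-8 comma-separated files with header rows
#' (missing values as empty fields); on any stage failure partial outputs
#' are removed.
#'
#' @param configs Named list of [regime_config()]s (default
#'   [default_regime_configs()]).
#' @param n_cages Replicate cages per regime (default 2).
#' @param seed Master integer seed.
#' @param levels Survival fractions for percentile lifespans.
#' @param cp_method,cp_penalty,min_seg_len Changepoint settings passed to
#'   [segment_mean()].
#' @param out_dir Optional output directory for the report files.
#' @return Object of class `study_report`: list with `survival_summary`,
#'   `logrank`, `pairwise_logrank`, `fecundity_summary`, `effects`,
#'   `demography`, `changepoints`, `manifest`, and the underlying `study`.
#' @examples
#' \donttest{
#' rep <- run_study(seed = 42)
#' rep$demography
#' }
#' @export
run_study <- function(configs = default_regime_configs(), n_cages = 2, seed = 42,
                      levels = c(0.9, 0.5, 0.1), cp_method = "pelt",
                      cp_penalty = NULL, min_seg_len = 2, out_dir = NULL) {
  if (any(levels <= 0 | levels >= 1)) abort("levels must lie in (0, 1)")
  study <- simulate_study(configs, n_cages = n_cages, seed = seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  curves_sex <- stage("survival", km_estimate(study$deaths, by = c("regime", "sex")))
  curves_all <- stage("survival", km_estimate(study$deaths, by = "regime"))
  survival_summary <- dplyr::bind_rows(
    km_percentile(curves_all, levels) |> dplyr::mutate(sex = "all"),
    km_percentile(curves_sex, levels)
  ) |>
    dplyr::select(dplyr::any_of(c("regime", "sex", "group", "level", "day",
                                  "ci_low", "ci_high", "defined")))
  lr <- stage("survival", logrank(study$deaths, by = "regime"))
  lr8 <- stage("survival", logrank(study$deaths, by = c("regime", "sex")))
  logrank_tbl <- tibble::tibble(
    comparison = c("regime", "regime_sex"),
    chisq = c(lr$chisq, lr8$chisq),
    df = c(lr$df, lr8$df),
    p = c(lr$p, lr8$p)
  )
  pairwise <- stage("survival", pairwise_logrank(study$deaths, by = "regime"))
  fecundity_summary <- stage(
    "fecundity", per_female_series(study$eggs, study$deaths, by = "regime"))
  per_cage <- stage(
    "fecundity", lifetime_fecundity(study$eggs, by = c("regime", "cage_id")))
  effects <- stage("fecundity", pairwise_hedges_d(per_cage, "total", by = "regime"))
  demog <- stage("demography", demography_summary(study$deaths, study$eggs, by = "regime"))
  cpts <- stage("changepoint", {
    purrr::imap(split_by(study$eggs, "regime"), function(g, label) {
      series <- g |>
        dplyr::group_by(.data$day) |>
        dplyr::summarise(eggs = sum(.data$eggs), .groups = "drop") |>
        dplyr::arrange(.data$day)
      cp <- segment_mean(series$eggs, penalty = cp_penalty, method = cp_method,
                         min_seg_len = min_seg_len)
      dplyr::bind_cols(tibble::tibble(regime = label),
                       segment_durations(cp, series$day))
    }) |> dplyr::bind_rows()
  })
  manifest <- list(
    package = "cagedemog",
    version = as.character(utils::packageVersion("cagedemog")),
    seed = seed,
    n_cages = n_cages,
    regimes = names(configs),
    levels = levels,
    cp_method = cp_method,
    cp_penalty = cp_penalty %||% "sic",
    min_seg_len = min_seg_len,
    rows = list(deaths = nrow(study$deaths), eggs = nrow(study$eggs))
  )
  report <- structure(
    list(survival_summary = survival_summary, logrank = logrank_tbl,
         pairwise_logrank = pairwise, fecundity_summary = fecundity_summary,
         effects = effects, demography = demog, changepoints = cpts,
         manifest = manifest, study = study),
    class = "study_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> seed ", x$manifest$seed, ", regimes: ",
      paste(x$manifest$regimes, collapse = ", "), "\n", sep = "")
  cat("  lambda by regime:\n")
  print(as.data.frame(x$demography), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits `survival_summary.csv`, `logrank.csv`, `pairwise_logrank.csv`,
#' `fecundity_summary.csv`, `effects.csv`, `demography.csv`,
#' `changepoints.csv` and `manifest.json` plus the simulation inputs
#' (`deaths.csv`, `eggs.csv`). Rounding happens only here: days are already
#' integers, lambda/rho/Vx are written to 3 decimals. Partial outputs are
#' removed if any write fails.
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(dir, name)
    readr::write_csv(df, path, na = "")
    written <<- c(written, path)
  }
  tryCatch({
    emit(report$study$deaths, "deaths.csv")
    emit(report$study$eggs, "eggs.csv")
    emit(report$survival_summary, "survival_summary.csv")
    emit(report$logrank, "logrank.csv")
    emit(report$pairwise_logrank, "pairwise_logrank.csv")
    emit(report$fecundity_summary, "fecundity_summary.csv")
    emit(report$effects, "effects.csv")
    demog <- report$demography |>
      dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ round(.x, 3)))
    emit(demog, "demography.csv")
    emit(report$changepoints, "changepoints.csv")
    jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    written <- c(written, file.path(dir, "manifest.json"))
  }, error = function(e) {
    unlink(written)
    abort(paste0("report write failed (partial outputs removed): ",
                 conditionMessage(e)))
  })
  invisible(dir)
}

#' Derived lifespan contrasts from a percentile summary
#'
#' Computes day differences (and optionally percent changes) between
#' group/level pairs of a percentile-lifespan summary - e.g. the gap between
#' median and maximal male lifespan within a regime, or the same percentile
#' across regimes.
#'
#' @param survival_summary Tibble with columns `group`, `level`, `day` (as
#'   produced by [km_percentile()] / [run_study()]).
#' @param contrasts Tibble with columns `group_a`, `level_a`, `group_b`,
#'   `level_b`; one row per requested contrast.
#' @param percent If `TRUE`, adds `pct_change` = percent change from b to a.
#' @return `contrasts` with `day_a`, `day_b`, `diff_days` (a minus b) and
#'   optionally `pct_change`; missing group/level combinations give `NA`.
#' @export
summarize_gaps <- function(survival_summary, contrasts, percent = FALSE) {
  survival_summary <- tibble::as_tibble(survival_summary)
  check_count_columns(survival_summary, c("group", "level", "day"), "survival_summary")
  contrasts <- tibble::as_tibble(contrasts)
  check_count_columns(contrasts, c("group_a", "level_a", "group_b", "level_b"),
                      "contrasts")
  lookup <- function(group, level) {
    day <- purrr::map2_dbl(group, level, function(g, l) {
      hit <- survival_summary$group == g &
        abs(survival_summary$level - l) < 1e-9
      if (sum(hit) == 0) NA_real_ else survival_summary$day[which(hit)[1]]
    })
    day
  }
  out <- contrasts
  out$day_a <- lookup(contrasts$group_a, contrasts$level_a)
  out$day_b <- lookup(contrasts$group_b, contrasts$level_b)
  out$diff_days <- out$day_a - out$day_b
  if (any(is.na(out$diff_days))) {
    warn("some contrasts reference missing group/level combinations; returned NA")
  }
  if (percent) {
    out$pct_change <- ifelse(
      !is.na(out$day_b) & out$day_b > 0,
      percent_change(out$day_b, out$day_a), NA_real_)
  }
  out
}
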