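#' Build a life table from death and egg censuses
#'
#' Constructs an interval-indexed life table per group on the mixed 2/3-day
#' census axis: survivorship `lx` of the female cohort entering each
#' interval (`l0 = 1` at day 0), mid-interval survivorship
#' `nLx = (lx + lx_next) / 2` (trapezoid on the proportion scale), females
#' alive at the laying window `kx`, eggs in the interval `bx`, and
#' per-female fecundity `mx = bx / kx`.
#'
#' Both `lx` entering the interval starting at census day `x` and `kx` at
#' `x` count the post-census survivors: individuals whose terminal event was
#' recorded at a census day `<= x` are excluded. Trailing intervals in which
#' the cohort is extinct are trimmed.
#'
#' @param deaths Death census tibble (`day`, `n_dead`, `n_censored`, and
#'   `sex` if present - only female rows are used).
#' @param eggs Egg census tibble (`day`, `eggs`).
#' @param by Grouping columns shared by both tables (default `"regime"`).
#' @return Tibble of class `life_table` with group columns and `x` (interval
#'   start day), `width`, `lx`, `lx_next`, `nLx`, `kx`, `bx`, `mx`.
#' @export
build_life_table <- function(deaths, eggs, by = "regime") {
  deaths <- tibble::as_tibble(deaths)
  eggs <- tibble::as_tibble(eggs)
  check_count_columns(deaths, c("day", "n_dead", "n_censored"), "deaths")
  check_count_columns(eggs, c("day", "eggs"), "eggs")
  if ("sex" %in% names(deaths)) {
    deaths <- deaths[deaths$sex == "female", , drop = FALSE]
  }
  death_groups <- split_by(deaths, by)
  egg_groups <- split_by(eggs, by)
  out <- purrr::imap(death_groups, function(gd, label) {
    ge <- egg_groups[[label]]
    if (is.null(ge)) {
      abort(paste0("no egg census for group '", label, "'"))
    }
    ev <- gd |>
      dplyr::group_by(.data$day) |>
      dplyr::summarise(events = sum(.data$n_dead + .data$n_censored), .groups = "drop")
    eg <- ge |>
      dplyr::group_by(.data$day) |>
      dplyr::summarise(bx = sum(.data$eggs), .groups = "drop")
    n0 <- sum(ev$events)
    days <- sort(union(ev$day, eg$day))
    x <- c(0, days)
    surv_counts <- n0 - vapply(x, function(d) sum(ev$events[ev$day <= d]), numeric(1))
    if (n0 == 0) {
      # no terminal events recorded: cohort still fully alive (incomplete
      # follow-up); survivorship is identically 1 and mx cannot be scaled
      warn(paste0("group '", label, "': no deaths or censorings recorded; ",
                  "treating the cohort as fully alive (lx = 1)"))
      lx <- rep(1, length(x))
      surv_counts <- rep(NA_real_, length(x))
    } else {
      lx <- surv_counts / n0
    }
    lx_next <- if (n0 == 0) rep(1, length(x)) else c(lx[-1], (n0 - sum(ev$events)) / n0)
    bx <- eg$bx[match(x, eg$day)]
    bx[is.na(bx)] <- 0
    widths <- c(diff(x), utils::tail(diff(x), 1))
    key <- gd[1, intersect(by, names(gd)), drop = FALSE]
    lt <- dplyr::bind_cols(
      key[rep(1, length(x)), , drop = FALSE],
      tibble::tibble(
        x = x, width = widths, lx = lx, lx_next = lx_next,
        nLx = (lx + lx_next) / 2,
        kx = surv_counts, bx = bx,
        mx = ifelse(!is.na(surv_counts) & surv_counts > 0, bx / surv_counts,
                    ifelse(bx > 0, NA_real_, 0))
      )
    )
    if (isTRUE(any(lt$bx > 0 & lt$kx <= 0))) {
      warn(paste0("group '", label, "': eggs recorded after cohort extinction; ",
                  "mx flagged NA on those rows"))
    }
    # trim trailing intervals where no one is alive
    alive <- which(lt$lx > 0)
    lt[seq_len(max(alive)), , drop = FALSE]
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("life_table", class(res))
  attr(res, "by") <- by
  res
}

# Leslie matrix from fertility and mid-interval survivorship vectors.
# Top row = mx; subdiagonal P_i = nL_{i+1} / nL_i capped at 1.
leslie_from_vectors <- function(mx, nLx) {
  k <- length(mx)
  stopifnot(length(nLx) == k, k >= 1)
  A <- matrix(0, k, k)
  A[1, ] <- mx
  if (k >= 2) {
    P <- nLx[-1] / nLx[-k]
    bad <- !is.finite(P)
    if (any(bad)) {
      abort(paste0("non-finite survival ratio nL[i+1]/nL[i] at interval ",
                   paste(which(bad), collapse = ", ")))
    }
    A[cbind(2:k, 1:(k - 1))] <- pmin(P, 1)
  }
  A
}

#' Leslie projection matrix from a life table
#'
#' Fecundity values `mx` form the top row while survival values line the
#' subdiagonal: `P_i = nL_{i+1} / nL_i`, capped at 1. One projection step is
#' one census interval (2 or 3 real days), following the construction the
#' census cadence imposes; `lambda` is therefore growth per census step.
#'
#' @param life_table A single-group [build_life_table()] result.
#' @return A square non-negative matrix with interval start days as
#'   dimnames.
#' @export
build_leslie <- function(life_table) {
  lt <- tibble::as_tibble(life_table)
  check_count_columns(lt, c("x", "nLx", "mx"), "life_table")
  if ("group" %in% names(lt) && dplyr::n_distinct(lt$group) > 1) {
    abort("build_leslie expects a single group; filter the life table first")
  }
  by <- attr(life_table, "by")
  if (!is.null(by) && length(intersect(by, names(lt))) > 0) {
    ng <- dplyr::n_distinct(group_label(lt, intersect(by, names(lt))))
    if (ng > 1) abort("build_leslie expects a single group; filter the life table first")
  }
  if (nrow(lt) < 2) abort("life table needs at least two intervals")
  if (any(is.na(lt$mx))) abort("life table has undefined mx rows (eggs with kx = 0)")
  A <- leslie_from_vectors(lt$mx, lt$nLx)
  dimnames(A) <- list(lt$x, lt$x)
  A
}

#' Eigen analysis of a projection matrix
#'
#' Full eigendecomposition of a non-negative projection matrix, returning
#' the asymptotic growth rate `lambda` (the dominant eigenvalue, asserted
#' real), the stable age distribution (right eigenvector `w`, normalized to
#' sum 1), reproductive values `Vx` (left eigenvector `v`, normalized so the
#' first age class has value 1), and the damping ratio
#' `rho = lambda / |lambda_2|` that bounds the rate of convergence to the
#' stable distribution (at least as fast as `log(rho)` per step).
#'
#' The dominant eigenvalue is chosen by modulus with a real-part tie-break
#' (so a periodic matrix with eigenvalues +/- lambda yields the positive
#' root and `rho = 1`). A complex dominant pair (non-primitive matrix) is an
#' error. A nilpotent matrix (all fertilities zero) returns `lambda = 0`
#' with a warning: population extinction, no stable structure.
#'
#' @param A Square, non-negative, finite numeric matrix.
#' @param tol Relative tolerance for realness/tie checks (default 1e-8).
#' @return Object of class `leslie_eigen`: list with `matrix`, `lambda`,
#'   `stable_age`, `repro_value`, `rho`, `lambda2_mod`.
#' @examples
#' A <- matrix(c(1, 0.5, 1, 0), 2, 2)
#' eigen_analysis(A)$lambda # (1 + sqrt(3)) / 2
#' @export
eigen_analysis <- function(A, tol = 1e-8) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) abort("A must be a square matrix")
  if (any(!is.finite(A))) abort("A must be finite")
  if (any(A < 0)) abort("A must be non-negative")
  k <- nrow(A)
  if (k == 1) {
    warn("1x1 matrix: damping ratio is undefined")
    return(structure(list(matrix = A, lambda = A[1, 1],
                          stable_age = 1, repro_value = 1,
                          rho = NA_real_, lambda2_mod = NA_real_),
                     class = "leslie_eigen"))
  }
  ev <- eigen(A)
  mods <- Mod(ev$values)
  mmax <- max(mods)
  if (mmax < tol) {
    warn("projection matrix is nilpotent (all eigenvalues 0): lambda = 0, extinction")
    return(structure(list(matrix = A, lambda = 0,
                          stable_age = rep(NA_real_, k),
                          repro_value = rep(NA_real_, k),
                          rho = NA_real_, lambda2_mod = NA_real_),
                     class = "leslie_eigen"))
  }
  cand <- which(mods >= mmax * (1 - tol))
  idx <- cand[which.max(Re(ev$values[cand]))]
  lam <- ev$values[idx]
  if (abs(Im(lam)) > tol * max(1, mmax)) {
    abort("dominant eigenvalue pair is complex: matrix is not primitive")
  }
  lambda <- Re(lam)
  w <- ev$vectors[, idx]
  if (max(abs(Im(w))) > 1e-6 * max(abs(w))) {
    abort("dominant right eigenvector is complex: matrix is not primitive")
  }
  w <- Re(w)
  w <- w / sum(w)
  lev <- eigen(t(A))
  lidx <- which.min(abs(lev$values - lambda))
  v <- Re(lev$vectors[, lidx])
  if (abs(v[1]) < 1e-12) {
    warn("first age class has zero reproductive value; Vx normalized by max instead")
    v <- v / max(abs(v)) * sign(sum(v))
  } else {
    v <- v / v[1]
  }
  others <- mods[-idx]
  lambda2_mod <- if (length(others)) max(others) else NA_real_
  rho <- if (!is.na(lambda2_mod) && lambda2_mod > 0) abs(lambda) / lambda2_mod else Inf
  structure(
    list(matrix = A, lambda = lambda, stable_age = w, repro_value = v,
         rho = rho, lambda2_mod = lambda2_mod),
    class = "leslie_eigen"
  )
}

#' @export
print.leslie_eigen <- function(x, ...) {
  cat("<leslie_eigen> ", nrow(x$matrix), " age classes\n", sep = "")
  cat("  lambda = ", format(x$lambda, digits = 6),
      ", rho = ", format(x$rho, digits = 4), "\n", sep = "")
  if (!anyNA(x$repro_value)) {
    cat("  Vx: max ", format(max(x$repro_value), digits = 4),
        ", min ", format(min(x$repro_value), digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Summary of reproductive values
#'
#' Maximum, minimum and range of the reproductive values `Vx` - the spread
#' of expected future contributions across age classes.
#'
#' @param x A `leslie_eigen` object or a numeric vector of `Vx` values.
#' @return One-row tibble with `max_vx`, `min_vx`, `range_vx`.
#' @examples
#' vx_summary(c(6.384, 1.2, 0.200)) # range 6.184
#' @export
vx_summary <- function(x) {
  vx <- if (inherits(x, "leslie_eigen")) x$repro_value else as.numeric(x)
  if (anyNA(vx)) {
    return(tibble::tibble(max_vx = NA_real_, min_vx = NA_real_, range_vx = NA_real_))
  }
  tibble::tibble(max_vx = max(vx), min_vx = min(vx), range_vx = max(vx) - min(vx))
}

#' Per-group demographic fitness summary
#'
#' Runs the full life-table -> Leslie -> eigen pipeline per group and
#' returns the fitness summary table: `lambda`, damping ratio `rho`, and the
#' reproductive-value spread (`max_vx`, `min_vx`, `range_vx`).
#'
#' @inheritParams build_life_table
#' @return Tibble with one row per group.
#' @export
demography_summary <- function(deaths, eggs, by = "regime") {
  lt <- build_life_table(deaths, eggs, by = by)
  lt$group <- group_label(lt, by)
  out <- purrr::imap(split(tibble::as_tibble(lt), lt$group), function(g, label) {
    A <- leslie_from_vectors(g$mx, g$nLx)
    ea <- eigen_analysis(A)
    key <- g[1, intersect(by, names(g)), drop = FALSE]
    dplyr::bind_cols(key, tibble::tibble(lambda = ea$lambda, rho = ea$rho),
                     vx_summary(ea))
  })
  dplyr::bind_rows(out)
}
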