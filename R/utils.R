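#' @importFrom rlang .data abort warn `%||%`
#' @importFrom dplyr across all_of
NULL

# Split a data frame into named groups by a character vector of column names.
# Returns list of tibbles; names are the dot-joined key values.
split_by <- function(data, by) {
  if (length(by) == 0) {
    return(list(all = tibble::as_tibble(data)))
  }
  missing <- setdiff(by, names(data))
  if (length(missing) > 0) {
    abort(paste0("grouping column(s) not found: ", paste(missing, collapse = ", ")))
  }
  keys <- interaction(data[by], drop = TRUE, sep = ".", lex.order = TRUE)
  lapply(split(tibble::as_tibble(data), keys), tibble::as_tibble)
}

# Single label per group, used for `group` columns in report tables.
group_label <- function(data, by) {
  if (length(by) == 0) return(rep("all", nrow(data)))
  do.call(paste, c(unname(as.list(data[by])), sep = "."))
}

check_count_columns <- function(data, cols, what) {
  for (cl in cols) {
    if (!cl %in% names(data)) {
      abort(paste0(what, " table is missing column '", cl, "'"))
    }
  }
  invisible(data)
}

# Derive independent integer substream seeds from one master seed, keeping
# every derived seed strictly below 2^31 (R integers are 32-bit).
spawn_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1, is.finite(seed))
  old <- withr_seed(as.integer(seed))
  on.exit(restore_seed(old))
  sample.int(.Machine$integer.max - 1L, n)
}

withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
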