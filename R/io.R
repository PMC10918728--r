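# Occurrence-record I/O. One row per observed individual:
#   id, site_id, y, v (empty = unverified), x_1..x_{n_e}, z_1..z_n,
#   score_1..score_J (optional ML prediction scores for the record's
#   reported state).

#' Read an occurrence CSV
#'
#' Reads individual-level occurrence records. Required columns: `id`,
#' `site_id`, `y` (reported state, `1..K`) plus any ecological covariates
#' `x_1..x_{n_e}` and classification covariates `z_1..z_n`. Optional: `v`
#' (verified true state; empty field = unverified) and per-true-state ML
#' prediction scores `score_1..score_J`.
#'
#' @param path Path to a CSV file with a header row.
#' @return A data frame of occurrence records.
#' @export
read_occurrence_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "site_id", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("malformed occurrence CSV: missing required column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"v" %in% names(df)) df$v <- NA_integer_
  df$y <- as.integer(df$y)
  df$v <- suppressWarnings(as.integer(df$v))
  df$id <- as.character(df$id)
  df$site_id <- as.character(df$site_id)
  df
}

#' Write an occurrence CSV
#'
#' @param records An occurrence data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrence_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Extract covariate matrices from occurrence records
#'
#' Collects the `x_*` (ecological) and `z_*` (classification) columns into
#' numeric matrices, ordered by their numeric suffix, and validates the
#' state columns against a state space.
#'
#' @param records An occurrence data frame.
#' @param space Optional [state_space] used to range-check `y` and `v`.
#' @return A list with matrices `X` (`S x n_e`), `Z` (`S x n`) and, when
#'   present, `scores` (`S x J`).
#' @export
occ_covariates <- function(records, space = NULL) {
  grab <- function(prefix) {
    cols <- grep(paste0("^", prefix, "_[0-9]+$"), names(records), value = TRUE)
    cols <- cols[order(as.integer(sub(paste0("^", prefix, "_"), "", cols)))]
    m <- as.matrix(as.data.frame(lapply(records[cols], as.numeric)))
    if (length(cols) == 0) m <- matrix(0, nrow(records), 0)
    colnames(m) <- cols
    m
  }
  X <- grab("x"); Z <- grab("z"); W <- grab("score")
  if (!is.null(space)) {
    if (any(records$y < 1L | records$y > space$K, na.rm = TRUE)) {
      stop("reported states y outside 1..K")
    }
    vv <- records$v[!is.na(records$v)]
    if (any(vv < 1L | vv > space$J)) stop("verified states v outside 1..J")
    if (ncol(W) > 0 && ncol(W) != space$J) {
      stop("score_* columns must number J (one per true state)")
    }
  }
  out <- list(X = X, Z = Z)
  if (ncol(W) > 0) out$scores <- W
  out
}

#' Cap an observer-experience covariate
#'
#' Observer experience measured as a report count is truncated: once an
#' observer has more than `cap` reports the extra reports are assumed not
#' to add further skill.
#'
#' @param n_reports Integer vector of per-observer report counts.
#' @param cap Truncation point (default 10).
#' @return `pmin(n_reports, cap)`.
#' @examples
#' cap_experience(c(1, 5, 25))
#' @export
cap_experience <- function(n_reports, cap = 10) {
  if (cap <= 0) stop("cap must be positive")
  pmin(as.numeric(n_reports), cap)
}
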