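## Longitudinal panel container and plain-text I/O.
##
## A gbtm_panel is an N x T outcome matrix on a common time grid, with NA for
## unobserved cells, plus per-subject dropout bookkeeping: dropout_occasion[i]
## is the first occasion after subject i's last observation (T + 1 when the
## subject is observed through the end of the grid).  Missing cells before the
## last observation are intermittent missingness, allowed and flagged.

#' Boundary-value adjustment for exact 0/1 observations
#'
#' The beta density is undefined at 0 and 1. Exact boundary observations are
#' moved inward by half a reciprocal sample size: 0 becomes `0.5/n` and 1
#' becomes `1 - 0.5/n`; interior values are untouched, so the map is
#' idempotent.
#'
#' @param values Numeric vector/matrix with entries in the closed interval
#'   [0, 1] (NAs pass through).
#' @param n_subjects The `n` in the adjustment, conventionally the number of
#'   subjects rather than the number of observations.
#' @return `values` with boundary entries mapped strictly inside (0, 1).
#' @examples
#' boundary_adjust(c(0, 0.5, 1), n_subjects = 396)
#' @export
boundary_adjust <- function(values, n_subjects) {
  if (length(n_subjects) != 1L || !is.finite(n_subjects) || n_subjects < 1)
    stopf("'n_subjects' must be a single count >= 1")
  v <- values
  obs <- !is.na(v)
  if (any(obs & (v < 0 | v > 1)))
    stopf("values outside [0, 1] cannot be boundary-adjusted")
  eps <- 0.5 / n_subjects
  v[obs & v == 0] <- eps
  v[obs & v == 1] <- 1 - eps
  v
}

#' Construct a longitudinal panel
#'
#' @param y Numeric `N x T` matrix of outcomes in (0, 1) (or [0, 1] when
#'   `adjust = TRUE`); `NA` marks unobserved cells.
#' @param times Strictly increasing numeric vector of length `T`.
#' @param id Optional subject identifiers (length `N`).
#' @param adjust Apply [boundary_adjust()] to exact 0/1 entries (default).
#' @param n_adjust Sample size used in the boundary adjustment; defaults to
#'   the number of subjects.
#' @return An object of class `"gbtm_panel"`: list with `y`, `times`, `id`,
#'   `N`, `T`, `dropout_occasion` (integer in `1..T+1`; `T+1` = followed to the
#'   end), `n_obs` per subject, and `intermittent` (any gap before the last
#'   observation).
#' @examples
#' y <- rbind(c(0.2, 0.3, NA), c(0.8, NA, 0.7))
#' p <- panel_data(y, times = c(0, 4, 8))
#' p$dropout_occasion   # subject 1 drops at occasion 3; subject 2 completes
#' @export
panel_data <- function(y, times, id = NULL, adjust = TRUE, n_adjust = NULL) {
  y <- as.matrix(y)
  if (!is.numeric(y)) stopf("'y' must be numeric")
  times <- as.numeric(times)
  if (length(times) != ncol(y))
    stopf("'times' must have one entry per column of 'y'")
  if (any(!is.finite(times)) || is.unsorted(times, strictly = TRUE))
    stopf("'times' must be finite and strictly increasing")
  N <- nrow(y)
  if (N < 1L) stopf("panel must contain at least one subject")
  if (is.null(id)) id <- seq_len(N)
  if (length(id) != N) stopf("'id' must have one entry per subject")
  if (adjust) y <- boundary_adjust(y, n_adjust %||% N)
  obs <- is.finite(y)
  if (any(!is.na(y) & !obs)) stopf("'y' contains non-finite observed values")
  if (any(obs & (y <= 0 | y >= 1)))
    stopf(paste("observed outcomes must lie strictly inside (0, 1);",
                "apply boundary_adjust() to exact 0/1 data"))
  n_obs <- rowSums(obs)
  if (any(n_obs == 0)) {
    drop_idx <- which(n_obs == 0)
    warnf("dropping %d subject(s) with no observed occasions (ids: %s)",
          length(drop_idx), paste(utils::head(id[drop_idx], 5), collapse = ", "))
    keep <- n_obs > 0
    y <- y[keep, , drop = FALSE]
    id <- id[keep]
    obs <- obs[keep, , drop = FALSE]
    n_obs <- n_obs[keep]
    N <- nrow(y)
    if (N == 0L) stopf("no subjects with observed data remain")
  }
  last_obs <- apply(obs, 1L, function(r) max(which(r)))
  dropout_occasion <- as.integer(ifelse(last_obs < ncol(y), last_obs + 1L,
                                        ncol(y) + 1L))
  intermittent <- vapply(seq_len(N), function(i)
    any(!obs[i, seq_len(last_obs[i])]), logical(1))
  structure(list(y = unname(y), times = times, id = id, N = N, T = ncol(y),
                 dropout_occasion = dropout_occasion, n_obs = n_obs,
                 intermittent = intermittent),
            class = "gbtm_panel")
}

#' @export
print.gbtm_panel <- function(x, ...) {
  cat(sprintf("Longitudinal panel: %d subjects x %d occasions (t = %s..%s)\n",
              x$N, x$T, format(min(x$times)), format(max(x$times))))
  cat(sprintf("  observed cells: %d of %d (%.1f%%); %d subject(s) drop out before the last occasion\n",
              sum(x$n_obs), x$N * x$T, 100 * sum(x$n_obs) / (x$N * x$T),
              sum(x$dropout_occasion <= x$T)))
  invisible(x)
}

#' Read a long-format longitudinal table into a panel
#'
#' Expects a delimited text file with a header and one row per subject x
#' occasion. The delimiter is inferred from the extension (`.tsv`/`.txt` =
#' tab, otherwise comma) unless given. Occasions are the sorted unique time
#' values; a subject's missing occasions are unobserved cells. Empty fields or
#' `NA` encode missing outcomes; no sentinel numerics.
#'
#' @param path File path.
#' @param id,time,value Column names holding subject id, measurement time and
#'   the outcome in [0, 1].
#' @param sep Field delimiter; `NULL` to infer from the extension.
#' @param adjust Apply [boundary_adjust()] to exact 0/1 values.
#' @param n_adjust Sample size for the adjustment (default: subjects).
#' @return A [panel_data()] object.
#' @export
read_long <- function(path, id = "id", time = "time", value = "value",
                      sep = NULL, adjust = TRUE, n_adjust = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  long_to_panel(df, id = id, time = time, value = value,
                adjust = adjust, n_adjust = n_adjust)
}

## shared pivot used by read_long() and the data-frame front end
long_to_panel <- function(df, id = "id", time = "time", value = "value",
                          adjust = TRUE, n_adjust = NULL) {
  for (col in c(id, time, value))
    if (!col %in% names(df)) stopf("column '%s' not found in the input", col)
  tv <- df[[time]]
  if (!is.numeric(tv)) stopf("time column '%s' must be numeric", time)
  yv <- df[[value]]
  if (!is.numeric(yv)) stopf("value column '%s' must be numeric", value)
  bad <- which(!is.na(yv) & (yv < 0 | yv > 1))
  if (length(bad))
    stopf("outcome values outside [0, 1] at row(s): %s",
          paste(utils::head(bad, 10), collapse = ", "))
  if (anyDuplicated(df[c(id, time)]))
    stopf("duplicate (id, time) rows in the input")
  ids <- unique(df[[id]])
  times <- sort(unique(tv))
  y <- matrix(NA_real_, length(ids), length(times))
  ri <- match(df[[id]], ids)
  ci <- match(tv, times)
  y[cbind(ri, ci)] <- yv
  panel_data(y, times, id = ids, adjust = adjust, n_adjust = n_adjust)
}

#' Write a panel as a long-format delimited file
#'
#' Inverse of [read_long()] (up to the boundary adjustment already applied to
#' the panel). Unobserved cells are omitted.
#'
#' @param panel A [panel_data()] object.
#' @param path Output path; extension picks the delimiter as in [read_long()].
#' @return `path`, invisibly.
#' @export
write_long <- function(panel, path) {
  stopifnot(inherits(panel, "gbtm_panel"))
  obs <- is.finite(panel$y)
  idx <- which(obs, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(id = panel$id[idx[, 1]],
                   time = panel$times[idx[, 2]],
                   value = panel$y[idx])
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
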