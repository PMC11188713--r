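# Calcium-like binary rasters and the three summary features used for
# network-parameter inference, plus the winners-take-all quality filter.

#' Binarize a spike raster into a calcium-like activity raster
#'
#' Bins spikes into non-overlapping 250 ms windows tiling `[0, duration)`
#' (half-open: a spike at exactly 250 ms falls in bin 2) and marks a bin
#' active when it contains at least one spike, emulating the temporal
#' resolution of slice calcium imaging.  Cells that never spike are dropped
#' from the matrix; their original indices are recorded.
#'
#' @param spikes a [spike_raster()] (or data.frame with `cell`, `time` and
#'   attributes `n_cells`, `duration_ms`).
#' @param bin_ms bin width in ms.
#' @return A list of class `ca_raster`: binary matrix `mat` (active cells x
#'   bins), `bin_ms`, `cells` (original indices of retained cells),
#'   `n_cells_total`, `duration_ms`.
#' @export
binarize <- function(spikes, bin_ms = 250) {
  dur <- attr(spikes, "duration_ms")
  n_cells <- attr(spikes, "n_cells")
  if (is.null(dur) || is.null(n_cells))
    stop("`spikes` must carry n_cells and duration_ms attributes")
  if (dur < bin_ms) stop("duration must cover at least one bin")
  if (nrow(spikes) && (min(spikes$time) < 0 || max(spikes$time) > dur))
    stop("spike times outside [0, duration)")
  n_bins <- floor(dur / bin_ms)
  active <- sort(unique(spikes$cell))
  mat <- matrix(0L, length(active), n_bins)
  if (length(active)) {
    b <- floor(spikes$time / bin_ms) + 1L
    keep <- b <= n_bins
    ci <- match(spikes$cell[keep], active)
    mat[cbind(ci, b[keep])] <- 1L
  }
  structure(list(mat = mat, bin_ms = bin_ms, cells = active,
                 n_cells_total = n_cells, duration_ms = dur),
            class = "ca_raster")
}

#' Construct a calcium raster from a binary matrix
#'
#' @param mat binary matrix, rows = cells, columns = 250 ms bins.
#' @param bin_ms bin width in ms.
#' @param cells original cell indices (defaults to row numbers).
#' @param drop_silent drop all-zero rows (the active-cell convention).
#' @return A `ca_raster`.
#' @export
ca_raster <- function(mat, bin_ms = 250, cells = seq_len(nrow(mat)),
                      drop_silent = TRUE) {
  mat <- as.matrix(mat)
  if (!all(mat %in% c(0, 1))) stop("raster entries must be 0/1")
  storage.mode(mat) <- "integer"
  n_total <- nrow(mat)
  if (drop_silent) {
    keep <- rowSums(mat) > 0
    cells <- cells[keep]
    mat <- mat[keep, , drop = FALSE]
  }
  structure(list(mat = mat, bin_ms = bin_ms, cells = cells,
                 n_cells_total = n_total,
                 duration_ms = ncol(mat) * bin_ms), class = "ca_raster")
}

#' @export
print.ca_raster <- function(x, ...) {
  cat(sprintf("<ca_raster> %d active cells x %d bins of %g ms (%.1f s)\n",
              nrow(x$mat), ncol(x$mat), x$bin_ms, x$duration_ms / 1000))
  invisible(x)
}

#' Activation intervals of one binary row
#'
#' Gaps between consecutive active bins, in bins: for active bins at
#' indices `i < j` with none active between them the interval is
#' `j - i - 1`, so temporally adjacent active bins count as a zero
#' interval.  A row with fewer than two active bins has no intervals.
#'
#' @param row binary vector (one cell's activity).
#' @return Integer vector of intervals (possibly empty).
#' @export
#' @examples
#' activation_intervals(c(1, 1, 0, 1))  # 0, 1
activation_intervals <- function(row) {
  if (length(row) == 0) stop("row must be non-empty")
  if (!all(row %in% c(0, 1))) stop("row entries must be 0/1")
  on <- which(row == 1)
  if (length(on) < 2) return(integer(0))
  as.integer(diff(on) - 1L)
}

# per-cell statistics behind the three features
.cell_stats <- function(row) {
  iv <- activation_intervals(row)
  activity <- mean(row)
  if (length(iv) == 0) return(c(activity = activity, interval = 0, cv = 0))
  m <- mean(iv)
  cv <- if (length(iv) < 2 || m == 0) 0 else sd(iv) / m
  c(activity = activity, interval = m, cv = cv)
}

#' The three summary features of a calcium raster
#'
#' Per active cell: the mean activity (fraction of active bins), the mean
#' interval between consecutive activations (in bins; multiply by the bin
#' width for ms), and the coefficient of variation of those intervals
#' (SD/mean).  Each quantity is then averaged across active cells.  Cells
#' with fewer than two intervals contribute an interval CV of 0; cells with
#' no intervals also contribute a mean interval of 0.  All three features
#' are invariant under temporal shifts of individual cells' time series.
#'
#' @param raster a `ca_raster`.
#' @return Named numeric vector `activity`, `interval`, `cv`.
#' @export
feature_vector <- function(raster) {
  m <- raster$mat
  if (nrow(m) == 0) stop("empty raster: no active cells")
  st <- t(apply(m, 1, .cell_stats))
  c(activity = mean(st[, "activity"]), interval = mean(st[, "interval"]),
    cv = mean(st[, "cv"]))
}

#' Total fluctuation of the network activity
#'
#' Coefficient of variation of the population-mean activity time series
#' after discarding an initial transient.  Near zero for networks that have
#' fallen into a fixed-point winners-take-all state; unlike the three
#' summary features its value depends strongly on the number of active
#' cells, which is why it serves only as a quality filter.
#'
#' @param raster a `ca_raster`.
#' @param transient_bins bins discarded from the start (default 120, i.e.
#'   30 s at 250 ms resolution).
#' @return A list of class `qc_metrics`: `value` (the CV), `dead` (`TRUE`
#'   when the post-transient mean is zero), `n_active`, `transient_bins`.
#' @export
total_fluctuation <- function(raster, transient_bins = 120) {
  m <- raster$mat
  if (ncol(m) - transient_bins < 10)
    stop("need at least 10 bins after the transient")
  pop <- colMeans(m)[(transient_bins + 1):ncol(m)]
  if (mean(pop) == 0) {
    warning("dead network: zero mean activity after transient")
    val <- 0; dead <- TRUE
  } else {
    val <- sd(pop) / mean(pop); dead <- FALSE
  }
  structure(list(value = val, dead = dead, n_active = nrow(m),
                 transient_bins = transient_bins), class = "qc_metrics")
}

#' Winners-take-all rejection filter
#'
#' Removes simulation records whose total network fluctuation falls below
#' the rejection threshold (strictly below 0.09; a record exactly at the
#' boundary is kept), flagging fixed-point winners-take-all runs that are
#' excluded from estimator training.
#'
#' @param records data.frame with a `fluct` column (plus any parameter and
#'   feature columns).
#' @param threshold rejection threshold.
#' @return A list with `kept` and `removed` data.frames.
#' @export
wta_filter <- function(records, threshold = 0.09) {
  stopifnot(is.data.frame(records), "fluct" %in% names(records))
  keep <- records$fluct >= threshold
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

#' Features and QC for a batch of simulated rasters
#'
#' Convenience wrapper: binarize a spike raster, compute the three summary
#' features and the total fluctuation.
#'
#' @param spikes a [spike_raster()].
#' @param bin_ms bin width, ms.
#' @param transient_bins transient dropped by [total_fluctuation()].
#' @return One-row data.frame `activity`, `interval`, `cv`, `fluct`,
#'   `n_active`.
#' @export
summarize_raster <- function(spikes, bin_ms = 250, transient_bins = 120) {
  ca <- binarize(spikes, bin_ms)
  fv <- feature_vector(ca)
  qc <- total_fluctuation(ca, transient_bins)
  data.frame(activity = fv[["activity"]], interval = fv[["interval"]],
             cv = fv[["cv"]], fluct = qc$value, n_active = qc$n_active)
}
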