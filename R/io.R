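# Plain-text readers/writers for the package's artifact formats: spike
# rasters and calcium rasters as delimited text with small headers,
# feature tables as CSV, transition graphs as edge lists, configs as YAML.

#' Write / read a spike raster
#'
#' Two-column tab-delimited text (`cell`, `time_ms`) with `#`-prefixed
#' header lines carrying the cell count and duration.
#'
#' @param x a [spike_raster()].
#' @param path file path.
#' @return `write_spike_raster` returns `path` invisibly;
#'   `read_spike_raster` returns a `spike_raster`.
#' @export
write_spike_raster <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_cells: %d", attr(x, "n_cells")),
               sprintf("# duration_ms: %.10g", attr(x, "duration_ms")),
               "cell\ttime_ms"), con)
  if (nrow(x))
    write.table(data.frame(x$cell, sprintf("%.10g", x$time)), con,
                sep = "\t", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_raster
#' @export
read_spike_raster <- function(path) {
  hdr <- readLines(path, n = 2)
  n_cells <- as.integer(sub("# n_cells: ", "", hdr[1]))
  dur <- as.numeric(sub("# duration_ms: ", "", hdr[2]))
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  spike_raster(d$cell, d$time_ms, n_cells, dur)
}

#' Write / read a calcium raster
#'
#' The binary matrix as tab-delimited 0/1 text (rows = active cells), with
#' a JSON sidecar (`<path>.json`) holding the bin width, duration and the
#' original indices of the retained cells.
#'
#' @param x a `ca_raster`.
#' @param path file path for the matrix; the sidecar is `<path>.json`.
#' @return `write_ca_raster` returns `path` invisibly; `read_ca_raster`
#'   returns a `ca_raster`.
#' @export
write_ca_raster <- function(x, path) {
  write.table(x$mat, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(bin_ms = x$bin_ms, duration_ms = x$duration_ms,
         n_cells_total = x$n_cells_total, cells = x$cells),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ca_raster
#' @export
read_ca_raster <- function(path) {
  mat <- as.matrix(read.table(path, sep = "\t"))
  dimnames(mat) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- ca_raster(mat, bin_ms = meta$bin_ms, cells = meta$cells,
                   drop_silent = FALSE)
  out$n_cells_total <- meta$n_cells_total
  out
}

#' Write / read a feature table
#'
#' @param x data.frame of per-simulation features/parameters.
#' @param path CSV path.
#' @return The path (write) or the data.frame (read).
#' @export
write_features <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) read.csv(path)

#' Write a voltage trace as two-column delimited text
#'
#' @param x a `voltage_trace` recorded with `simulate_cell(record = TRUE)`.
#' @param path output path (tab-delimited `time_ms`, `v_mv`; spike times as
#'   `#`-prefixed header metadata).
#' @return The path, invisibly.
#' @export
write_voltage_trace <- function(x, path) {
  if (is.null(x$time)) stop("trace was not recorded; use record = TRUE")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# drive: %.10g", x$drive),
               sprintf("# dt_ms: %g", x$dt),
               sprintf("# spikes_ms: %s", paste(x$spikes, collapse = ",")),
               "time_ms\tv_mv"), con)
  write.table(data.frame(x$time, x$v), con, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a transition graph as an edge list
#'
#' @param x a [transition_graph()].
#' @param path output path (tab-delimited `src dst weight`).
#' @return The path, invisibly.
#' @export
write_edge_list <- function(x, path) {
  write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
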