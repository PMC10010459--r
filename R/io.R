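#' Read and write the pipeline's standard file formats
#'
#' Thin wrappers over the `tiff` package and base CSV I/O so every container
#' round-trips through the formats acquisition software produces: 16-bit
#' multi-page TIFF for movies and kymographs, CSV for traces, event tables
#' and lumen series.
#'
#' @param path file path.
#' @param stack integer/numeric array (rows x cols x frames) or matrix.
#' @name io
NULL

#' @rdname io
#' @export
writeStackTIFF <- function(stack, path) {
  if (length(dim(stack)) == 2) stack <- array(stack, dim = c(dim(stack), 1))
  pages <- lapply(seq_len(dim(stack)[3]), function(k)
    pmin(pmax(stack[, , k] / 65535, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname io
#' @export
readStackTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr
}

#' @rdname io
#' @param traces matrix of raw fluorescence (samples x ROIs).
#' @param time numeric time vector, seconds.
#' @export
writeTraceCSV <- function(traces, time, path) {
  utils::write.csv(data.frame(time = time, traces, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @return `readTraceCSV`: list with `time` and `traces` (matrix).
#' @export
readTraceCSV <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  list(time = d[[1]], traces = as.matrix(d[, -1, drop = FALSE]))
}

#' @rdname io
#' @param eventTable an [EventTable].
#' @export
writeEventCSV <- function(eventTable, path) {
  utils::write.csv(events(eventTable), path, row.names = FALSE)
  invisible(path)
}
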