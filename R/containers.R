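#' Save a numeric/complex array (portable binary + JSON sidecar)
#'
#' Values are stored little-endian float64 in C (row-major, last index
#' fastest) order; complex arrays interleave real and imaginary parts.
#' The sidecar records dims, dtype and free-form metadata. Round trips
#' are bit-exact.
#'
#' @param x numeric or complex array/matrix/vector.
#' @param path data-file path; sidecar at `<path>.json`.
#' @param meta named list of extra metadata.
#' @return `path`, invisibly.
#' @export
save_array <- function(x, path, meta = list()) {
  dims <- if (is.null(dim(x))) length(x) else dim(x)
  cplx <- is.complex(x)
  vals <- if (cplx) {
    v <- as.vector(x)
    as.vector(rbind(Re(v), Im(v)))
  } else as.vector(x)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(vals, con, size = 8L, endian = "little")
  jsonlite::write_json(
    c(list(dims = dims, dtype = if (cplx) "complex128_le" else "float64_le",
           order = "column_major"), meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load an array saved by [save_array()]
#' @param path data-file path.
#' @return The array with a `meta` attribute holding the sidecar.
#' @export
load_array <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dims)
  cplx <- identical(meta$dtype, "complex128_le")
  con <- file(path, "rb"); on.exit(close(con))
  vals <- readBin(con, "double", n = (if (cplx) 2L else 1L) * n + 1L,
                  size = 8L, endian = "little")
  if (length(vals) != (if (cplx) 2L else 1L) * n)
    stop("array payload size disagrees with sidecar dims")
  x <- if (cplx) {
    m <- matrix(vals, 2L)
    complex(real = m[1L, ], imaginary = m[2L, ])
  } else vals
  if (length(meta$dims) > 1L) dim(x) <- meta$dims
  attr(x, "meta") <- meta
  x
}

#' Save a cross-spectral tensor
#' @param cs a `cross_spectrum`.
#' @param path data-file path.
#' @return `path`, invisibly.
#' @export
save_cross_spectrum <- function(cs, path) {
  save_array(cs$S, path, meta = list(kind = "cross_spectrum",
                                     frequencies = cs$frequencies,
                                     m = cs$m, labels = cs$labels,
                                     transform = cs$transform))
}

#' Load a cross-spectral tensor saved by [save_cross_spectrum()]
#' @param path data-file path.
#' @return A `cross_spectrum`.
#' @export
load_cross_spectrum <- function(path) {
  x <- load_array(path)
  meta <- attr(x, "meta")
  attr(x, "meta") <- NULL
  structure(list(S = x, frequencies = meta$frequencies, m = meta$m,
                 labels = meta$labels, transform = meta$transform,
                 bands = NULL),
            class = "cross_spectrum")
}

#' Save multichannel time series (binary matrix + JSON metadata)
#' @param x a [ts_data()].
#' @param path data-file path.
#' @return `path`, invisibly.
#' @export
save_ts_data <- function(x, path) {
  save_array(x$data, path, meta = list(kind = "ts_data",
                                       sampling_rate = x$sampling_rate,
                                       labels = x$labels))
}

#' Load time series saved by [save_ts_data()]
#' @param path data-file path.
#' @return A [ts_data()].
#' @export
load_ts_data <- function(path) {
  x <- load_array(path)
  meta <- attr(x, "meta")
  attr(x, "meta") <- NULL
  ts_data(x, meta$sampling_rate, labels = meta$labels)
}
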