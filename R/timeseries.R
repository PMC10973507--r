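#' 4D signal time series container
#'
#' Light container for a 4D gradient-echo EPI time series with its
#' acquisition metadata and an optional brain mask.
#'
#' @param data Numeric 4D array (x, y, z, t).
#' @param TR,TE Repetition and echo time in seconds.
#' @param field_strength Main field strength in tesla.
#' @param mask Optional logical 3D array; default all TRUE.
#' @return Object of class \code{bhdsc_ts}.
#' @export
bhdsc_ts <- function(data, TR, TE, field_strength = NA_real_, mask = NULL) {
  if (length(dim(data)) != 4L) stop("data must be a 4D array (x, y, z, t)")
  stopifnot(TR > 0, TE > 0)
  d3 <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d3)
  if (!identical(dim(mask), d3)) stop("mask dimensions must match data")
  structure(list(data = data, TR = TR, TE = TE,
                 field_strength = field_strength,
                 mask = array(as.logical(mask), d3)),
            class = "bhdsc_ts")
}

#' @export
print.bhdsc_ts <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bhDSC time series: %d x %d x %d voxels, %d volumes\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("TR = %g s, TE = %g ms, field = %g T, %d voxels in mask\n",
              x$TR, 1000 * x$TE, x$field_strength, sum(x$mask)))
  invisible(x)
}

## V x T matrix of in-mask voxel time courses (V = sum(mask)).
ts_matrix <- function(ts) {
  d <- dim(ts$data)
  m <- matrix(ts$data, nrow = prod(d[1:3]), ncol = d[4])
  m[mask_idx(ts$mask), , drop = FALSE]
}

## Rebuild a 3D map from per-masked-voxel values.
map_from_masked <- function(values, mask, fill = NA_real_) {
  out <- array(fill, dim(mask))
  out[mask_idx(mask)] <- values
  out
}
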