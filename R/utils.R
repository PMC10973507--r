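#' Trapezoidal integral
#'
#' @param x Abscissa (monotone increasing).
#' @param y Ordinate, same length as \code{x}.
#' @return Numeric scalar, the trapezoid-rule integral of \code{y} over \code{x}.
#' @keywords internal
#' @noRd
trapz <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

## Row-wise trapezoid over a common time grid (V x T matrix).
trapz_rows <- function(x, ymat) {
  if (length(x) < 2L) return(numeric(nrow(ymat)))
  w <- numeric(length(x))
  dx <- diff(x)
  w[1L] <- dx[1L] / 2
  w[length(x)] <- dx[length(dx)] / 2
  if (length(x) > 2L) w[2:(length(x) - 1L)] <- (dx[-length(dx)] + dx[-1L]) / 2
  as.numeric(ymat %*% w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Flatten a 3D logical/numeric mask to voxel indices.
mask_idx <- function(mask) which(as.logical(mask))
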