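#' Linear detrend and temporal Gaussian smoothing
#'
#' Removes each voxel's best-fit linear trend (preserving its mean) and then
#' smooths along time with a length-5 normalised Gaussian kernel
#' (sigma = 1 sample), with reflection at the series edges.
#'
#' @param ts A [bhdsc_ts()].
#' @param kernel_length,kernel_sigma Smoothing kernel size (samples) and
#'   width (samples).
#' @return A [bhdsc_ts()] with processed data.
#' @export
detrend_and_smooth <- function(ts, kernel_length = 5, kernel_sigma = 1) {
  stopifnot(inherits(ts, "bhdsc_ts"))
  d <- dim(ts$data)
  nt <- d[4]
  if (nt < kernel_length) {
    stop("need at least ", kernel_length, " volumes, got ", nt)
  }
  m <- matrix(ts$data, nrow = prod(d[1:3]), ncol = nt)

  ## closed-form least-squares slope per voxel; remove slope, keep mean
  tc <- seq_len(nt) - (nt + 1) / 2
  denom <- sum(tc^2)
  slope <- as.numeric(m %*% tc) / denom
  m <- m - outer(slope, tc)

  half <- (kernel_length - 1) %/% 2
  w <- stats::dnorm(seq(-half, half), 0, kernel_sigma)
  w <- w / sum(w)
  ## reflect edges, convolve, crop
  pad <- cbind(m[, (half + 1):2, drop = FALSE], m,
               m[, (nt - 1):(nt - half), drop = FALSE])
  sm <- matrix(0, nrow(m), nt)
  for (j in seq_len(kernel_length)) {
    sm <- sm + w[j] * pad[, j:(j + nt - 1), drop = FALSE]
  }
  out <- ts
  out$data <- array(sm, d)
  out
}

#' Bolus-triggered averaging of breath-hold blocks
#'
#' Locates the bolus extremum of each breath-hold block, allots a 72 s
#' window centred at the bolus maximum, and averages the first \code{n_use}
#' windows sample-wise per voxel. Baseline bookkeeping follows the
#' operational definition: ten volumes immediately before bolus onset and
#' ten after the signal returns to the pre-bolus baseline (first post-peak
#' sample within one baseline standard deviation of the pre-bolus mean)
#' define the baseline signal S0 and its temporal standard deviation eps_t.
#'
#' The per-block extremum search is restricted to hold onset + 5 s through
#' block end + 20 s, reflecting the 10-15 s lung-to-brain lag. Windows
#' extending past the array bounds are padded by the edge value with a
#' warning.
#'
#' @param ts A [bhdsc_ts()] (typically after [detrend_and_smooth()]).
#' @param protocol A [bh_protocol()].
#' @param n_use Number of initial boluses to average (default 8; the ninth
#'   block of the standard protocol is ignored).
#' @param window_s Bolus window length in seconds (default 72).
#' @param baseline_n \code{"twenty"}: eps_t over the 10 + 10 baseline
#'   volumes; \code{"ten"}: over 5 + 5 (the literal ten-total reading).
#' @return Object of class \code{bolus_average}: list with \code{window}
#'   (V x W matrix of averaged windows over in-mask voxels), \code{time}
#'   (window time axis, s), \code{S0}, \code{Smax} (signed extremum),
#'   \code{eps_t}, \code{peak_index}, \code{n_boluses_used}, \code{mask},
#'   \code{TR}, \code{TE}.
#' @export
average_boluses <- function(ts, protocol, n_use = 8, window_s = 72,
                            baseline_n = c("twenty", "ten")) {
  stopifnot(inherits(ts, "bhdsc_ts"), inherits(protocol, "bh_protocol"))
  baseline_n <- match.arg(baseline_n)
  if (n_use > protocol$n_blocks) {
    stop("n_use = ", n_use, " exceeds the ", protocol$n_blocks,
         " protocol blocks")
  }
  TR <- ts$TR
  nt <- dim(ts$data)[4]
  W <- as.integer(round(window_s / TR))
  m <- ts_matrix(ts)
  V <- nrow(m)

  ## per-block extremum search bounds (volume indices)
  lo <- hi <- integer(n_use)
  for (b in seq_len(n_use)) {
    t0 <- (b - 1) * protocol$block_s
    lo[b] <- as.integer(round((t0 + protocol$prep_s + 5) / TR)) + 1L
    hi[b] <- min(as.integer(round((t0 + protocol$block_s + 20) / TR)) + 1L, nt)
  }
  if (any(lo >= hi)) stop("protocol blocks do not fit the time series")

  ## one window per block, centred at the bolus maximum of the mean in-mask
  ## time course, identical for every voxel (this preserves inter-voxel
  ## delays through the averaging)
  warned <- FALSE
  half_pre <- as.integer(floor((W - 1) / 2))
  avg <- matrix(0, V, W)
  ref <- colMeans(m)
  ref_med <- stats::median(ref)
  for (b in seq_len(n_use)) {
    pk <- lo[b] - 1L + which.max(abs(ref[lo[b]:hi[b]] - ref_med))
    idx <- pk - half_pre + 0:(W - 1L)
    if ((idx[1] < 1L || idx[W] > nt) && !warned) {
      warning("bolus window exceeds array bounds; padding by edge value")
      warned <- TRUE
    }
    idx <- pmin(pmax(idx, 1L), nt)
    avg <- avg + m[, idx, drop = FALSE]
  }
  avg <- avg / n_use

  ## baseline bookkeeping per voxel on the averaged window
  nb <- 10L
  S0 <- Smax <- eps <- numeric(V)
  peak <- integer(V)
  for (v in seq_len(V)) {
    x <- avg[v, ]
    pre_mean <- mean(x[1:nb])
    pre_sd <- stats::sd(x[1:nb])
    pk <- which.max(abs(x - pre_mean))
    within <- abs(x - pre_mean) <= pre_sd
    onset <- if (pk > 1 && any(within[1:(pk - 1)])) max(which(within[1:(pk - 1)])) else nb
    ret <- if (pk < W && any(within[(pk + 1):W])) pk + min(which(within[(pk + 1):W])) else W - nb + 1L
    pre_idx <- max(1L, onset - nb + 1L):onset
    post_idx <- ret:min(W, ret + nb - 1L)
    base_idx <- unique(c(pre_idx, post_idx))
    if (baseline_n == "ten") {
      base_idx <- unique(c(pre_idx[max(1, length(pre_idx) - 4L):length(pre_idx)],
                           post_idx[1:min(5L, length(post_idx))]))
    }
    S0[v] <- mean(x[base_idx])
    eps[v] <- stats::sd(x[base_idx])
    pk <- which.max(abs(x - S0[v]))
    peak[v] <- pk
    Smax[v] <- x[pk]
  }

  structure(list(window = avg, time = (seq_len(W) - 1) * TR,
                 S0 = S0, Smax = Smax, eps_t = eps, peak_index = peak,
                 n_boluses_used = n_use, mask = ts$mask,
                 TR = TR, TE = ts$TE, window_s = window_s),
            class = "bolus_average")
}

#' Percentage maximal signal change
#'
#' \eqn{\Delta S = 100\,|S_{max} - S_0| / S_0}, with the sign of the
#' excursion stored separately (negative-going voxels, the AIF candidates,
#' keep a -1 flag).
#'
#' @param b A [average_boluses()] result.
#' @return List with \code{dS} (percent, non-negative) and \code{sign}
#'   (+1/-1 per voxel).
#' @export
delta_s <- function(b) {
  stopifnot(inherits(b, "bolus_average"))
  if (any(b$S0 <= 0)) {
    stop("non-positive baseline S0 in voxel(s) ",
         paste(utils::head(which(b$S0 <= 0), 5), collapse = ", "))
  }
  dev <- b$Smax - b$S0
  list(dS = 100 * abs(dev) / b$S0, sign = ifelse(dev >= 0, 1, -1))
}

#' Contrast-to-noise ratio of the averaged bolus
#'
#' \eqn{CNR = |S_{max} - S_0| / \varepsilon_t}. Voxels with zero baseline
#' temporal standard deviation are flagged invalid (NA), not infinite.
#'
#' @param b A [average_boluses()] result.
#' @return Numeric vector of CNR values with attribute \code{valid}.
#' @export
cnr <- function(b) {
  stopifnot(inherits(b, "bolus_average"))
  valid <- b$eps_t > 0
  out <- rep(NA_real_, length(b$eps_t))
  out[valid] <- abs(b$Smax - b$S0)[valid] / b$eps_t[valid]
  attr(out, "valid") <- valid
  out
}

#' Gray-to-white matter contrast
#'
#' Difference of the mean gray- and white-matter CNRs.
#'
#' @param cnr_gm,cnr_wm Mean CNR in gray and white matter.
#' @return \code{cnr_gm - cnr_wm}.
#' @examples
#' gw_contrast(6.2, 4.0)   # 2.2
#' @export
gw_contrast <- function(cnr_gm, cnr_wm) {
  stopifnot(is.finite(cnr_gm), is.finite(cnr_wm))
  cnr_gm - cnr_wm
}

#' Apparent transverse relaxation rate change
#'
#' Converts signal to the apparent relaxation rate change
#' \deqn{\Delta R_2^*(t) = -\frac{1}{TE}\,\ln\frac{S(t)}{S_0},}
#' negative when the signal rises. The area under the curve is the
#' trapezoidal integral over the bolus window.
#'
#' @param x A \code{bolus_average} object, or a numeric vector/matrix of
#'   signal samples (rows = voxels).
#' @param TE Echo time in seconds (taken from \code{x} when available).
#' @param S0 Baseline signal (scalar or per-row); taken from \code{x} when
#'   available.
#' @param time Time axis in seconds for the AUC (taken from \code{x} when
#'   available).
#' @return Object of class \code{relaxation_series}: list with \code{dR2s}
#'   (V x W matrix, 1/s), \code{time}, \code{AUC}, \code{TE}, \code{S0} and,
#'   when computed from a \code{bolus_average}, \code{mask}.
#' @export
delta_r2star <- function(x, TE = NULL, S0 = NULL, time = NULL) {
  mask <- NULL
  if (inherits(x, "bolus_average")) {
    TE <- TE %||% x$TE
    S0 <- S0 %||% x$S0
    time <- time %||% x$time
    mask <- x$mask
    x <- x$window
  }
  if (is.null(TE) || TE <= 0) stop("TE must be supplied and positive")
  if (is.null(S0)) stop("S0 must be supplied")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(time)) time <- (seq_len(ncol(x)) - 1)
  bad <- which(rowSums(x <= 0) > 0)
  if (length(bad)) {
    stop("non-positive signal sample in voxel(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(S0 <= 0)) stop("non-positive S0")
  dr <- -(1 / TE) * log(x / S0)
  structure(list(dR2s = dr, time = time, AUC = trapz_rows(time, dr),
                 TE = TE, S0 = S0, mask = mask),
            class = "relaxation_series")
}

#' Apparent relaxation-rate AUC map
#'
#' Per-voxel signed trapezoidal integral of the apparent relaxation rate
#' change over the bolus window, reshaped onto the acquisition grid.
#'
#' @param rs A [delta_r2star()] result carrying a voxel mask.
#' @param mask Logical 3D array; defaults to the mask stored in \code{rs}.
#' @return 3D numeric array (1/s * s); NA outside the mask.
#' @export
auc_map <- function(rs, mask = NULL) {
  stopifnot(inherits(rs, "relaxation_series"))
  mask <- mask %||% rs$mask
  if (is.null(mask)) stop("no voxel mask available")
  map_from_masked(rs$AUC, mask)
}
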