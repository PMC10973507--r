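#' Tracer-kinetic constants
#'
#' The constants of the standard DSC quantification: hematocrit correction
#' factor k_H = 1.45 (large- versus small-vessel hematocrit), brain density
#' factor rho = 1.05 g/mL, and the truncated-SVD noise threshold of 20\% of
#' the largest singular value.
#'
#' @param k_H Hematocrit correction factor.
#' @param rho Brain density factor.
#' @param svd_threshold Fraction of the largest singular value below which
#'   singular values are zeroed; must lie in (0, 1) (0 is accepted for
#'   exact-inverse oracle checks).
#' @return Object of class \code{kinetic_constants}.
#' @export
kinetic_constants <- function(k_H = 1.45, rho = 1.05, svd_threshold = 0.20) {
  if (k_H <= 0 || rho <= 0) stop("k_H and rho must be positive")
  if (svd_threshold < 0 || svd_threshold >= 1) {
    stop("svd_threshold must lie in [0, 1)")
  }
  structure(list(k_H = k_H, rho = rho, svd_threshold = svd_threshold),
            class = "kinetic_constants")
}

#' Truncate time courses to the AIF-to-VOF bolus window
#'
#' Cuts all voxel time courses and both input functions to the interval
#' from the start of the AIF bolus to the end of the VOF bolus.
#'
#' @param x Numeric matrix (voxels x time) or vector of tissue relaxation
#'   samples.
#' @param time Time axis in seconds.
#' @param aif,vof \code{input_function} objects carrying bolus edges.
#' @return List with \code{x}, \code{time}, \code{aif_tc}, \code{vof_tc}
#'   restricted to the window, and the retained \code{indices}.
#' @export
truncate_window <- function(x, time, aif, vof) {
  if (aif$bolus_start >= vof$bolus_end) {
    stop(sprintf("inverted truncation window: AIF start %.1f s >= VOF end %.1f s",
                 aif$bolus_start, vof$bolus_end))
  }
  keep <- which(time >= aif$bolus_start & time <= vof$bolus_end)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  list(x = x[, keep, drop = FALSE], time = time[keep],
       aif_tc = aif$timecourse[keep], vof_tc = vof$timecourse[keep],
       indices = keep)
}

#' Discrete convolution matrix of the scaled AIF
#'
#' Builds the lower-triangular (Toeplitz) rectangle-rule discretisation of
#' the tracer-kinetic convolution, \eqn{A_{ij} = \Delta t\,
#' AIF_{scaled}(t_{i-j})} for \eqn{j \le i}, so that the tissue curve is
#' \eqn{c = A k} for residue function k.
#'
#' @param aif_tc Scaled AIF samples on a uniform grid.
#' @param dt Sampling interval in seconds.
#' @return n x n lower-triangular matrix.
#' @export
build_convolution_matrix <- function(aif_tc, dt) {
  if (length(dt) > 1) {
    if (max(abs(diff(dt))) > 1e-9 * max(abs(dt))) {
      stop("non-uniform sampling: the convolution matrix needs a constant dt")
    }
    dt <- dt[1]
  }
  n <- length(aif_tc)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, 1:i] <- dt * aif_tc[i:1]
  A
}

#' Truncated-SVD deconvolution
#'
#' Solves \eqn{c = A k} for the residue function by singular value
#' decomposition of A, zeroing singular values below
#' \code{svd_threshold} times the largest (the 20\% noise threshold of the
#' standard analysis).
#'
#' @param tissue Numeric vector or matrix (voxels x time) of tissue
#'   relaxation samples on the truncated window.
#' @param A Convolution matrix from [build_convolution_matrix()].
#' @param constants A [kinetic_constants()] (only \code{svd_threshold} is
#'   used here).
#' @return Residue function(s) k(t), same shape as \code{tissue}, units 1/s
#'   per second.
#' @export
svd_deconvolve <- function(tissue, A, constants = kinetic_constants()) {
  vec <- is.null(dim(tissue))
  if (vec) tissue <- matrix(tissue, nrow = 1)
  if (ncol(tissue) != nrow(A)) stop("tissue length must match A")
  sv <- svd(A)
  keep <- sv$d >= constants$svd_threshold * sv$d[1]
  if (!any(keep)) stop("all singular values fall below the threshold")
  dinv <- ifelse(keep, 1 / sv$d, 0)
  ## k = V S^+ U' c, per voxel (rows of `tissue`)
  k <- tissue %*% sv$u %*% (dinv * t(sv$v))
  if (vec) as.numeric(k) else k
}

#' Relative cerebral blood volume from bolus integrals
#'
#' \deqn{CBV = \frac{k_H}{\rho}\; \frac{\int c_{tissue}\,dt}{\int
#' AIF_{scaled}\,dt}} on the truncated window; both integrals share sign
#' after the VOF scaling, so CBV is positive for normal voxels.
#'
#' @param tissue Vector or matrix (voxels x time) of tissue relaxation
#'   samples on the truncated window.
#' @param aif_tc Scaled-AIF samples on the same window.
#' @param time Window time axis.
#' @param constants A [kinetic_constants()].
#' @return CBV in arbitrary units (volume-fraction scale), one per voxel.
#' @export
compute_cbv <- function(tissue, aif_tc, time, constants = kinetic_constants()) {
  if (is.null(dim(tissue))) tissue <- matrix(tissue, nrow = 1)
  denom <- trapz(time, aif_tc)
  if (abs(denom) < .Machine$double.eps) stop("zero scaled-AIF integral")
  as.numeric(constants$k_H / constants$rho * trapz_rows(time, tissue) / denom)
}

#' Relative CBF and MTT from the residue function
#'
#' \eqn{CBF = (k_H/\rho)\,\max k(t)} and, by the central volume principle,
#' \eqn{MTT = CBV / CBF}. Voxels with a non-positive residue maximum are
#' invalidated (NA).
#'
#' @param k Residue function(s) from [svd_deconvolve()] (vector or
#'   voxels x time matrix).
#' @param cbv CBV per voxel from [compute_cbv()].
#' @param constants A [kinetic_constants()].
#' @return List with \code{CBF} (a.u.), \code{MTT} (s) and logical
#'   \code{valid}.
#' @export
compute_cbf_mtt <- function(k, cbv, constants = kinetic_constants()) {
  if (is.null(dim(k))) k <- matrix(k, nrow = 1)
  kmax <- apply(k, 1, max)
  valid <- kmax > 0 & !is.na(cbv) & cbv > 0
  cbf <- ifelse(valid, constants$k_H / constants$rho * kmax, NA_real_)
  mtt <- ifelse(valid, cbv / cbf, NA_real_)
  list(CBF = cbf, MTT = mtt, valid = valid)
}

#' Voxel-wise perfusion maps
#'
#' Applies truncation, VOF scaling of the AIF, integral-based CBV, and
#' truncated-SVD deconvolution for CBF and MTT to every in-mask voxel,
#' excluding voxels that yield negative CBV or CBF from the validity mask
#' (they are retained in the raw maps, since negative values carry meaning
#' in steal physiology).
#'
#' @param rs A [delta_r2star()] result over the in-mask voxels.
#' @param aif Raw AIF from [select_aif()] (scaled internally if needed).
#' @param vof VOF from [select_vof()].
#' @param masks Optional list of logical 3D arrays (e.g. \code{gm},
#'   \code{wm}) used for the summary table.
#' @param constants A [kinetic_constants()].
#' @return Object of class \code{perfusion_result}: 3D maps \code{CBV},
#'   \code{CBF} (a.u.), \code{MTT} (s), \code{valid_mask}, the scaled AIF,
#'   and a per-region \code{summary} data frame (mean, sd, CV).
#' @export
perfusion_maps <- function(rs, aif, vof, masks = NULL,
                           constants = kinetic_constants()) {
  stopifnot(inherits(rs, "relaxation_series"))
  if (is.null(rs$mask)) stop("relaxation series must carry a voxel mask")
  aif_s <- if (aif$scaled) aif else scale_aif(aif, vof)
  tw <- truncate_window(rs$dR2s, rs$time, aif_s, vof)
  if (all(abs(tw$x) < .Machine$double.eps)) {
    warning("all-zero tissue curves; empty validity mask")
  }
  dt <- diff(tw$time[1:2])
  A <- build_convolution_matrix(tw$aif_tc, dt)
  cbv <- compute_cbv(tw$x, tw$aif_tc, tw$time, constants)
  k <- svd_deconvolve(tw$x, A, constants)
  fm <- compute_cbf_mtt(k, cbv, constants)
  valid <- fm$valid & cbv > 0

  mk <- rs$mask
  res <- structure(list(
    CBV = map_from_masked(cbv, mk),
    CBF = map_from_masked(fm$CBF, mk),
    MTT = map_from_masked(fm$MTT, mk),
    valid_mask = map_from_masked(valid, mk, fill = FALSE) == 1,
    aif_scaled = aif_s, vof = vof, constants = constants,
    window = tw$time
  ), class = "perfusion_result")
  res$summary <- summarize_perfusion(res, masks)
  res
}

summarize_perfusion <- function(res, masks) {
  if (is.null(masks)) return(NULL)
  rows <- lapply(names(masks), function(nm) {
    sel <- as.logical(masks[[nm]]) & res$valid_mask
    do.call(rbind, lapply(c("CBV", "CBF", "MTT"), function(p) {
      v <- res[[p]][sel]
      v <- v[is.finite(v)]
      data.frame(region = nm, parameter = p, n = length(v),
                 mean = mean(v), sd = stats::sd(v),
                 cv = stats::sd(v) / mean(v), stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' @export
print.perfusion_result <- function(x, ...) {
  cat(sprintf("bhDSC perfusion maps: %d valid voxels; window %.1f-%.1f s\n",
              sum(x$valid_mask), min(x$window), max(x$window)))
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
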