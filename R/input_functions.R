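## Constructor shared by AIF/VOF selection and the simulation experiments.
new_input_function <- function(kind, voxels, timecourse, time,
                               frac = 0.1, min_run = 2L, scaled = FALSE,
                               scale_ratio = NA_real_) {
  edges <- bolus_edges(timecourse, time, frac = frac, min_run = min_run)
  win <- time >= edges[1] & time <= edges[2]
  structure(list(
    kind = kind, voxels = voxels, timecourse = timecourse, time = time,
    bolus_start = edges[1], bolus_end = edges[2],
    integral = trapz(time[win], timecourse[win]),
    scaled = scaled, scale_ratio = scale_ratio
  ), class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("%s from %d voxel(s): bolus %.1f-%.1f s, integral %.4g 1/s*s%s\n",
              x$kind, length(x$voxels), x$bolus_start, x$bolus_end,
              x$integral, if (x$scaled) " (scaled)" else ""))
  invisible(x)
}

## Bolus edges: first/last crossing of `frac` of the peak |dR2s| sustained
## for at least `min_run` samples.
bolus_edges <- function(tc, time, frac = 0.1, min_run = 2L) {
  a <- abs(tc)
  thr <- frac * max(a)
  above <- a >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  if (!any(keep)) return(range(time))
  c(time[min(starts[keep])], time[max(ends[keep])])
}

#' Refine gray/white matter masks with partial-volume and noise criteria
#'
#' Keeps voxels whose partial-volume estimate exceeds 0.9 and whose baseline
#' temporal standard deviation lies in the lowest 10\% of the eps_t range
#' within the brain mask - the rationale being that high-blood-volume voxels
#' have elevated physiological noise and must not contaminate the tissue
#' masks.
#'
#' @param pve_gm,pve_wm 3D partial-volume probability maps on the
#'   acquisition grid.
#' @param eps_t_map 3D map of baseline temporal standard deviation.
#' @param brain_mask Logical 3D array; defaults to all voxels.
#' @param pve_threshold Partial-volume threshold (default 0.9).
#' @param eps_quantile Fraction of the eps_t range retained (default 0.10).
#' @return List of class \code{tissue_masks} with logical arrays \code{gm},
#'   \code{wm} (disjoint) and the eps_t cutoff used.
#' @export
refine_tissue_masks <- function(pve_gm, pve_wm, eps_t_map, brain_mask = NULL,
                                pve_threshold = 0.9, eps_quantile = 0.10) {
  stopifnot(identical(dim(pve_gm), dim(pve_wm)),
            identical(dim(pve_gm), dim(eps_t_map)))
  brain_mask <- brain_mask %||% array(TRUE, dim(pve_gm))
  e <- eps_t_map[brain_mask]
  cutoff <- min(e, na.rm = TRUE) +
    eps_quantile * (max(e, na.rm = TRUE) - min(e, na.rm = TRUE))
  quiet <- brain_mask & !is.na(eps_t_map) & eps_t_map <= cutoff
  gm <- brain_mask & pve_gm > pve_threshold & quiet
  wm <- brain_mask & pve_wm > pve_threshold & quiet & !gm
  if (!any(gm) || !any(wm)) {
    stop(sprintf(
      paste0("empty tissue mask after refinement: GM %d -> %d, WM %d -> %d ",
             "voxels (PVE > %.2f then eps_t <= %.4g)"),
      sum(pve_gm > pve_threshold & brain_mask), sum(gm),
      sum(pve_wm > pve_threshold & brain_mask), sum(wm),
      pve_threshold, cutoff))
  }
  structure(list(gm = gm, wm = wm, eps_cutoff = cutoff),
            class = "tissue_masks")
}

#' Select the vasodilation-based arterial input function
#'
#' Among candidate arterial voxels with a negative signal change, retains
#' those whose magnitude exceeds the 99th percentile of the negative-voxel
#' magnitudes and whose bolus delay is short, ranks them by magnitude and
#' keeps 15-20; their apparent relaxation time courses are averaged into the
#' AIF. The negative signal change reflects pure arterial vasodilation
#' (blood displacing CSF/tissue), not a paramagnetic bolus, which is what
#' makes this input function usable for hypercapnic paradigms.
#'
#' @param ds Result of [delta_s()] (list with \code{dS} and \code{sign}
#'   over in-mask voxels).
#' @param rs The matching [delta_r2star()] series.
#' @param candidate_mask Logical 3D array of arterial candidates (e.g.
#'   MCA/PCA/ACA seeds, or the artery region of a phantom).
#' @param delay Optional per-voxel delay vector (s) over in-mask voxels;
#'   voxels with delay greater than \code{max_delay} are dropped.
#' @param mask Acquisition-grid voxel mask matching \code{ds}; defaults to
#'   the mask in \code{rs}.
#' @param percentile Magnitude percentile within the negative candidates
#'   (default 0.99).
#' @param n_min,n_max Target voxel count band (15-20).
#' @param max_delay Largest delay (s) accepted as "short" (default 0.5).
#' @return An \code{input_function} of kind \code{"AIF"} (raw, unscaled;
#'   positive apparent relaxation integral).
#' @export
select_aif <- function(ds, rs, candidate_mask, delay = NULL, mask = NULL,
                       percentile = 0.99, n_min = 15L, n_max = 20L,
                       max_delay = 0.5) {
  mask <- mask %||% rs$mask
  if (is.null(mask)) stop("voxel mask required")
  cand <- as.logical(candidate_mask)[mask_idx(mask)]
  neg <- cand & ds$sign < 0
  if (!any(neg)) stop("no candidate AIF: no negative-dS voxel in the mask")
  mag <- ds$dS
  thr <- stats::quantile(mag[neg], percentile, names = FALSE)
  keep <- neg & mag >= thr
  if (!is.null(delay)) keep <- keep & !is.na(delay) & delay <= max_delay
  idx <- which(keep)
  idx <- idx[order(mag[idx], decreasing = TRUE)]
  if (length(idx) < n_min) {
    extra <- setdiff(which(neg)[order(mag[neg], decreasing = TRUE)], idx)
    idx <- c(idx, utils::head(extra, n_min - length(idx)))
  }
  idx <- utils::head(idx, n_max)
  if (length(idx) < 3L) {
    warning("fewer than 3 AIF voxels survive selection; proceeding with ",
            length(idx))
  }
  tc <- colMeans(rs$dR2s[idx, , drop = FALSE])
  new_input_function("AIF", voxels = mask_idx(mask)[idx],
                     timecourse = tc, time = rs$time)
}

#' Select the venous output function
#'
#' Retains candidate venous voxels (superior sagittal sinus territory) with
#' a positive signal change above the 99.9th percentile, a long bolus delay
#' (about 2-3 s) and low baseline signal (below the candidate median, as
#' venous blood carries more deoxyhemoglobin), keeps 15-20 by magnitude and
#' averages their relaxation time courses. If no voxel passes, the delay
#' window is progressively relaxed with a warning.
#'
#' @inheritParams select_aif
#' @param S0 Baseline signal per in-mask voxel.
#' @param delay_window Accepted delay range in seconds (default 1.5-4).
#' @param percentile Magnitude percentile (default 0.999).
#' @return An \code{input_function} of kind \code{"VOF"} (negative apparent
#'   relaxation integral).
#' @export
select_vof <- function(ds, rs, candidate_mask, delay = NULL, S0 = NULL,
                       mask = NULL, percentile = 0.999, n_min = 15L,
                       n_max = 20L, delay_window = c(1.5, 4.0)) {
  mask <- mask %||% rs$mask
  if (is.null(mask)) stop("voxel mask required")
  cand <- as.logical(candidate_mask)[mask_idx(mask)]
  pos <- cand & ds$sign > 0
  if (!any(pos)) stop("no candidate VOF: no positive-dS voxel in the mask")
  mag <- ds$dS
  thr <- stats::quantile(mag[pos], percentile, names = FALSE)
  keep <- pos & mag >= thr
  if (!is.null(S0)) keep <- keep & S0 <= stats::median(S0[pos])
  if (!is.null(delay)) {
    win <- delay_window
    repeat {
      k2 <- keep & !is.na(delay) & delay >= win[1] & delay <= win[2]
      if (any(k2) || (win[1] <= 0 && win[2] >= 8)) break
      win <- c(max(0, win[1] - 0.5), min(8, win[2] + 0.5))
      warning(sprintf("no VOF voxel in delay window; relaxing to [%.1f, %.1f] s",
                      win[1], win[2]))
    }
    keep <- k2
  }
  idx <- which(keep)
  idx <- idx[order(mag[idx], decreasing = TRUE)]
  if (length(idx) < n_min) {
    extra <- setdiff(which(pos)[order(mag[pos], decreasing = TRUE)], idx)
    idx <- c(idx, utils::head(extra, n_min - length(idx)))
  }
  idx <- utils::head(idx, n_max)
  tc <- colMeans(rs$dR2s[idx, , drop = FALSE])
  new_input_function("VOF", voxels = mask_idx(mask)[idx],
                     timecourse = tc, time = rs$time)
}

#' Scale the AIF by the integral of the VOF
#'
#' \deqn{AIF_{scaled}(t) = \frac{\int VOF\,dt}{\int AIF\,dt}\; AIF(t).}
#' The VOF integral represents the amount of contrast agent
#' (deoxyhemoglobin) while the raw AIF integral represents the degree of
#' vasodilation; the ratio is negative (VOF integral < 0, AIF integral > 0),
#' so scaling also flips the AIF into the tissue sign convention. By
#' construction the scaled AIF integral equals the VOF integral exactly.
#'
#' @param aif,vof \code{input_function} objects from [select_aif()] /
#'   [select_vof()] (or constructed from simulation curves).
#' @return The scaled AIF (an \code{input_function} with
#'   \code{scaled = TRUE} and the applied ratio stored).
#' @export
scale_aif <- function(aif, vof) {
  stopifnot(inherits(aif, "input_function"), inherits(vof, "input_function"))
  if (abs(aif$integral) < .Machine$double.eps) stop("zero AIF integral")
  if (abs(vof$integral) < .Machine$double.eps) stop("zero VOF integral")
  ratio <- vof$integral / aif$integral
  out <- aif
  out$timecourse <- ratio * aif$timecourse
  out$integral <- ratio * aif$integral   # == vof$integral exactly
  out$scaled <- TRUE
  out$scale_ratio <- ratio
  out
}
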