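#' Fit the breath-hold DSC perfusion model
#'
#' End-to-end estimation of relative perfusion from a breath-hold
#' gradient-echo time series: linear detrending and temporal smoothing,
#' bolus-triggered averaging of the first eight breath-holds, conversion to
#' apparent relaxation-rate change, selection of the vasodilation-based
#' arterial input function (negative signal change, 99th percentile, short
#' delay) and the venous output function (99.9th percentile, long delay,
#' low baseline signal), scaling of the AIF by the VOF integral, truncated
#' singular-value-decomposition deconvolution into CBV / CBF / MTT maps, and
#' a model-independent bolus delay map.
#'
#' @param ts A [bhdsc_ts()] 4D time series.
#' @param artery_mask,vein_mask Logical 3D candidate masks for the AIF
#'   (cerebral arteries) and the VOF (superior sagittal sinus).
#' @param gm_mask,wm_mask Optional logical 3D tissue masks for the summary
#'   statistics (e.g. from [refine_tissue_masks()]).
#' @param protocol A [bh_protocol()].
#' @param config A [bhdsc_config()].
#' @return Object of class \code{bhdsc}: components \code{bolus_average},
#'   \code{dS} / \code{dS_sign} / \code{CNR} / \code{eps_t} (3D maps),
#'   \code{relax} (relaxation series), \code{aif}, \code{vof},
#'   \code{aif_scaled}, \code{delay} (a \code{delay_map}),
#'   \code{perfusion} (a \code{perfusion_result}), \code{masks},
#'   \code{summary} (per-region statistics), \code{gw_contrast}.
#' @seealso [summary.bhdsc()], [coef.bhdsc()], [plot.bhdsc()]
#' @export
bhdsc <- function(ts, artery_mask, vein_mask, gm_mask = NULL, wm_mask = NULL,
                  protocol = bh_protocol(), config = bhdsc_config()) {
  stopifnot(inherits(ts, "bhdsc_ts"))
  validate_config(config)
  constants <- kinetic_constants(config$k_H, config$rho, config$svd_threshold)

  pre <- detrend_and_smooth(ts, config$kernel_length, config$kernel_sigma)
  b <- average_boluses(pre, protocol, n_use = config$n_use,
                       window_s = config$window_s,
                       baseline_n = config$baseline_n)
  ds <- delta_s(b)
  cn <- cnr(b)
  rs <- delta_r2star(b)

  ## provisional AIF (mean over negative-change artery candidates),
  ## sign-flipped, to bootstrap the delay map used during selection
  cand <- as.logical(artery_mask)[mask_idx(ts$mask)]
  neg <- cand & ds$sign < 0
  if (!any(neg)) stop("no candidate AIF: no negative-dS voxel in artery mask")
  prelim <- new_input_function(
    "AIF", which(neg), -colMeans(rs$dR2s[neg, , drop = FALSE]), rs$time)
  dm0 <- delay_map(rs, prelim, max_shift = config$delay_max,
                   step = config$delay_step)

  aif <- select_aif(ds, rs, artery_mask, delay = dm0$delay_vec,
                    percentile = config$aif_percentile,
                    max_delay = config$aif_max_delay)
  vof <- select_vof(ds, rs, vein_mask, delay = dm0$delay_vec, S0 = b$S0,
                    percentile = config$vof_percentile,
                    delay_window = config$vof_delay_window)
  aif_s <- scale_aif(aif, vof)
  dm <- delay_map(rs, aif_s, max_shift = config$delay_max,
                  step = config$delay_step)

  masks <- list()
  if (!is.null(gm_mask)) masks$gm <- gm_mask
  if (!is.null(wm_mask)) masks$wm <- wm_mask
  perf <- perfusion_maps(rs, aif_s, vof,
                         masks = if (length(masks)) masks else NULL,
                         constants = constants)

  gw <- NA_real_
  tissue_summary <- NULL
  if (!is.null(gm_mask) && !is.null(wm_mask)) {
    sel <- function(m) as.logical(m)[mask_idx(ts$mask)]
    cnr_gm <- mean(cn[sel(gm_mask)], na.rm = TRUE)
    cnr_wm <- mean(cn[sel(wm_mask)], na.rm = TRUE)
    gw <- gw_contrast(cnr_gm, cnr_wm)
    tissue_summary <- data.frame(
      region = c("gm", "wm"),
      dS = c(mean(ds$dS[sel(gm_mask)]), mean(ds$dS[sel(wm_mask)])),
      CNR = c(cnr_gm, cnr_wm))
  }

  structure(list(
    bolus_average = b,
    dS = map_from_masked(ds$dS, ts$mask),
    dS_sign = map_from_masked(ds$sign, ts$mask),
    CNR = map_from_masked(cn, ts$mask),
    eps_t = map_from_masked(b$eps_t, ts$mask),
    relax = rs, aif = aif, vof = vof, aif_scaled = aif_s,
    delay = dm, perfusion = perf, masks = masks,
    gw_contrast = gw, tissue_summary = tissue_summary,
    config = config, protocol = protocol,
    field_strength = ts$field_strength, TR = ts$TR, TE = ts$TE
  ), class = "bhdsc")
}

#' @export
print.bhdsc <- function(x, ...) {
  cat(sprintf("Breath-hold DSC fit (%g T, TR %g s, TE %g ms)\n",
              x$field_strength, x$TR, 1000 * x$TE))
  cat(sprintf("AIF: %d voxels, integral %+.3g | VOF: %d voxels, integral %+.3g\n",
              length(x$aif$voxels), x$aif$integral,
              length(x$vof$voxels), x$vof$integral))
  cat(sprintf("scaling ratio %.3g; deconvolution window %.1f-%.1f s\n",
              x$aif_scaled$scale_ratio, x$aif$bolus_start, x$vof$bolus_end))
  if (!is.na(x$gw_contrast)) {
    cat(sprintf("GM-to-WM CNR contrast: %.2f\n", x$gw_contrast))
  }
  invisible(x)
}

#' Summary of a bhDSC fit
#'
#' Per-region means, standard deviations and coefficients of variation of
#' dS, CNR, CBV, CBF and MTT over the valid voxels.
#'
#' @param object A [bhdsc()] fit.
#' @param ... Unused.
#' @return Data frame of region statistics (invisible NULL when no tissue
#'   masks were supplied).
#' @export
summary.bhdsc <- function(object, ...) {
  ps <- object$perfusion$summary
  out <- list(tissue = object$tissue_summary, perfusion = ps,
              gw_contrast = object$gw_contrast)
  class(out) <- "summary.bhdsc"
  out
}

#' @export
print.summary.bhdsc <- function(x, ...) {
  if (!is.null(x$tissue)) {
    cat("Signal change and contrast-to-noise:\n")
    print(x$tissue, row.names = FALSE, digits = 3)
    cat(sprintf("GM-to-WM contrast: %.2f\n\n", x$gw_contrast))
  }
  if (!is.null(x$perfusion)) {
    cat("Perfusion (valid voxels):\n")
    print(x$perfusion, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Region-mean perfusion coefficients
#'
#' @param object A [bhdsc()] fit with tissue masks.
#' @param ... Unused.
#' @return Named numeric vector of region-mean CBV / CBF / MTT values.
#' @export
coef.bhdsc <- function(object, ...) {
  ps <- object$perfusion$summary
  if (is.null(ps)) return(numeric(0))
  stats::setNames(ps$mean, paste(ps$parameter, ps$region, sep = "_"))
}

#' Map montage of a bhDSC fit
#'
#' Displays an axial slice of the CBV, CBF, MTT and delay maps.
#'
#' @param x A [bhdsc()] fit.
#' @param slice Axial slice index (default: middle slice).
#' @param ... Passed to [graphics::image()].
#' @export
plot.bhdsc <- function(x, slice = NULL, ...) {
  p <- x$perfusion
  slice <- slice %||% max(1L, dim(p$CBV)[3] %/% 2L)
  maps <- list(CBV = p$CBV, CBF = p$CBF, MTT = p$MTT,
               `delay (s)` = x$delay$delay)
  op <- graphics::par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (nm in names(maps)) {
    m <- maps[[nm]][, , slice]
    m[!is.finite(m)] <- NA
    graphics::image(m, main = nm, axes = FALSE,
                    col = grDevices::hcl.colors(64, "viridis"), ...)
  }
  invisible(x)
}
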