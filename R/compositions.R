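#' Voxel compartment composition
#'
#' Defines the volume-fraction makeup of a simulated voxel: extravascular
#' tissue, CSF, and blood split into arterial, capillary and venous pools
#' with their baseline oxygenation fractions. Arterial blood is near
#' saturation (Y = 0.98); capillary and venous baselines sit in the 0.60-0.80
#' tissue oxygenation band.
#'
#' Large-vessel voxels carry large-vessel hematocrit in the extravascular
#' dephasing term; microvascular (tissue) classes carry the reduced
#' capillary hematocrit (rho / k_H of the large-vessel value), which is what
#' the standard hematocrit correction factor compensates for.
#'
#' @param f_tissue,f_csf Extravascular tissue and CSF volume fractions.
#' @param f_art,f_cap,f_ven Blood volume fractions of the arterial, capillary
#'   and venous pools. All five fractions must be non-negative and sum to 1.
#' @param Y_art,Y_cap,Y_ven Baseline oxygenation fraction per pool.
#' @param vessel_class One of \code{"arterial"}, \code{"capillary"},
#'   \code{"venous"} (microvascular tissue classes) or \code{"large_vessel"}.
#' @param perturber Optional effective vascular perturber volume fraction for
#'   the extravascular dephasing term when it differs from the in-voxel blood
#'   volume; used by the venous reference voxel which is normalised to unit
#'   blood volume (the standard assumption that the venous output function
#'   samples 100\% blood). Default \code{NULL}: perturber = blood fractions.
#' @param label Free-text label.
#' @return An object of class \code{voxel_composition}.
#' @seealso [composition_preset()]
#' @export
voxel_composition <- function(f_tissue, f_csf, f_art, f_cap, f_ven,
                              Y_art = 0.98, Y_cap = 0.75, Y_ven = 0.65,
                              vessel_class = c("capillary", "venous",
                                               "arterial", "large_vessel"),
                              perturber = NULL, label = NULL) {
  vessel_class <- match.arg(vessel_class)
  f <- c(tissue = f_tissue, csf = f_csf, art = f_art, cap = f_cap, ven = f_ven)
  if (any(f < -1e-12)) stop("invalid composition: negative volume fraction")
  if (abs(sum(f) - 1) > 1e-8) {
    stop(sprintf("invalid composition: fractions sum to %.6f, not 1", sum(f)))
  }
  Y <- c(art = Y_art, cap = Y_cap, ven = Y_ven)
  if (any(Y < 0 | Y > 1)) stop("oxygenation fractions must lie in [0, 1]")
  structure(list(
    f_tissue = f_tissue, f_csf = f_csf,
    f_blood = c(art = f_art, cap = f_cap, ven = f_ven),
    Y_baseline = Y, vessel_class = vessel_class,
    perturber = perturber,
    label = label %||% vessel_class
  ), class = "voxel_composition")
}

#' Canonical voxel composition presets
#'
#' Named stand-in compositions for the simulation experiments:
#' \describe{
#'   \item{capillary}{Tissue voxel, capillary-weighted blood pool (gray or
#'     white matter); blood split 0/70/30 arterial/capillary/venous - the
#'     parenchymal signal is carried by the exchanging vasculature.}
#'   \item{venous}{Venous-dominated tissue voxel; blood split 0/30/70.}
#'   \item{arterial}{Arteriole-weighted tissue voxel; blood split 8/62/30
#'     (the small arterial fraction is tracer-silent, as arterial blood is
#'     near saturation).}
#'   \item{large_artery_csf}{Voxel containing a large artery adjacent to CSF
#'     (30\% arterial blood, 40\% CSF) - the vasodilation-only AIF voxel.}
#'   \item{large_vein_csf}{Voxel containing a large vein adjacent to CSF.}
#'   \item{vof_reference}{Venous reference voxel: extravascular spins fully
#'     coupled to the draining-vein susceptibility, normalised to unit
#'     effective blood volume, so that the measured venous output function
#'     represents a 100\%-blood voxel.}
#' }
#'
#' @param name Preset name.
#' @param f_blood Total blood volume fraction for the three tissue presets
#'   (replaces the default 0.04); ignored for the large-vessel presets.
#' @param f_csf CSF fraction for the tissue presets (default 0: parenchymal
#'   voxels as retained by partial-volume-thresholded tissue masks carry no
#'   CSF). Set positive to study the CSF-inclusive variant, in which blood
#'   displaces CSF before tissue and the vasodilation dip is stronger.
#' @return A [voxel_composition()].
#' @examples
#' composition_preset("venous", f_blood = 0.04)
#' @export
composition_preset <- function(name = c("capillary", "venous", "arterial",
                                        "large_artery_csf", "large_vein_csf",
                                        "vof_reference"),
                               f_blood = 0.04, f_csf = 0) {
  name <- match.arg(name)
  tissue_preset <- function(split, class) {
    fb <- f_blood * split
    voxel_composition(
      f_tissue = 1 - f_blood - f_csf, f_csf = f_csf,
      f_art = fb[1], f_cap = fb[2], f_ven = fb[3],
      vessel_class = class, label = name)
  }
  switch(name,
    capillary = tissue_preset(c(0.00, 0.70, 0.30), "capillary"),
    venous    = tissue_preset(c(0.00, 0.30, 0.70), "venous"),
    arterial  = tissue_preset(c(0.08, 0.62, 0.30), "arterial"),
    large_artery_csf = voxel_composition(
      f_tissue = 0.30, f_csf = 0.40, f_art = 0.30, f_cap = 0, f_ven = 0,
      vessel_class = "large_vessel", label = name),
    large_vein_csf = voxel_composition(
      f_tissue = 0.30, f_csf = 0.40, f_art = 0, f_cap = 0, f_ven = 0.30,
      vessel_class = "large_vessel", label = name),
    vof_reference = voxel_composition(
      f_tissue = 1, f_csf = 0, f_art = 0, f_cap = 0, f_ven = 0,
      vessel_class = "large_vessel",
      perturber = c(art = 0, cap = 0, ven = 1),
      label = name)
  )
}

#' @export
print.voxel_composition <- function(x, ...) {
  cat(sprintf("Voxel composition '%s' (%s):\n", x$label, x$vessel_class))
  cat(sprintf("  tissue %.3f | CSF %.3f | blood art/cap/ven %.3f/%.3f/%.3f\n",
              x$f_tissue, x$f_csf, x$f_blood["art"], x$f_blood["cap"],
              x$f_blood["ven"]))
  cat(sprintf("  baseline Y art/cap/ven: %.2f/%.2f/%.2f\n",
              x$Y_baseline["art"], x$Y_baseline["cap"], x$Y_baseline["ven"]))
  if (!is.null(x$perturber))
    cat(sprintf("  perturber volume override: %.2f\n", sum(x$perturber)))
  invisible(x)
}
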