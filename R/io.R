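#' Read a 4D time series from NIfTI with a JSON sidecar
#'
#' @param image Path to a NIfTI-1 4D image.
#' @param sidecar Path to a JSON sidecar holding \code{TR}, \code{TE}
#'   (seconds) and \code{field_strength} (tesla); when absent, TR is taken
#'   from the NIfTI header and TE/field must be given.
#' @param TR,TE,field_strength Metadata overrides.
#' @param mask Optional path to a NIfTI brain mask.
#' @return A [bhdsc_ts()].
#' @export
read_timeseries_nifti <- function(image, sidecar = NULL, TR = NULL, TE = NULL,
                                  field_strength = NULL, mask = NULL) {
  img <- RNifti::readNifti(image)
  meta <- list()
  if (!is.null(sidecar)) meta <- jsonlite::fromJSON(sidecar)
  TR <- TR %||% meta$TR %||% RNifti::pixdim(img)[4]
  TE <- TE %||% meta$TE
  field_strength <- field_strength %||% meta$field_strength %||% NA_real_
  if (is.null(TE)) stop("TE not found in sidecar and not supplied")
  m <- if (!is.null(mask)) as.array(RNifti::readNifti(mask)) > 0 else NULL
  bhdsc_ts(as.array(img), TR = TR, TE = TE,
           field_strength = field_strength, mask = m)
}

#' Write perfusion maps and summaries
#'
#' Writes \code{cbv.nii.gz}, \code{cbf.nii.gz}, \code{mtt.nii.gz},
#' \code{valid_mask.nii.gz} and \code{summary.tsv} into a directory.
#'
#' @param perf A \code{perfusion_result}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_perfusion_maps <- function(perf, dir) {
  stopifnot(inherits(perf, "perfusion_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cbv = file.path(dir, "cbv.nii.gz"),
             cbf = file.path(dir, "cbf.nii.gz"),
             mtt = file.path(dir, "mtt.nii.gz"),
             valid = file.path(dir, "valid_mask.nii.gz"))
  RNifti::writeNifti(perf$CBV, paths["cbv"])
  RNifti::writeNifti(perf$CBF, paths["cbf"])
  RNifti::writeNifti(perf$MTT, paths["mtt"])
  RNifti::writeNifti(perf$valid_mask * 1L, paths["valid"])
  if (!is.null(perf$summary)) {
    utils::write.table(perf$summary, file.path(dir, "summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, summary = file.path(dir, "summary.tsv"))
  }
  invisible(paths)
}

#' Write an input function as TSV plus JSON metadata
#'
#' @param inf An \code{input_function}.
#' @param path Output TSV path (columns \code{time_s}, \code{dR2s});
#'   metadata (kind, voxel count, bolus edges, integral, scaling) is written
#'   alongside as \code{<path>.json}.
#' @return Invisibly, the TSV path.
#' @export
write_input_function <- function(inf, path) {
  stopifnot(inherits(inf, "input_function"))
  utils::write.table(
    data.frame(time_s = inf$time, dR2s = inf$timecourse),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(kind = inf$kind, n_voxels = length(inf$voxels),
         bolus_start = inf$bolus_start, bolus_end = inf$bolus_end,
         integral = inf$integral, scaled = inf$scaled,
         scale_ratio = inf$scale_ratio),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a synthetic phantom to NIfTI with sidecar and ground truth
#'
#' Writes the 4D image (\code{phantom.nii.gz}), a JSON sidecar (TR, TE,
#' field strength, seed, noise sd), integer region labels
#' (\code{regions.nii.gz}) and the ground-truth maps
#' (\code{truth_cbv/cbf/mtt/delay.nii.gz}).
#'
#' @param phantom A [generate_phantom()] result.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_phantom_nifti <- function(phantom, dir) {
  stopifnot(inherits(phantom, "bhdsc_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(phantom$ts$data, file.path(dir, "phantom.nii.gz"))
  jsonlite::write_json(
    list(TR = phantom$ts$TR, TE = phantom$ts$TE,
         field_strength = phantom$ts$field_strength,
         seed = phantom$seed, noise_sd = phantom$noise_sd),
    file.path(dir, "phantom.json"), auto_unbox = TRUE, digits = NA)
  RNifti::writeNifti(phantom$truth$region, file.path(dir, "regions.nii.gz"))
  for (nm in c("cbv", "cbf", "mtt", "delay")) {
    m <- phantom$truth[[nm]]
    m[is.na(m)] <- -1
    RNifti::writeNifti(m, file.path(dir, sprintf("truth_%s.nii.gz", nm)))
  }
  invisible(dir)
}
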