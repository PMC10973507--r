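#' Pipeline configuration
#'
#' Collects every tunable constant of the bhDSC analysis with defaults at
#' the standard values: 72 s bolus window, first 8 boluses averaged,
#' length-5 Gaussian temporal kernel, 99th / 99.9th percentile AIF / VOF
#' selection, 20\% SVD noise threshold, hematocrit correction 1.45, brain
#' density 1.05, and the 0.5 s / 8 s delay grid.
#'
#' @param ... Named overrides of the defaults.
#' @return Validated list of class \code{bhdsc_config}.
#' @examples
#' cfg <- bhdsc_config(n_use = 6)
#' @export
bhdsc_config <- function(...) {
  cfg <- list(
    window_s = 72,
    n_use = 8,
    kernel_length = 5,
    kernel_sigma = 1,
    baseline_n = "twenty",
    aif_percentile = 0.99,
    vof_percentile = 0.999,
    aif_max_delay = 0.5,
    vof_delay_window = c(1.5, 4.0),
    k_H = 1.45,
    rho = 1.05,
    svd_threshold = 0.20,
    delay_step = 0.5,
    delay_max = 8
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "bhdsc_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$window_s > 0, cfg$n_use >= 1, cfg$kernel_length >= 3,
            cfg$kernel_sigma > 0)
  if (!cfg$baseline_n %in% c("twenty", "ten")) {
    stop("baseline_n must be 'twenty' or 'ten'")
  }
  if (cfg$svd_threshold < 0 || cfg$svd_threshold >= 1) {
    stop("svd_threshold must lie in [0, 1), got ", cfg$svd_threshold)
  }
  if (cfg$aif_percentile <= 0 || cfg$aif_percentile >= 1 ||
      cfg$vof_percentile <= 0 || cfg$vof_percentile >= 1) {
    stop("selection percentiles must lie in (0, 1)")
  }
  stopifnot(cfg$k_H > 0, cfg$rho > 0, cfg$delay_step > 0,
            cfg$delay_max >= cfg$delay_step)
  invisible(cfg)
}
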