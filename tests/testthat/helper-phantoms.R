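## Phantoms are deterministic and reused across test files.
.phantom_cache <- new.env(parent = emptyenv())

test_phantom <- function(name) {
  if (!is.null(.phantom_cache[[name]])) return(.phantom_cache[[name]])
  ph <- switch(name,
    ## realistic study conditions: 9 blocks, mid-typical vasodilation, noise
    noisy = generate_phantom(seed = 42),
    ## larger grid for distributional checks (CNR scaling)
    noisy_cnr = generate_phantom(seed = 42,
                                 layout = phantom_layout(dims = c(14, 14, 3))),
    ## noise-free, vasodilation-free, shift-only: the recovery construction
    clean = generate_phantom(noise_sd = 0, seed = 7,
                             layout = phantom_layout(dcbv_tissue = 0),
                             dispersion = FALSE),
    ## noise-free with dispersion and vasodilation (default dynamics)
    clean_disp = generate_phantom(noise_sd = 0, seed = 7),
    stop("unknown phantom ", name))
  .phantom_cache[[name]] <- ph
  ph
}

region_masks <- function(ph) bhdsc:::phantom_masks(ph)

## relaxation curves per phantom region, baseline = first 10 volumes
region_curves <- function(ph) {
  m <- bhdsc:::ts_matrix(ph$ts)
  reg <- as.vector(ph$truth$region)
  lapply(stats::setNames(1:4, c("artery", "gm", "wm", "vein")), function(r) {
    s <- m[which(reg == r)[1], ]
    as.numeric(delta_r2star(s, TE = ph$ts$TE, S0 = mean(s[1:10]),
                            time = (seq_along(s) - 1) * ph$ts$TR)$dR2s)
  })
}

## minimal hand-built bolus_average for unit tests of dS / CNR
fake_bolus_average <- function(S0, Smax, eps_t = rep(1, length(S0))) {
  structure(list(window = NULL, time = NULL, S0 = S0, Smax = Smax,
                 eps_t = eps_t, n_boluses_used = 8),
            class = "bolus_average")
}

## minimal input_function for truncation tests
fake_input_function <- function(kind, start, end, tc = NULL, time = NULL) {
  structure(list(kind = kind, voxels = integer(0), timecourse = tc,
                 time = time, bolus_start = start, bolus_end = end,
                 integral = if (!is.null(tc)) bhdsc:::trapz(time, tc) else NA,
                 scaled = FALSE, scale_ratio = NA_real_),
            class = "input_function")
}
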