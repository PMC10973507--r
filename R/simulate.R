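#' Multi-compartment gradient-echo signal for one voxel
#'
#' Computes the GRE signal time course of a voxel as the volume-fraction
#' weighted sum of mono-exponential compartments,
#' \deqn{S(t) = S_0 \sum_i f_i(t)\, e^{-TE\, R_2^{*}{}_i(t)},}
#' with tissue and CSF spins sharing the extravascular dephasing imposed by
#' the deoxygenated blood pools, and intravascular signal following the
#' quadratic oxygenation dependence of [field_params()]. Vasodilation
#' increases the blood fractions and displaces CSF first, then tissue,
#' renormalising the fractions at every time point; an oxygenation rise
#' lowers the relaxation rates. The fine-grid signal is box-car resampled
#' to one sample per TR.
#'
#' @param comp A [voxel_composition()].
#' @param fp A [field_params()].
#' @param dyn A [bolus_dynamics()] on a grid finer than or equal to TR.
#' @param S0 Baseline equilibrium signal scale.
#' @return List with \code{time} (volume times, s), \code{signal}
#'   (one value per TR), \code{time_fine}, \code{signal_fine}, \code{TR},
#'   \code{TE}.
#' @examples
#' fp <- field_params(7)
#' dyn <- bolus_dynamics(bh_protocol(n_blocks = 1))
#' s <- simulate_voxel_signal(composition_preset("capillary"), fp, dyn)
#' @export
simulate_voxel_signal <- function(comp, fp, dyn, S0 = 1) {
  stopifnot(inherits(comp, "voxel_composition"), inherits(fp, "field_params"),
            inherits(dyn, "bolus_dynamics"))
  TE <- fp$TE
  n <- length(dyn$time)

  dcbv <- dyn$dcbv
  fb0 <- comp$f_blood
  fb <- lapply(names(fb0), function(p) fb0[[p]] * (1 + dcbv))
  names(fb) <- names(fb0)
  extra <- sum(fb0) * dcbv                      # total added blood volume
  csf <- comp$f_csf - pmin(extra, comp$f_csf)   # blood displaces CSF first
  tissue <- comp$f_tissue - pmax(extra - comp$f_csf, 0)
  if (any(tissue < -1e-12)) {
    stop("composition-overflow: vasodilation displaces more than the ",
         "available CSF and tissue volume")
  }

  Y <- lapply(names(fb0), function(p) {
    y <- comp$Y_baseline[[p]] + dyn$dY[[p]]
    if (any(y < 0 | y > 1)) {
      stop("oxygenation out of [0, 1] for pool '", p, "' during the bolus")
    }
    y
  })
  names(Y) <- names(fb0)

  ## perturber volume for the extravascular dephasing term; the venous
  ## reference voxel overrides this with unit blood volume
  pert0 <- comp$perturber %||% fb0
  pert <- lapply(names(fb0), function(p) pert0[[p]] * (1 + dcbv))
  names(pert) <- names(fb0)
  h <- if (comp$vessel_class == "large_vessel") 1 else hct_small_rel()
  r2ev <- fp$r_ev * h *
    Reduce(`+`, lapply(names(fb0), function(p) pert[[p]] * (1 - Y[[p]])))

  s <- tissue * exp(-TE * (fp$R2s_tissue_base + r2ev)) +
    csf * exp(-TE * (fp$R2s_csf_base + r2ev))
  for (p in names(fb0)) {
    s <- s + fb[[p]] * exp(-TE * fp$iv_r2star(Y[[p]]))
  }
  s <- S0 * s
  if (any(s < 0)) stop("negative signal produced; check parameters")

  per <- as.integer(round(fp$TR / dyn$dt))
  if (abs(per * dyn$dt - fp$TR) > 1e-9) {
    stop("simulation grid dt must divide TR")
  }
  nvol <- n %/% per
  sv <- colMeans(matrix(s[seq_len(nvol * per)], nrow = per))
  list(time = (seq_len(nvol) - 1) * fp$TR, signal = sv,
       time_fine = dyn$time, signal_fine = s, TR = fp$TR, TE = TE)
}
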