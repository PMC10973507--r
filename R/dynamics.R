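## Default oxygenation bolus amplitudes (absolute change in Y per pool).
## The hypercapnic flow increase raises oxygenation throughout the
## exchanging (capillary and venous) vasculature by the same amount:
## +0.085 on baselines of 0.75 (capillary) and 0.65 (venous) keeps both
## pools inside the 0.60-0.80 tissue oxygenation band throughout the bolus.
## Arterial blood is near saturation and carries no oxygenation change.
DEFAULT_DY <- c(art = 0, cap = 0.085, ven = 0.085)

## Typical relative vasodilation (dCBV/CBV) for a 16 s breath-hold: 4-9%,
## midpoint 6.5%.
DCBV_TYPICAL_RANGE <- c(0.04, 0.09)

#' Breath-hold bolus dynamics for one voxel
#'
#' Builds the oxygenation and vasodilation time courses driven by a paced
#' breath-hold protocol. Each block contributes one smooth, compactly
#' supported raised-cosine pulse starting a lung-to-brain lag after the hold
#' onset; the pulse lasts about 35 s at the tissue for a 16 s hold. The
#' relative vasodilation time course is shape-locked to the oxygenation
#' pulse. Regional delay is a pure shift; dispersion is a causal
#' area-preserving exponential kernel (time constant = mean transit time),
#' so downstream curves are later and broader but carry the same integral.
#'
#' @param protocol A [bh_protocol()].
#' @param onset_delay Lung-to-brain lag in seconds (default 12, within the
#'   physiological 10-15 s range).
#' @param duration Bolus duration at the tissue in seconds; default
#'   \code{hold_s + 19} (35 s for the 16 s hold).
#' @param dY Named numeric: peak oxygenation increase per blood pool
#'   (\code{art}, \code{cap}, \code{ven}).
#' @param dcbv_rel Peak relative vasodilation (dCBV/CBV); typical range
#'   0.04-0.09 for a 16 s hold.
#' @param delay Additional regional delay in seconds.
#' @param mtt Optional dispersion time constant in seconds (exponential
#'   transport kernel); \code{NULL} = no dispersion.
#' @param dt Internal simulation grid in seconds (default 0.5; box-car
#'   resampled to TR by the signal simulator).
#' @return An object of class \code{bolus_dynamics}: list with \code{time}
#'   (fine grid), \code{pulse} (unit-peak pulse train), \code{dY} (list of
#'   per-pool time courses), \code{dcbv} (relative vasodilation time course)
#'   and the generating parameters.
#' @examples
#' dyn <- bolus_dynamics(bh_protocol(n_blocks = 1))
#' max(dyn$dcbv)  # 0.065
#' @export
bolus_dynamics <- function(protocol = bh_protocol(), onset_delay = 12,
                           duration = NULL, dY = DEFAULT_DY,
                           dcbv_rel = mean(DCBV_TYPICAL_RANGE),
                           delay = 0, mtt = NULL, dt = 0.5) {
  stopifnot(onset_delay >= 0, delay >= 0, dt > 0, dcbv_rel >= 0)
  duration <- duration %||% (protocol$hold_s + 19)
  if (duration <= 0) stop("bolus duration must be positive")
  tt <- seq(0, protocol$total_s - dt, by = dt)
  pulse <- numeric(length(tt))
  for (b in seq_len(protocol$n_blocks)) {
    t0 <- hold_onset_s(protocol, b) + onset_delay
    u <- tt - t0
    inside <- u >= 0 & u <= duration
    pulse[inside] <- pulse[inside] + 0.5 * (1 - cos(2 * pi * u[inside] / duration))
  }
  if (!is.null(mtt) && mtt > 0) pulse <- disperse(pulse, mtt, dt)
  if (delay > 0) {
    nshift <- as.integer(round(delay / dt))
    pulse <- c(numeric(nshift), pulse)[seq_along(pulse)]
  }
  dY <- dY[c("art", "cap", "ven")]
  structure(list(
    time = tt, dt = dt, pulse = pulse,
    dY = lapply(as.list(dY), function(a) a * pulse),
    dcbv = dcbv_rel * pulse,
    onset_delay = onset_delay, duration = duration, delay = delay,
    mtt = mtt, dY_peak = dY, dcbv_rel = dcbv_rel
  ), class = "bolus_dynamics")
}

## Causal exponential dispersion, kernel area 1 (preserves curve integral).
disperse <- function(x, tau, dt) {
  u <- seq(0, max(8 * tau, dt), by = dt)
  kern <- exp(-u / tau)
  kern <- kern / sum(kern)
  p <- length(kern)
  xx <- c(numeric(p - 1L), x)
  y <- stats::filter(xx, kern, method = "convolution", sides = 1)
  as.numeric(y[p:(p - 1L + length(x))])
}
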