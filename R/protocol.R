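#' Breath-hold block protocol
#'
#' Describes the paced breath-hold paradigm: each block is 10 s of preparation
#' with regular breathing, 16 s of breath-holding and 34 s of regular
#' breathing (60 s total), repeated nine times, followed by a final 80 s
#' baseline. Sampling is one volume per TR.
#'
#' @param prep_s Preparation (regular breathing) duration per block, seconds.
#' @param hold_s Breath-hold duration, seconds.
#' @param recovery_s Post-hold regular breathing duration, seconds.
#' @param n_blocks Number of breath-hold blocks.
#' @param final_baseline_s Trailing baseline after the last block, seconds.
#' @param TR Repetition time, seconds.
#' @return An object of class \code{bh_protocol}: a list with the arguments
#'   plus \code{block_s} (block length) and \code{n_volumes} (total volumes).
#' @examples
#' p <- bh_protocol()
#' p$block_s     # 60
#' p$n_volumes   # 310 at TR = 2 s
#' @export
bh_protocol <- function(prep_s = 10, hold_s = 16, recovery_s = 34,
                        n_blocks = 9, final_baseline_s = 80, TR = 2) {
  stopifnot(prep_s >= 0, hold_s > 0, recovery_s >= 0, n_blocks >= 1, TR > 0)
  block_s <- prep_s + hold_s + recovery_s
  total_s <- n_blocks * block_s + final_baseline_s
  structure(list(
    prep_s = prep_s, hold_s = hold_s, recovery_s = recovery_s,
    n_blocks = n_blocks, final_baseline_s = final_baseline_s, TR = TR,
    block_s = block_s, total_s = total_s,
    n_volumes = as.integer(round(total_s / TR))
  ), class = "bh_protocol")
}

#' @export
print.bh_protocol <- function(x, ...) {
  cat(sprintf(
    "Breath-hold protocol: %d blocks of %gs prep + %gs hold + %gs rest (%gs), final baseline %gs\n",
    x$n_blocks, x$prep_s, x$hold_s, x$recovery_s, x$block_s, x$final_baseline_s))
  cat(sprintf("TR = %gs, %d volumes (%gs total)\n", x$TR, x$n_volumes, x$total_s))
  invisible(x)
}

## Volume index (1-based) at which block b starts.
block_start_index <- function(protocol, b) {
  as.integer(round((b - 1) * protocol$block_s / protocol$TR)) + 1L
}

## Time (s) at which the hold of block b begins.
hold_onset_s <- function(protocol, b) {
  (b - 1) * protocol$block_s + protocol$prep_s
}
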