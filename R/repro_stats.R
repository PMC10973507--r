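#' CNR as a function of boluses averaged
#'
#' Averages the first n boluses for each n in \code{n_grid}, computes the
#' mean in-mask CNR, and fits the radical model \eqn{a\sqrt{b\,n}+c}
#' (the square-root-of-averages law). The model is non-identifiable in
#' (a, b) jointly, so it is fitted as a linear model in \eqn{\sqrt{n}} and
#' reported with b = 1.
#'
#' @param ts A [bhdsc_ts()] (after [detrend_and_smooth()]).
#' @param protocol A [bh_protocol()].
#' @param mask Logical 3D array over which the mean CNR is taken.
#' @param n_grid Bolus counts to evaluate (default 1:8).
#' @return Object of class \code{cnr_scaling}: list with \code{table}
#'   (data frame n, cnr), \code{fit} (named a, b, c or NULL when the grid is
#'   too small to fit) and \code{r_squared}.
#' @export
cnr_vs_boluses <- function(ts, protocol, mask, n_grid = 1:8) {
  stopifnot(max(n_grid) <= protocol$n_blocks)
  vox <- as.logical(mask)[mask_idx(ts$mask)]
  cnr_n <- vapply(n_grid, function(n) {
    b <- average_boluses(ts, protocol, n_use = n)
    x <- cnr(b)[vox]
    mean(x, na.rm = TRUE)
  }, numeric(1))
  tab <- data.frame(n = n_grid, cnr = cnr_n)
  rf <- radical_fit(tab$n, tab$cnr)
  structure(list(table = tab, fit = rf$fit, r_squared = rf$r_squared),
            class = "cnr_scaling")
}

#' Fit the radical model a*sqrt(b*x)+c
#'
#' Least-squares fit of the square-root-of-averages law. Since (a, b) are
#' jointly non-identifiable, the fit is linear in \eqn{\sqrt{x}} and b is
#' reported as 1. Fewer than three points make the fit underdetermined and
#' only the data are returned, with a warning.
#'
#' @param x,y Data to fit.
#' @return List with \code{fit} (named a, b, c; or NULL) and
#'   \code{r_squared}.
#' @examples
#' radical_fit(1:8, 2 * sqrt(1:8))   # a*sqrt(b) = 2, c = 0, R^2 = 1
#' @export
radical_fit <- function(x, y) {
  if (length(x) < 3L) {
    warning("fewer than 3 points: radical fit is underdetermined; ",
            "returning the raw data only")
    return(list(fit = NULL, r_squared = NA_real_))
  }
  lmfit <- stats::lm(y ~ sqrt(x))
  r2 <- 1 - sum(stats::residuals(lmfit)^2) / sum((y - mean(y))^2)
  list(fit = c(a = unname(stats::coef(lmfit)[2]), b = 1,
               c = unname(stats::coef(lmfit)[1])),
       r_squared = r2)
}

#' @export
print.cnr_scaling <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 3)
  if (!is.null(x$fit)) {
    cat(sprintf("radical fit a*sqrt(b*n)+c: a = %.3f, b = %g, c = %.3f, R^2 = %.4f\n",
                x$fit["a"], x$fit["b"], x$fit["c"], x$r_squared))
  }
  invisible(x)
}

#' One-way random-effects intraclass correlation
#'
#' ICC(1,1): with between-subject mean square MSB and within-subject mean
#' square MSW over k repeated measurements,
#' \deqn{ICC = \frac{MSB - MSW}{MSB + (k-1)\,MSW},}
#' the share of total variance attributable to between-subject variance.
#' The literal "proportion of within-subject variance to total variance"
#' reading is available via \code{literal = TRUE}.
#'
#' @param values Numeric matrix, subjects x repeated measurements.
#' @param literal Return within/total instead of the standard estimator.
#' @return The ICC (in \eqn{[-1/(k-1), 1]} for the standard estimator).
#' @export
icc_oneway <- function(values, literal = FALSE) {
  values <- as.matrix(values)
  ns <- nrow(values)
  k <- ncol(values)
  if (ns < 2L) stop("at least two subjects are required for an ICC")
  subj <- factor(rep(seq_len(ns), k))
  y <- as.vector(values)
  ms <- summary(stats::aov(y ~ subj))[[1]][["Mean Sq"]]
  msb <- ms[1]
  msw <- ms[2]
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  if (!literal) return(icc)
  sig_b <- max((msb - msw) / k, 0)
  msw / (sig_b + msw)
}

#' Bootstrap bolus-combination repeatability of GM CBV
#'
#' Enumerates every choose-k combination of the available boluses
#' (4 of 8 gives exactly 70 combinations), evaluates a pipeline handle that
#' maps a bolus subset to a gray-matter CBV value for each subject, and
#' returns the one-way intraclass correlation of the resulting
#' subjects x combinations panel.
#'
#' @param subjects A list with one element per subject; each element is
#'   passed to \code{pipeline} together with a bolus-index vector.
#' @param pipeline Function \code{(subject_data, bolus_indices) -> numeric}
#'   returning the GM CBV for that subset (e.g. the full bhDSC pipeline on
#'   the subset-averaged data).
#' @param n_boluses Total boluses per subject (default 8).
#' @param k_choose Boluses per combination (default 4).
#' @param literal Passed to [icc_oneway()].
#' @return Object of class \code{bolus_bootstrap}: list with \code{icc},
#'   \code{values} (subjects x combinations), \code{combinations}
#'   (k x n_combinations matrix).
#' @export
bolus_bootstrap_icc <- function(subjects, pipeline, n_boluses = 8,
                                k_choose = 4, literal = FALSE) {
  if (length(subjects) < 2L) stop("at least two subjects are required")
  comb <- utils::combn(n_boluses, k_choose)
  vals <- t(vapply(subjects, function(sd) {
    apply(comb, 2, function(ix) pipeline(sd, ix))
  }, numeric(ncol(comb))))
  structure(list(icc = icc_oneway(vals, literal = literal),
                 values = vals, combinations = comb),
            class = "bolus_bootstrap")
}

#' @export
print.bolus_bootstrap <- function(x, ...) {
  cat(sprintf("Bolus bootstrap: %d subjects x %d combinations, ICC = %.3f\n",
              nrow(x$values), ncol(x$values), x$icc))
  invisible(x)
}
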