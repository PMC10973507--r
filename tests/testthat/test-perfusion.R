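## well-conditioned test AIF (nonzero at onset) on a uniform grid
gamma_aif <- function(n = 32, dt = 2) {
  t <- seq_len(n) * dt
  t * exp(-t / 6)
}

test_that("truncation retains exactly the AIF-start to VOF-end samples", {
  time <- seq(0, 100, by = 2)
  x <- matrix(stats::rnorm(3 * length(time)), 3)
  aif <- fake_input_function("AIF", 10, 40)
  aif$timecourse <- seq_along(time)
  vof <- fake_input_function("VOF", 20, 60)
  vof$timecourse <- seq_along(time)
  tw <- truncate_window(x, time, aif, vof)
  expect_identical(ncol(tw$x), 26L)  # 10..60 s inclusive at TR 2
  expect_identical(range(tw$time), c(10, 60))
  ## identity when the window spans the full series
  aif2 <- fake_input_function("AIF", 0, 100); aif2$timecourse <- time
  vof2 <- fake_input_function("VOF", 0, 100); vof2$timecourse <- time
  expect_identical(truncate_window(x, time, aif2, vof2)$x, x)
  ## inverted window
  expect_error(truncate_window(x, time, fake_input_function("AIF", 50, 60),
                               fake_input_function("VOF", 10, 20)),
               "inverted")
})

test_that("the truncated window keeps essentially all of the tissue bolus", {
  cv <- simulate_bh_curves(composition_preset("venous", f_blood = 0.04))
  aif <- bhdsc:::new_input_function("AIF", integer(0), cv$aif, cv$time)
  vof <- bhdsc:::new_input_function("VOF", integer(0), cv$vof, cv$time)
  tw <- truncate_window(cv$tissue, cv$time, scale_aif(aif, vof), vof)
  full <- abs(bhdsc:::trapz(cv$time, cv$tissue))
  inside <- abs(bhdsc:::trapz(tw$time, as.numeric(tw$x)))
  ## the dispersed exponential tail past the VOF bolus end carries < 3%,
  ## and the matching VOF tail loss cancels in the CBV integral ratio
  expect_gt(inside / full, 0.97)
})

test_that("the convolution matrix is the rectangle-rule Toeplitz operator", {
  dt <- 2
  ## a unit impulse at t0 gives dt times the identity
  A1 <- build_convolution_matrix(c(1, 0, 0, 0), dt)
  expect_equal(A1, dt * diag(4))
  ## general Toeplitz structure A[i, j] = dt * a[i - j + 1], j <= i
  a <- c(3, 1, 4, 1, 5)
  A <- build_convolution_matrix(a, dt)
  for (i in 1:5) for (j in 1:5) {
    expect_identical(A[i, j], if (j <= i) dt * a[i - j + 1] else 0)
  }
  ## A applied to a constant residue is dt * cumsum(AIF) * k
  aif <- gamma_aif(16)
  A2 <- build_convolution_matrix(aif, dt)
  expect_equal(as.numeric(A2 %*% rep(3, 16)), 3 * dt * cumsum(aif))
  expect_error(build_convolution_matrix(aif, c(1, 2, 4)), "non-uniform")
})

test_that("forward convolution then deconvolution is consistent with a direct oracle", {
  dt <- 2
  n <- 32
  aif <- gamma_aif(n, dt)
  t <- seq_len(n) * dt
  k_true <- 0.01 * exp(-t / 4)
  ## independent oracle: direct double-sum discrete convolution
  c_oracle <- vapply(seq_len(n), function(i)
    dt * sum(aif[seq_len(i)] * k_true[i:1]), numeric(1))
  A <- build_convolution_matrix(aif, dt)
  expect_equal(as.numeric(A %*% k_true), c_oracle, tolerance = 1e-12)

  ## threshold 0: SVD inverse matches the triangular solve and the truth
  k_svd <- svd_deconvolve(c_oracle, A, kinetic_constants(svd_threshold = 0))
  k_tri <- as.numeric(forwardsolve(A, c_oracle))
  expect_lt(max(abs(k_svd - k_tri)) / max(abs(k_tri)), 1e-8)
  expect_lt(max(abs(k_svd - k_true)) / max(abs(k_true)), 1e-8)
})

test_that("deconvolving the AIF against itself returns a discrete delta", {
  dt <- 2
  aif <- gamma_aif(24, dt)
  A <- build_convolution_matrix(aif, dt)
  k <- svd_deconvolve(aif, A, kinetic_constants(svd_threshold = 0))
  expect_equal(k[1], 1 / dt, tolerance = 1e-8)
  expect_lt(max(abs(k[-1])), 1e-8)
})

test_that("the 20% threshold under a long bolus underestimates peak flow", {
  cv <- simulate_bh_curves(composition_preset("capillary", f_blood = 0.04),
                           dcbv_tissue = 0, mtt_true = 4)
  rec <- bhdsc:::recover_from_curves(cv)
  cbf_true <- 0.04 / 4
  expect_lt(rec$cbf, cbf_true)
  expect_gt(rec$cbf, 0)
})

test_that("CBV follows the hematocrit/density-scaled integral ratio", {
  t <- seq(0, 60, by = 2)
  aif <- sin(pi * t / 60)^2 + 0.05
  expect_equal(compute_cbv(aif, aif, t), 1.45 / 1.05, tolerance = 1e-12)
  expect_equal(compute_cbv(0.04 * aif, aif, t), 0.04 * 1.45 / 1.05,
               tolerance = 1e-12)
  ## opposite-sign tissue integral gives a negative CBV (flagged, not valid)
  cbv_neg <- compute_cbv(-aif, aif, t)
  expect_lt(cbv_neg, 0)
  k <- rep(1, length(t))
  fm <- compute_cbf_mtt(k, cbv_neg)
  expect_false(fm$valid[1])
})

test_that("a delta residue gives the closed-form CBF and MTT", {
  dt <- 2
  k <- c(1 / dt, rep(0, 9))
  fm <- compute_cbf_mtt(k, cbv = 1.45 / 1.05)
  expect_equal(fm$CBF[1], (1.45 / 1.05) / dt)
  expect_equal(fm$MTT[1], dt)
  expect_false(compute_cbf_mtt(rep(-1, 5), cbv = 1)$valid[1])
})

test_that("longer boluses inflate the calculated MTT", {
  mtts <- vapply(c(5, 35), function(dur) {
    cv <- simulate_bh_curves(composition_preset("capillary", f_blood = 0.04),
                             dcbv_tissue = 0, mtt_true = 4, duration = dur)
    bhdsc:::recover_from_curves(cv)$mtt
  }, numeric(1))
  expect_gt(mtts[2], mtts[1])
  ## the short-bolus estimate stays within 50% of the 4 s truth
  expect_lt(abs(mtts[1] - 4) / 4, 0.5)
})

test_that("noise-free parameter recovery: CBV within 10% over 2-8% blood volume", {
  tab <- vasodilation_bias_experiment(cbv_grid = c(0.02, 0.04, 0.08),
                                      dcbv_grid = 0)
  expect_true(all(abs(tab$pct_error) < 10))
  expect_false(any(tab$flagged))
})

test_that("perfusion maps recover the constructed GM/WM blood-volume ratio", {
  ph <- test_phantom("clean")
  m <- region_masks(ph)
  fit <- bhdsc(ph$ts, m$artery, m$vein, gm_mask = m$gm, wm_mask = m$wm,
               protocol = ph$protocol)
  cf <- coef(fit)
  expect_equal(unname(cf["CBV_gm"] / cf["CBV_wm"]), 2, tolerance = 0.05)
  expect_equal(unname(cf["CBV_gm"]), 0.04, tolerance = 0.10)
  expect_equal(unname(cf["CBV_wm"]), 0.02, tolerance = 0.10)
})

test_that("perfusion is linear in the tissue curves and MTT is scale-free", {
  cv <- simulate_bh_curves(composition_preset("venous", f_blood = 0.04))
  rec1 <- bhdsc:::recover_from_curves(cv)
  cv2 <- cv
  cv2$tissue <- 2.5 * cv$tissue
  rec2 <- bhdsc:::recover_from_curves(cv2)
  expect_equal(rec2$cbv, 2.5 * rec1$cbv, tolerance = 1e-10)
  expect_equal(rec2$cbf, 2.5 * rec1$cbf, tolerance = 1e-10)
  expect_equal(rec2$mtt, rec1$mtt, tolerance = 1e-10)
  ## central volume identity holds exactly within the valid set
  expect_equal(rec1$mtt * rec1$cbf, rec1$cbv, tolerance = 1e-12)
})

test_that("all-zero tissue gives an empty validity mask with a warning", {
  t <- seq(0, 60, by = 2)
  n <- length(t)
  pulse <- sin(pi * pmin(pmax(t - 6, 0), 40) / 40)^2
  rs <- structure(list(dR2s = matrix(0, 4, n), time = t,
                       AUC = numeric(4), TE = 0.02, S0 = rep(1, 4),
                       mask = array(TRUE, c(4, 1, 1))),
                  class = "relaxation_series")
  aif <- bhdsc:::new_input_function("AIF", integer(0), pulse + 0.01, t)
  vof <- bhdsc:::new_input_function("VOF", integer(0), -2 * pulse - 0.01, t)
  expect_warning(res <- perfusion_maps(rs, aif, vof), "all-zero")
  expect_identical(sum(res$valid_mask), 0L)
})

test_that("invalid kinetic constants are rejected before any computation", {
  expect_error(kinetic_constants(svd_threshold = 1.5), "svd_threshold")
  expect_error(kinetic_constants(k_H = -1), "positive")
  expect_error(bhdsc_config(svd_threshold = 1.5), "svd_threshold")
  expect_error(bhdsc_config(nonsense = 1), "unknown configuration")
})
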