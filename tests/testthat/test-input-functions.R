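## compact relaxation_series over a fully-masked grid
fake_rs <- function(dR2s, time = (seq_len(ncol(dR2s)) - 1) * 2) {
  structure(list(dR2s = dR2s, time = time,
                 AUC = bhdsc:::trapz_rows(time, dR2s), TE = 0.02,
                 S0 = rep(1, nrow(dR2s)),
                 mask = array(TRUE, c(nrow(dR2s), 1, 1))),
            class = "relaxation_series")
}

test_that("tissue mask refinement applies the partial-volume and eps_t range rules", {
  d <- c(10, 10, 1)
  odd <- seq(1, 99, by = 2)
  pve_gm <- array(0.5, d); pve_gm[odd] <- 0.95
  pve_wm <- array(0.5, d); pve_wm[odd + 1] <- 0.95
  eps <- array(seq(0, 1, length.out = 100), d)  # uniform on [0, 1]
  tm <- refine_tissue_masks(pve_gm, pve_wm, eps)
  ## eps_t rule keeps the lowest 10% of the range, combined with PVE > 0.9
  expect_true(all(eps[tm$gm] <= 0.1 + 1e-12))
  expect_true(all(eps[tm$wm] <= 0.1 + 1e-12))
  expect_true(all(pve_gm[tm$gm] > 0.9))
  expect_false(any(tm$gm & tm$wm))
  expect_identical(sum(tm$gm) + sum(tm$wm), sum(eps <= 0.1 + 1e-12))

  ## planted vessel voxels (high eps_t) inside GM are excluded
  eps2 <- array(0.05, d)
  vessels <- c(3, 7, 11)
  eps2[vessels] <- 0.9
  tm2 <- refine_tissue_masks(pve_gm, pve_wm, eps2)
  expect_false(any(which(tm2$gm) %in% vessels))
  expect_identical(sum(tm2$gm), 50L - 3L)
  expect_identical(sum(tm2$wm), 50L)

  ## everything filtered out -> informative error
  expect_error(refine_tissue_masks(array(0.5, d), array(0.5, d), eps),
               "empty tissue mask")
})

test_that("noise-free AIF selection returns exactly the planted artery voxels", {
  ph <- test_phantom("clean_disp")
  m <- region_masks(ph)
  b <- average_boluses(ph$ts, ph$protocol)
  ds <- delta_s(b)
  rs <- delta_r2star(b)
  aif <- select_aif(ds, rs, m$artery)
  expect_setequal(aif$voxels, which(m$artery))
  expect_length(aif$voxels, 18)
  expect_gt(aif$integral, 0)
})

test_that("AIF selection degenerates and caps as specified", {
  set.seed(5)
  dR2s <- matrix(stats::rnorm(80 * 10, 0, 0.01), 80, 10)
  rs <- fake_rs(dR2s)
  ## all-positive dS map -> no candidate error
  ds_pos <- list(dS = runif(80), sign = rep(1, 80))
  expect_error(select_aif(ds_pos, rs, array(TRUE, c(80, 1, 1))),
               "no candidate AIF")
  ## many survivors above a permissive percentile -> top 20 by magnitude
  mag <- seq(1, 80)
  ds_neg <- list(dS = mag, sign = rep(-1, 80))
  aif <- select_aif(ds_neg, rs, array(TRUE, c(80, 1, 1)), percentile = 0.5)
  expect_length(aif$voxels, 20)
  expect_setequal(aif$voxels, 61:80)
  ## selection is invariant to global rescaling of the dS map
  aif3 <- select_aif(list(dS = 3 * mag, sign = rep(-1, 80)), rs,
                     array(TRUE, c(80, 1, 1)), percentile = 0.5)
  expect_setequal(aif3$voxels, aif$voxels)
})

test_that("VOF selection finds the sinus voxels and relaxes the delay window when empty", {
  ph <- test_phantom("clean")
  m <- region_masks(ph)
  b <- average_boluses(ph$ts, ph$protocol)
  ds <- delta_s(b)
  rs <- delta_r2star(b)
  reg <- as.vector(ph$truth$region)[bhdsc:::mask_idx(ph$ts$mask)]
  delay_true <- as.vector(ph$truth$delay)[bhdsc:::mask_idx(ph$ts$mask)]
  vof <- select_vof(ds, rs, m$vein, delay = delay_true, S0 = b$S0)
  expect_true(all(vof$voxels %in% which(m$vein)))
  expect_lt(vof$integral, 0)
  ## vein response dwarfs the GM response
  cur <- region_curves(ph)
  t <- (seq_along(cur$gm) - 1) * ph$ts$TR
  expect_gt(abs(vof$integral), abs(bhdsc:::trapz(t, cur$gm)))

  ## only zero-delay candidates -> progressive relaxation with warnings
  w <- testthat::capture_warnings(
    vof0 <- select_vof(ds, rs, m$vein, delay = rep(0, length(delay_true)),
                       S0 = b$S0))
  expect_true(any(grepl("relaxing", w)))
  expect_s3_class(vof0, "input_function")
})

test_that("VOF scaling follows the integral-ratio definition exactly", {
  t <- seq(0, 60, by = 2)
  pulse <- sin(pi * pmin(pmax(t - 10, 0), 30) / 30)^2
  aif <- bhdsc:::new_input_function("AIF", integer(0), pulse, t)
  ## same integral, same sign -> unchanged
  same <- scale_aif(aif, bhdsc:::new_input_function("VOF", integer(0), pulse, t))
  expect_equal(same$timecourse, aif$timecourse)
  ## constant AIF, VOF integral = -2x AIF integral -> AIF_scaled = -2a
  ca <- fake_input_function("AIF", 0, 60, tc = rep(2, length(t)), time = t)
  cv <- fake_input_function("VOF", 0, 60, tc = rep(-4, length(t)), time = t)
  sc <- scale_aif(ca, cv)
  expect_equal(sc$timecourse, rep(-4, length(t)))
  ## post-condition holds to machine precision for arbitrary inputs
  set.seed(9)
  v2 <- bhdsc:::new_input_function("VOF", integer(0),
                                   -pulse * runif(1, 0.5, 3) - 0.01, t)
  sc2 <- scale_aif(aif, v2)
  expect_identical(sc2$integral - v2$integral, 0)
  expect_true(sc2$scaled)
  ## zero integrals are rejected
  z <- fake_input_function("VOF", 0, 60, tc = rep(0, length(t)), time = t)
  expect_error(scale_aif(aif, z), "zero VOF integral")
  expect_error(scale_aif(z, aif), "zero AIF integral")
})

test_that("after scaling, AIF, tissue and VOF integrals share one sign", {
  ph <- test_phantom("clean_disp")
  m <- region_masks(ph)
  b <- average_boluses(ph$ts, ph$protocol)
  ds <- delta_s(b)
  rs <- delta_r2star(b)
  aif <- select_aif(ds, rs, m$artery)
  vof <- suppressWarnings(select_vof(ds, rs, m$vein, S0 = b$S0))
  sc <- scale_aif(aif, vof)
  gm_auc <- mean(rs$AUC[as.vector(m$gm)[bhdsc:::mask_idx(ph$ts$mask)]])
  expect_true(all(sign(c(sc$integral, vof$integral, gm_auc)) == -1))
})

test_that("the selected AIF reproduces the planted vasodilation time course", {
  ph <- test_phantom("clean_disp")
  m <- region_masks(ph)
  b <- average_boluses(ph$ts, ph$protocol)
  aif <- select_aif(delta_s(b), delta_r2star(b), m$artery)
  ## compare with the generating raised-cosine pulse train over the window
  dyn <- bolus_dynamics(ph$protocol, dcbv_rel = 1)
  pulse_tr <- colMeans(matrix(dyn$pulse, nrow = round(ph$ts$TR / dyn$dt)))
  ## align the pulse to the averaged 72 s window via the same block windows
  big <- which(aif$timecourse > 0.5 * max(aif$timecourse))
  expect_gt(length(big), 3)
  pk_win <- which.max(aif$timecourse)
  pk_pulse <- which.max(pulse_tr[1:40])
  lag <- pk_pulse - pk_win
  idx <- seq_along(aif$timecourse) + lag
  ok <- idx >= 1 & idx <= length(pulse_tr)
  expect_gt(stats::cor(aif$timecourse[ok], pulse_tr[idx[ok]]), 0.99)
})
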