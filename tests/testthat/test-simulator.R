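test_that("a static composition yields a constant signal at S0", {
  fp <- field_params(7)
  dyn <- bolus_dynamics(bh_protocol(n_blocks = 1, final_baseline_s = 40),
                        dY = c(art = 0, cap = 0, ven = 0), dcbv_rel = 0)
  s <- simulate_voxel_signal(composition_preset("capillary"), fp, dyn)
  expect_true(all(abs(s$signal - s$signal[1]) < 1e-12))
  expect_gt(s$signal[1], 0)
})

test_that("signal sign dichotomy: vasodilation dips, oxygenation rises", {
  proto <- bh_protocol(n_blocks = 1, final_baseline_s = 60)
  auc_of <- function(field, comp, dcbv, oxy) {
    fp <- field_params(field)
    dyn <- bolus_dynamics(proto, dcbv_rel = dcbv,
                          dY = if (oxy) bhdsc:::DEFAULT_DY else c(art = 0, cap = 0, ven = 0))
    s <- simulate_voxel_signal(comp, fp, dyn)
    dr <- delta_r2star(s$signal, TE = fp$TE, S0 = s$signal[1], time = s$time)
    dr$AUC
  }
  ## pure vasodilation in a large-vessel voxel: signal down, dR2* AUC > 0 at 7 T
  big <- composition_preset("large_artery_csf")
  expect_gt(auc_of(7, big, 0.065, oxy = FALSE), 0)
  ## pure oxygenation rise: signal up, dR2* AUC < 0 at both fields
  tis <- composition_preset("venous")
  expect_lt(auc_of(7, tis, 0, oxy = TRUE), 0)
  expect_lt(auc_of(3, tis, 0, oxy = TRUE), 0)
})

test_that("matched dynamics give larger relaxation response at 7 T than 3 T", {
  proto <- bh_protocol(n_blocks = 1, final_baseline_s = 60)
  for (preset in c("capillary", "venous", "vof_reference")) {
    auc <- vapply(c(3, 7), function(field) {
      fp <- field_params(field)
      s <- simulate_voxel_signal(composition_preset(preset), fp,
                                 bolus_dynamics(proto, dcbv_rel = 0))
      delta_r2star(s$signal, TE = fp$TE, S0 = s$signal[1], time = s$time)$AUC
    }, numeric(1))
    expect_gt(abs(auc[2]), abs(auc[1]))
  }
})

test_that("intravascular share of the signal change sits in the documented windows", {
  ## 10-40% of the functional signal change at 3 T, 0-5% at 7 T
  comp <- composition_preset("capillary", f_blood = 0.04)
  dY <- bhdsc:::DEFAULT_DY
  pools <- c("art", "cap", "ven")
  share <- function(field) {
    fp <- field_params(field)
    h <- bhdsc:::hct_small_rel()
    iv <- function(shift) sum(vapply(pools, function(p)
      comp$f_blood[p] * exp(-fp$TE * fp$iv_r2star(comp$Y_baseline[p] + shift * dY[p])),
      numeric(1)))
    ev <- function(shift) {
      r2 <- fp$r_ev * h * sum(comp$f_blood * (1 - comp$Y_baseline - shift * dY[pools]))
      comp$f_tissue * exp(-fp$TE * (fp$R2s_tissue_base + r2)) +
        comp$f_csf * exp(-fp$TE * (fp$R2s_csf_base + r2))
    }
    d_iv <- iv(1) - iv(0)
    d_ev <- ev(1) - ev(0)
    100 * d_iv / (d_iv + d_ev)
  }
  expect_gt(share(3), 10)
  expect_lt(share(3), 40)
  expect_gte(share(7), 0)
  expect_lt(share(7), 5)
})

test_that("intravascular relaxation decreases monotonically with oxygenation", {
  for (field in c(3, 7)) {
    fp <- field_params(field)
    y <- seq(0, 1, by = 0.05)
    expect_true(all(diff(fp$iv_r2star(y)) <= 0))
  }
})

test_that("invalid compositions are rejected", {
  expect_error(voxel_composition(0.8, 0.1, 0.2, 0, 0), "sum")
  expect_error(voxel_composition(0.9, -0.1, 0.1, 0.05, 0.05), "negative")
  ## vasodilation displacing more than the available CSF + tissue
  comp <- voxel_composition(0.02, 0.02, 0.96, 0, 0,
                            vessel_class = "large_vessel")
  dyn <- bolus_dynamics(bh_protocol(n_blocks = 1, final_baseline_s = 40),
                        dcbv_rel = 0.1,
                        dY = c(art = 0, cap = 0, ven = 0))
  expect_error(simulate_voxel_signal(comp, field_params(7), dyn),
               "composition-overflow")
})

test_that("phantom carries nine positive tissue boluses and a negative artery response", {
  ph <- test_phantom("clean_disp")
  m <- bhdsc:::ts_matrix(ph$ts)
  reg <- as.vector(ph$truth$region)
  gm <- m[which(reg == 2L)[1], ]
  dev <- gm - stats::median(gm)
  expect_gt(max(dev), 0)
  expect_identical(sum(rle(dev > 0.5 * max(dev))$values), 9L)
  art <- m[which(reg == 1L)[1], ]
  expect_lt(min(art - stats::median(art)), 0)
  expect_lt(abs(max(art - stats::median(art))), abs(min(art - stats::median(art))))
})

test_that("phantom generation is bit-reproducible under a fixed seed", {
  a <- generate_phantom(noise_sd = 0.01, seed = 123,
                        layout = phantom_layout(dims = c(4, 4, 1),
                                                n_artery = 4, n_vein = 4))
  b <- generate_phantom(noise_sd = 0.01, seed = 123,
                        layout = phantom_layout(dims = c(4, 4, 1),
                                                n_artery = 4, n_vein = 4))
  expect_identical(a$ts$data, b$ts$data)
  expect_identical(a$truth, b$truth)
  expect_error(generate_phantom(noise_sd = -1), "non-negative")
})

test_that("doubling blood volume doubles the relaxation response", {
  ## GM has twice the WM blood volume and identical dynamics, so the
  ## apparent dR2* AUC ratio is 2 (computed directly from the raw signals)
  ph <- test_phantom("clean_disp")
  cur <- region_curves(ph)
  t <- (seq_along(cur$gm) - 1) * ph$ts$TR
  ratio <- bhdsc:::trapz(t, cur$gm) / bhdsc:::trapz(t, cur$wm)
  expect_equal(ratio, 2, tolerance = 0.02)
})
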