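# Phantom-validated segmentation, midline and feature extraction.

test_that("cranial segmentation matches phantom ground truth", {
  ph <- generate_head_phantom(phantom_spec(seed = 41L, noise_sd = 0))
  cr <- segment_cranial_cavity(ph$ct)
  expect_gte(dice(cr, ph$truth$cranial_mask), 0.98)
  vol <- sum(cr) * prod(ph$ct$spacing) / 1000
  expect_lt(abs(vol / ph$truth$cranial_ml - 1), 0.02)
})

test_that("segmentation fails informatively without a skull", {
  air <- ct_volume(array(-1000, c(16, 16, 8)), c(3, 3, 6))
  expect_error(segment_cranial_cavity(air), "no skull")
})

test_that("CSF segmentation is accurate on noiseless and noisy phantoms", {
  ph0 <- generate_head_phantom(phantom_spec(seed = 42L, noise_sd = 0))
  cr0 <- segment_cranial_cavity(ph0$ct)
  csf0 <- segment_csf(ph0$ct, cr0)
  expect_gte(dice(csf0, ph0$truth$csf_mask), 0.95)
  expect_true(all(!csf0 | cr0))
  ph <- generate_head_phantom(phantom_spec(seed = 42L, noise_sd = 4))
  cr <- segment_cranial_cavity(ph$ct)
  csf <- segment_csf(ph$ct, cr)
  expect_lt(abs(sum(csf) / sum(ph$truth$csf_mask) - 1), 0.10)
})

test_that("a scan without CSF-range voxels yields an empty CSF mask", {
  ph <- generate_head_phantom(small_phantom_spec(seed = 43L, noise_sd = 0))
  ct <- ph$ct
  ct$data[ph$truth$csf_mask] <- 35  # overwrite CSF with parenchyma
  cr <- segment_cranial_cavity(ct)
  csf <- segment_csf(ct, cr)
  expect_lt(sum(csf) / sum(cr), 0.01)
  expect_error(segment_csf(ct, array(FALSE, dim(ct$data))), "empty cranial")
})

test_that("midline recovery: symmetric, rotated, and content-shifted", {
  ph <- generate_head_phantom(phantom_spec(seed = 44L))
  cr <- segment_cranial_cavity(ph$ct)
  pl <- estimate_midline(cr, ph$ct$spacing)
  expect_lt(abs(pl$theta_deg), 1)
  expect_lt(abs(pl$offset_mm), 1.5)

  phr <- generate_head_phantom(phantom_spec(seed = 44L, rotation_deg = 5))
  crr <- segment_cranial_cavity(phr$ct)
  plr <- estimate_midline(crr, phr$ct$spacing)
  expect_lt(abs(plr$theta_deg - 5), 1)

  # 8 mm content shift, fixed skull: plane must not move
  fu <- apply_edema(ph$ct, ph$truth, edema_spec("left", shift_mm = 8))
  crs <- segment_cranial_cavity(fu$ct)
  pls <- estimate_midline(crs, fu$ct$spacing)
  expect_lt(abs(pls$offset_mm - pl$offset_mm), 1.5)
  expect_lt(abs(pls$theta_deg - pl$theta_deg), 1)
})

test_that("hemispheric split conserves volume and respects symmetry", {
  ph <- generate_head_phantom(phantom_spec(seed = 45L))
  cr <- segment_cranial_cavity(ph$ct)
  csf <- segment_csf(ph$ct, cr)
  pl <- estimate_midline(cr, ph$ct$spacing)
  v <- hemispheric_csf_volumes(csf, pl, ph$ct$spacing)
  total <- sum(csf) * prod(ph$ct$spacing) / 1000
  expect_equal(unname(v["left_ml"] + v["right_ml"]), total)
  expect_lt(abs(v["left_ml"] / v["right_ml"] - 1), 0.02)
  bad <- pl ; bad$normal <- c(0, 0, 0)
  expect_error(hemispheric_csf_volumes(csf, bad), "degenerate")
})

test_that("affected-side rule: less CSF, lesion override, tie to left", {
  expect_equal(determine_affected_side(60, 70), "left")
  expect_equal(determine_affected_side(80, 10), "right")
  expect_equal(determine_affected_side(10, 80, lesion_side = "right"),
               "right")
  expect_warning(side <- determine_affected_side(50, 50), "tie")
  expect_equal(side, "left")
  expect_error(determine_affected_side(0, 0), "zero")
})

test_that("feature arithmetic follows the biomarker definitions", {
  base <- c(left_ml = 75, right_ml = 75, cranial_ml = 1500)
  fu <- c(left_ml = 16, right_ml = 32)
  f <- compute_features(base, fu, "left")
  expect_equal(f$intracranial_reserve, 0.10)
  expect_equal(f$csf_ratio_baseline, 1.0)
  expect_equal(f$csf_ratio_24h, 0.5)
  expect_equal(f$delta_csf, 100 * (48 - 150) / 150)
  f2 <- compute_features(c(left_ml = 50, right_ml = 50, cranial_ml = 1000),
                         c(left_ml = 24, right_ml = 24), "left")
  expect_equal(f2$delta_csf, -52)
  expect_error(compute_features(base, c(left_ml = 10, right_ml = 0),
                                "left"),
               "ratio undefined")
})

test_that("an identical scan pair yields zero CSF change and equal ratios", {
  ph <- generate_head_phantom(phantom_spec(seed = 46L))
  f <- extract_volumetrics(ph$ct, ph$ct)
  expect_equal(f$delta_csf, 0)
  expect_equal(f$csf_ratio_baseline, f$csf_ratio_24h)
})
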