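make_vol <- function(values, tube, spacing = c(1, 1, 1)) {
  a <- if (is.array(values)) values else array(values, c(1, 1, 1))
  voxel_volume(a, spacing, -(dim(a) - 1) / 2 * spacing, tube)
}

test_that("dual-energy conversion reproduces hand-evaluated voxels", {
  co <- physics_constants()
  beam <- beam_spec(131)
  p <- default_dect_params()

  # water voxel: rho_e = b, soft branch, ln(I/Iw) = -c0_soft
  res <- deedz_spr_map(make_vol(0, "80kV"), make_vol(0, "135kV"), p, beam, co)
  denom <- log(2 * 510998.95 * beam$beta^2 /
                 (75.3 * (1 - beam$beta^2))) - beam$beta^2
  expect_equal(res$spr$data[1], 1.0 * (1 + 0.0206 / denom), tolerance = 1e-12)
  expect_equal(res$spr$data[1], 1.0025, tolerance = 2e-4)
  expect_equal(res$intermediates$branch[1], 1L)

  # HU pair (1000, 1000): rho_e = a + b = 2.01
  res2 <- deedz_spr_map(make_vol(1000, "80kV"), make_vol(1000, "135kV"),
                        p, beam, co)
  expect_equal(res2$intermediates$rho_e[1], 2.01, tolerance = 1e-12)

  # air voxel
  res3 <- deedz_spr_map(make_vol(-1000, "80kV"), make_vol(-1000, "135kV"),
                        p, beam, co)
  expect_equal(res3$spr$data[1], 0)
  expect_equal(res3$intermediates$branch[1], 0L)

  # shape mismatch and incomplete parameters are rejected
  expect_error(deedz_spr_map(make_vol(0, "80kV"),
                             make_vol(array(0, c(2, 1, 1)), "135kV"),
                             p, beam, co), "different grids")
  p_bad <- p; p_bad$gamma_L <- NULL
  expect_error(deedz_spr_map(make_vol(0, "80kV"), make_vol(0, "135kV"),
                             p_bad, beam, co), "gamma_L")
})

test_that("vectorized dual-energy conversion equals the scalar oracle", {
  co <- physics_constants()
  beam <- beam_spec(131)
  p <- default_dect_params()
  set.seed(16)
  d <- c(16, 16, 16)
  hu_L <- array(stats::runif(prod(d), -1000, 1800), d)
  hu_H <- array(stats::runif(prod(d), -1000, 1300), d)
  res <- deedz_spr_map(make_vol(hu_L, "80kV"), make_vol(hu_H, "135kV"),
                       p, beam, co)
  ref <- array(0, d)
  for (i in seq_len(prod(d))) {
    ref[i] <- oracle_deedz_voxel(hu_L[i], hu_H[i], p, beam$beta, co$Zeff_w)
  }
  expect_lt(max(abs(res$spr$data - ref)), 1e-12)

  # the branch map covers every voxel with exactly one branch
  expect_true(all(res$intermediates$branch %in% 0:2))
})

test_that("single-energy conversion matches scalar lookups", {
  setup <- calibrated_setup()
  lut <- setup$lut
  v0 <- make_vol(array(0, c(4, 4, 2)), "120kV")
  expect_equal(max(abs(sect_spr_map(v0, lut)$data - 1)), 0,
               tolerance = 1e-9)

  set.seed(3)
  hu <- array(stats::runif(64, -1000, 2000), c(4, 4, 4))
  vol <- make_vol(hu, "120kV")
  res <- sect_spr_map(vol, lut)
  for (i in sample(64, 10)) {
    expect_equal(res$data[i], lut_lookup(lut, hu[i]), tolerance = 1e-12)
  }
})

test_that("SPR difference maps are antisymmetric and grid-checked", {
  a <- spr_volume(array(1.0, c(4, 4, 2)), c(1, 1, 1), c(0, 0, 0), "DECT")
  b <- spr_volume(array(1.1, c(4, 4, 2)), c(1, 1, 1), c(0, 0, 0), "SECT")
  expect_true(all(delta_spr_map(a, a) == 0))
  expect_equal(delta_spr_map(a, b), -delta_spr_map(b, a))
  expect_true(all(abs(delta_spr_map(a, b) + 0.1) < 1e-12))
  c_mis <- spr_volume(array(1, c(4, 4, 3)), c(1, 1, 1), c(0, 0, 0), "SECT")
  expect_error(delta_spr_map(a, c_mis), "different grids")
})

test_that("cylindrical ROI mean uses voxel-center membership", {
  d <- c(21, 21, 21)
  vals <- array(1.0, d)
  vals[11:21, , ] <- 2.0            # half-space split at x = 0.5
  spr <- spr_volume(vals, c(1, 1, 1), -(d - 1) / 2, "truth")

  roi <- roi_cylinder_mean(spr, c(0, 0, 0), axis = c(0, 1, 0))
  expect_gt(roi$n_voxels, 0)

  const <- spr_volume(array(1.7, d), c(1, 1, 1), -(d - 1) / 2, "truth")
  expect_equal(roi_cylinder_mean(const, c(2, 3, -1))$mean, 1.7)

  # axis-aligned half split: mean 1.5 within one voxel layer
  roi_split <- roi_cylinder_mean(spr, c(0.5, 0, 0), axis = c(0, 1, 0),
                                 diameter = 8, length = 9)
  expect_equal(roi_split$mean, 1.5, tolerance = 0.15)

  expect_error(roi_cylinder_mean(spr, c(500, 0, 0)), "empty ROI")
})

test_that("mask statistics report histogram, median and scatter pairs", {
  d <- c(3, 1, 1)
  spr <- spr_volume(array(c(1, 2, 3), d), c(1, 1, 1), c(0, 0, 0), "DECT")
  mask <- array(TRUE, d)
  st <- mask_statistics(spr, mask, breaks = seq(0, 3.5, 0.5))
  expect_equal(st$median, 2)
  expect_equal(st$mean, 2)
  expect_equal(sum(st$counts), 3)

  const <- spr_volume(array(1.2, d), c(1, 1, 1), c(0, 0, 0), "DECT")
  st_c <- mask_statistics(const, mask)
  expect_equal(sum(st_c$counts > 0), 1)
  expect_equal(st_c$median, 1.2)

  # median ratio mirrors a constructed relative difference
  low <- spr_volume(0.927 * const$data, c(1, 1, 1), c(0, 0, 0), "DECT")
  st_l <- mask_statistics(low, mask)
  expect_equal(100 * (st_l$median - st_c$median) / st_c$median, -7.3,
               tolerance = 1e-9)

  ref <- spr_volume(array(1.0, d), c(1, 1, 1), c(0, 0, 0), "SECT")
  st_p <- mask_statistics(spr, mask, reference = ref)
  expect_equal(st_p$scatter$delta_spr, c(0, 1, 2))
  expect_error(mask_statistics(spr, array(FALSE, d)), "empty mask")
})

test_that("region override replaces only masked voxels and copies", {
  d <- c(4, 4, 2)
  spr <- spr_volume(array(seq_len(prod(d)) / 10, d), c(1, 1, 1),
                    c(0, 0, 0), "DECT")
  mask <- array(FALSE, d); mask[1:2, , ] <- TRUE
  out <- override_spr_region(spr, mask, 1.0)
  expect_true(all(out$data[mask] == 1))
  expect_identical(out$data[!mask], spr$data[!mask])
  expect_false(identical(out$data, spr$data))   # input untouched
  expect_identical(override_spr_region(spr, array(FALSE, d))$data, spr$data)
  expect_error(override_spr_region(spr, mask, -1), "non-negative")
  st <- mask_statistics(override_spr_region(spr, mask, 1.0), mask)
  expect_equal(st$median, 1.0)
})

test_that("hypothetical CT volumes round-trip through the lookup table", {
  setup <- calibrated_setup()
  lut <- setup$lut
  d <- c(8, 8, 4)
  set.seed(11)
  vals <- array(stats::runif(prod(d), 0, 1.8), d)
  spr <- spr_volume(vals, c(1, 1, 1), -(d - 1) / 2, "DECT")
  hypo <- spr_to_hypothetical_ct(spr, lut)
  expect_true(hypo$hypothetical)
  expect_identical(hypo$tube, "120kV")
  back <- sect_spr_map(hypo, lut)
  expect_lt(max(abs(back$data - spr$data)), 1e-6)

  ones <- spr_volume(array(1, d), c(1, 1, 1), -(d - 1) / 2, "DECT")
  expect_lt(max(abs(spr_to_hypothetical_ct(ones, lut)$data)), 1e-6)
  zeros <- spr_volume(array(0, d), c(1, 1, 1), -(d - 1) / 2, "DECT")
  expect_true(all(spr_to_hypothetical_ct(zeros, lut)$data == -1000))
})
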