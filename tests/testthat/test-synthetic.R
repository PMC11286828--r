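test_that("calibration phantom has disjoint inserts over a water bore", {
  ph <- build_calibration_phantom()
  insert_masks <- grep("^insert_", names(ph$masks), value = TRUE)
  expect_length(insert_masks, 10)
  total <- Reduce(`+`, lapply(insert_masks, function(m) ph$masks[[m]]))
  expect_true(all(total <= 1))
  expect_false(any(ph$masks$background &
                     Reduce(`|`, lapply(insert_masks, function(m) ph$masks[[m]]))))

  # voxel count per insert approximates the analytic cylinder volume
  vox_vol <- prod(ph$spacing)
  cyl_vol <- pi * 6^2 * (ph$dim[3] * ph$spacing[3])
  for (m in insert_masks) {
    expect_equal(sum(ph$masks[[m]]) * vox_vol, cyl_vol, tolerance = 0.05)
  }

  # empty insert list: pure water bore, one mask
  ph0 <- build_calibration_phantom(inserts = character(0))
  expect_length(grep("^insert_", names(ph0$masks)), 0)
  expect_true(all(ph0$fractions$water[ph0$masks$background] == 1))

  # body arrangement relocates the same inserts
  phb <- build_calibration_phantom(arrangement = "body")
  expect_false(identical(which(phb$masks$insert_water),
                         which(ph$masks$insert_water)))
  expect_equal(sum(phb$masks$insert_water) * vox_vol, cyl_vol,
               tolerance = 0.05)
})

test_that("porosity phantom realizes the requested pore fraction", {
  ha <- get_material("hydroxyapatite")
  ph <- build_porosity_phantom(porosity = 0.75)
  m <- ph$masks$sample
  # uniform model: every sample voxel at 25% mineral, bulk density
  # 0.25 * 3.16 + 0.75 * rho_air
  expect_true(all(abs(ph$fractions$hydroxyapatite[m] - 0.25) < 1e-12))
  bulk <- ph$fractions$hydroxyapatite[m][1] * 3.16 +
    ph$fractions$air[m][1] * get_material("air")$density
  expect_equal(bulk, 0.25 * 3.16 + 0.75 * 0.0012, tolerance = 1e-9)

  # porosity 0: pure base
  ph0 <- build_porosity_phantom(porosity = 0)
  expect_true(all(ph0$fractions$hydroxyapatite[ph0$masks$sample] == 1))

  # binary model: filler fraction within 3-sigma binomial error
  phb <- build_porosity_phantom(porosity = 0.5, pore_model = "binary",
                                seed = 7, dim = c(32, 32, 16))
  n <- sum(phb$masks$sample)
  frac <- mean(phb$fractions$air[phb$masks$sample])
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))

  expect_error(build_porosity_phantom(porosity = 1), "porosity")
})

test_that("simulated CT numbers obey the normalization and linearity", {
  scans <- noiseless_scans()
  ph <- build_porosity_phantom(porosity = 0.5, dim = c(48, 16, 4))
  for (s in scans) {
    v <- simulate_ct(ph, s)
    expect_equal(max(abs(v$data[ph$masks$background])), 0, tolerance = 1e-9)
  }

  # air close to -1000 HU (true air carries ~0.1% of water's attenuation)
  air_ph <- build_porosity_phantom(base = get_material("air"), porosity = 0,
                                   dim = c(8, 8, 4))
  v <- simulate_ct(air_ph, scans$`120kV`)
  expect_lt(max(v$data[air_ph$masks$sample]), -998.5)

  # HU is exactly linear in volume fractions (noiseless)
  hu_mix <- vapply(c(0, 0.25, 0.5), function(p) {
    phx <- build_porosity_phantom(porosity = p, dim = c(8, 8, 4))
    simulate_ct(phx, scans$`120kV`)$data[phx$masks$sample][1]
  }, 0)
  expect_equal(hu_mix[2], (hu_mix[1] + hu_mix[3]) / 2, tolerance = 1e-9)

  # monotone in mineral content, per tube
  for (s in scans) {
    hu_p <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(p) {
      phx <- build_porosity_phantom(porosity = p, dim = c(8, 8, 4))
      simulate_ct(phx, s)$data[phx$masks$sample][1]
    }, 0)
    expect_false(is.unsorted(rev(hu_p)))
  }

  # noiseless acquisition is deterministic and seed-independent
  v1 <- simulate_ct(ph, scans$`80kV`, seed = 1)
  v2 <- simulate_ct(ph, scans$`80kV`, seed = 99)
  expect_identical(v1$data, v2$data)
  # noisy acquisition is seed-reproducible
  sn <- scan_model("80kV")
  expect_identical(simulate_ct(ph, sn, seed = 5)$data,
                   simulate_ct(ph, sn, seed = 5)$data)
  expect_false(identical(simulate_ct(ph, sn, seed = 5)$data,
                         simulate_ct(ph, sn, seed = 6)$data))
})

test_that("ground-truth SPR agrees with material-level physics", {
  beam <- beam_spec(131)
  co <- physics_constants()
  ph <- build_calibration_phantom(inserts = character(0), dim = c(16, 16, 4))
  truth <- ground_truth_spr_volume(ph, beam, co)
  expect_equal(max(abs(truth$data[ph$masks$background] - 1)), 0,
               tolerance = 1e-12)

  # uniform porous mixture: constant SPR equal to the mixed material's
  ha <- get_material("hydroxyapatite")
  air <- get_material("air")
  php <- build_porosity_phantom(porosity = 0.75, dim = c(8, 8, 4))
  truth_p <- ground_truth_spr_volume(php, beam, co)
  mixed <- mix_materials(list(ha, air), c(0.25, 0.75))
  expect_equal(truth_p$data[php$masks$sample][1], material_spr(mixed, beam, co),
               tolerance = 1e-12)

  # SPR of base+air mixtures is nearly linear in (1 - porosity): air
  # carries negligible mass, so the excitation term stays the base's
  sprs <- vapply(c(0, 0.25, 0.5, 0.75), function(p) {
    phx <- build_porosity_phantom(porosity = p, dim = c(8, 8, 4))
    ground_truth_spr_volume(phx, beam, co)$data[phx$masks$sample][1]
  }, 0)
  ratios <- sprs / sprs[1]
  expect_equal(ratios, c(1, 0.75, 0.5, 0.25), tolerance = 2e-3)
})

test_that("phantom validation rejects inconsistent mixtures", {
  w <- get_material("water")
  f <- array(0.5, c(4, 4, 2))
  expect_error(phantom_definition(c(4, 4, 2), c(1, 1, 1),
                                  list(water = w), list(water = f)),
               "sum to 1")
  expect_error(phantom_definition(c(4, 4, 2), c(1, 1, 1), list(water = w),
                                  list(water = array(1, c(2, 2, 2)))),
               "shape mismatch")
})
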