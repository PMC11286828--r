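test_that("noiseless calibration round trip recovers generating parameters", {
  co <- physics_constants()
  gen <- default_dect_params()
  obs <- gen_dect_obs(gen, insert_hu_pairs(), co)
  fitted <- fit_dect_params(obs, co)
  for (f in c("a", "b", "alpha", "gamma_L", "c1_soft", "c0_soft",
              "c1_bone", "c0_bone")) {
    expect_equal(fitted[[f]], gen[[f]], tolerance = 1e-9,
                 label = paste("recovered", f))
  }
  expect_equal(fitted$r_squared$rho_e, 1, tolerance = 1e-9)
  expect_equal(fitted$r_squared$gamma_L, 1, tolerance = 1e-9)

  # round trip holds for an arbitrary second parameter set too
  gen2 <- dect_params(a = 1.0, b = 1.0, alpha = 0.9, gamma_L = 9.5,
                      c1_soft = 0.31, c0_soft = 0.015, c1_bone = 0.058,
                      c0_bone = 0.012)
  obs2 <- gen_dect_obs(gen2, insert_hu_pairs(), co)
  fitted2 <- fit_dect_params(obs2, co)
  for (f in c("a", "b", "alpha", "gamma_L", "c1_soft", "c0_soft",
              "c1_bone", "c0_bone")) {
    expect_equal(fitted2[[f]], gen2[[f]], tolerance = 1e-9)
  }
})

test_that("electron-density fit reports degeneracy and propagates noise sanely", {
  co <- physics_constants()
  # HU_H == HU_L: the subtraction weight is unidentifiable
  pairs_deg <- cbind(hu_L = c(-500, 0, 300, 900),
                     hu_H = c(-500, 0, 300, 900))
  obs_deg <- gen_dect_obs(default_dect_params(), pairs_deg, co)
  expect_error(fit_rho_e_params(obs_deg), "collinear")
  expect_error(fit_rho_e_params(obs_deg[1:2, ]), "at least 3")

  # noisy inserts: estimates within 3 fitted standard errors
  gen <- default_dect_params()
  obs <- gen_dect_obs(gen, insert_hu_pairs(), co)
  set.seed(1)
  obs$hu_L <- obs$hu_L + stats::rnorm(nrow(obs), 0, 5)
  obs$hu_H <- obs$hu_H + stats::rnorm(nrow(obs), 0, 5)
  fit <- fit_rho_e_params(obs)
  se_a <- 1000 * (fit$std_errors[["hu_H"]] + fit$std_errors[["hu_L"]])
  expect_lt(abs(fit$a - gen$a), 3 * se_a)
  se_alpha <- 1000 * fit$std_errors[["hu_L"]] / fit$a +
    abs(fit$alpha) / fit$a * se_a
  expect_lt(abs(fit$alpha - gen$alpha), 3 * se_alpha)
})

test_that("atomic-number slope fit is exact least squares through the origin", {
  co <- physics_constants()
  # two-point exact dataset: gamma = sum(xy)/sum(x^2)
  obs <- data.frame(hu_L = 1000 * ((c(0.1, 0.2) + 1) - 1),
                    rho_e_ref = 1, zeff_ref = NA)
  x <- c(0.1, 0.2)
  y <- c(1.085, 2.17)
  obs$zeff_ref <- co$Zeff_w * (1 + y)^(1 / co$m)
  fit <- fit_gamma_L(obs, co)
  expect_equal(fit$gamma_L, 10.85, tolerance = 1e-9)

  # water-only observations carry no contrast
  obs_w <- data.frame(hu_L = 0, rho_e_ref = 1, zeff_ref = co$Zeff_w)
  expect_error(fit_gamma_L(obs_w[c(1, 1), ], co), "degenerate")
})

test_that("excitation-energy calibration splits branches and flags degeneracy", {
  co <- physics_constants()
  gen <- default_dect_params()
  obs <- gen_dect_obs(gen, insert_hu_pairs(), co)

  # boundary effective atomic number goes to the bone branch
  obs_b <- data.frame(zeff_ref = c(6, 7, 8.8, 12),
                      i_ref_eV = c(65, 70, 90, 110))
  fit_b <- fit_i_calibration(obs_b, co)
  expect_identical(fit_b$groups, c("soft", "soft", "bone", "bone"))

  # a branch with fewer than 2 inserts errors
  expect_error(fit_i_calibration(obs_b[c(1, 2, 4), ], co), "fewer than 2")

  # no regressor contrast: c1 unidentifiable, flagged; c0 from the mean
  obs_d <- data.frame(zeff_ref = rep(co$Zeff_w, 3), i_ref_eV = rep(co$Iw, 3))
  obs_d <- rbind(obs_d, data.frame(zeff_ref = c(10, 12),
                                   i_ref_eV = c(90, 100)))
  fit_d <- fit_i_calibration(obs_d, co)
  expect_true(fit_d$degenerate[["soft"]])
  expect_true(is.na(fit_d$c1_soft))
  expect_equal(fit_d$c0_soft, 0, tolerance = 1e-9)

  # sign convention: a bone insert with I > Iw maps back to ln(I/Iw) > 0
  bone_sel <- fit_i_calibration(obs, co)$groups == "bone"
  x_bone <- (obs$zeff_ref[bone_sel] / co$Zeff_w)^co$m - 1
  fit <- fit_i_calibration(obs, co)
  ln_pred <- fit$c1_bone * x_bone - fit$c0_bone
  expect_equal(ln_pred, log(obs$i_ref_eV[bone_sel] / co$Iw),
               tolerance = 1e-9)
  expect_true(all(ln_pred[obs$i_ref_eV[bone_sel] > co$Iw] > 0))
})

test_that("noisy fits are unbiased over seeded replicates", {
  co <- physics_constants()
  gen <- default_dect_params()
  base <- gen_dect_obs(gen, insert_hu_pairs(), co)
  set.seed(2024)
  n_rep <- 200
  err_a <- err_g <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    obs <- base
    obs$hu_L <- obs$hu_L + stats::rnorm(nrow(obs), 0, 5)
    obs$hu_H <- obs$hu_H + stats::rnorm(nrow(obs), 0, 5)
    err_a[r] <- fit_rho_e_params(obs)$a - gen$a
    err_g[r] <- fit_gamma_L(obs, co)$gamma_L - gen$gamma_L
  }
  expect_lt(abs(mean(err_a)), 3 * stats::sd(err_a) / sqrt(n_rep))
  # the origin-constrained slope is a classical errors-in-variables
  # estimator: CT-number noise in its regressor attenuates it by
  # sum(sigma_x^2) / (sum(x^2) + sum(sigma_x^2)); after correcting for
  # that predictable attenuation the estimate is unbiased
  x_true <- (base$hu_L / 1000 + 1) / base$rho_e_ref - 1
  sigma_x <- 5e-3 / base$rho_e_ref
  pred_bias <- -gen$gamma_L * sum(sigma_x^2) /
    (sum(x_true^2) + sum(sigma_x^2))
  expect_lt(abs(mean(err_g) - pred_bias),
            3 * stats::sd(err_g) / sqrt(n_rep))
})

test_that("parameter serialization round-trips through JSON", {
  p <- default_dect_params()
  path <- tempfile(fileext = ".json")
  write_dect_params(p, path)
  q <- read_dect_params(path)
  expect_equal(unclass(q)[names(q) != "r_squared"],
               unclass(p)[names(p) != "r_squared"])
})
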