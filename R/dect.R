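# Dual-energy (energy-subtraction) calibration: fitting the constants of
# the HU-pair -> electron density -> effective atomic number -> mean
# excitation energy chain from insert observations.

#' Dual-energy conversion parameter set
#'
#' All constants of the dual-energy energy-subtraction SPR conversion:
#' the electron-density relation `rho_e = a ((1+alpha) HU_H - alpha HU_L)
#' / 1000 + b`, the effective-atomic-number relation
#' `(Zeff/Zeff_w)^m - 1 = gamma_L (mu_L / rho_e - 1)` with reduced CT
#' number `mu_L = HU_L/1000 + 1`, and the two-branch mean-excitation
#' relation `ln(I/Iw) = c1 * ((Zeff/Zeff_w)^m - 1) - c0` with a soft/bone
#' split at effective atomic number `ean_split`.
#'
#' @param a,b,alpha Electron-density coefficients (`a > 0`).
#' @param gamma_L Effective-atomic-number slope (> 0).
#' @param c1_soft,c0_soft,c1_bone,c0_bone Mean-excitation coefficients.
#' @param m Mayneord exponent.
#' @param Iw Water mean excitation energy, eV.
#' @param ean_split Soft/bone separation effective atomic number
#'   (boundary values are assigned to the bone branch).
#' @param r_squared Optional named list of fit R-squared values.
#' @return An object of class `dect_params`.
#' @export
dect_params <- function(a, b, alpha, gamma_L, c1_soft, c0_soft, c1_bone,
                        c0_bone, m = 3.3, Iw = 75.3, ean_split = 8.8,
                        r_squared = list()) {
  stopifnot(a > 0, gamma_L > 0, ean_split > 0, m > 0, Iw > 0)
  structure(list(a = a, b = b, alpha = alpha, gamma_L = gamma_L,
                 c1_soft = c1_soft, c0_soft = c0_soft, c1_bone = c1_bone,
                 c0_bone = c0_bone, m = m, Iw = Iw, ean_split = ean_split,
                 r_squared = r_squared),
            class = "dect_params")
}

#' Reference dual-energy parameter set
#'
#' The published 80/135 kV scanner calibration: `a = 1.01`, `b = 1.00`,
#' `alpha = 1.01`, `gamma_L = 10.85`, soft branch `c1 = 0.3423`,
#' `c0 = 0.0206`, bone branch `c1 = 0.0696`, `c0 = 0.0444`, with
#' `m = 3.3`, `Iw = 75.3` eV and the soft/bone split at effective atomic
#' number 8.8.  Lets the conversion run without refitting.
#'
#' @return A [dect_params()] object.
#' @export
default_dect_params <- function() {
  dect_params(a = 1.01, b = 1.00, alpha = 1.01, gamma_L = 10.85,
              c1_soft = 0.3423, c0_soft = 0.0206,
              c1_bone = 0.0696, c0_bone = 0.0444)
}

#' Measure calibration-insert observations from simulated scans
#'
#' Extracts the per-insert mean CT numbers from one or more volumes and
#' attaches reference values (relative electron density, effective atomic
#' number at `m`, mean excitation energy) computed from the insert
#' materials themselves.
#'
#' @param phantom A calibration [phantom_definition()] with
#'   `insert_<name>` masks.
#' @param volumes Named list of [voxel_volume()]s, e.g.
#'   `list(hu_L = ..., hu_H = ..., hu_120 = ...)`; each contributes a
#'   mean-HU column of that name.
#' @param constants A [physics_constants()].
#' @return A data frame with one row per insert: `material`, the mean-HU
#'   columns, `rho_e_ref`, `zeff_ref`, `i_ref_eV`.
#' @export
measure_inserts <- function(phantom, volumes,
                            constants = physics_constants()) {
  insert_masks <- grep("^insert_", names(phantom$masks), value = TRUE)
  if (!length(insert_masks)) stop("phantom has no insert_* masks")
  rows <- lapply(insert_masks, function(mk) {
    nm <- sub("^insert_", "", mk)
    mat <- phantom$materials[[nm]]
    row <- list(material = nm)
    for (vn in names(volumes)) {
      row[[vn]] <- mean(volumes[[vn]]$data[phantom$masks[[mk]]])
    }
    row$rho_e_ref <- relative_electron_density(mat)
    row$zeff_ref <- effective_atomic_number(mat$composition, constants$m)
    row$i_ref_eV <- mean_excitation_energy(mat$composition)
    as.data.frame(row)
  })
  do.call(rbind, rows)
}

#' Fit the electron-density coefficients
#'
#' Ordinary least squares of reference relative electron density on the
#' high- and low-kV CT numbers, re-expressed in the energy-subtraction
#' form `rho_e = a ((1+alpha) HU_H - alpha HU_L)/1000 + b`.  The raw OLS
#' coefficients `(c_H, c_L)` map to `a = 1000 (c_H + c_L)` and
#' `alpha = -1000 c_L / a`; the identity holds exactly, so predictions by
#' either form agree.
#'
#' @param obs Data frame with columns `hu_L`, `hu_H`, `rho_e_ref`
#'   (>= 3 rows spanning distinct CT numbers).
#' @return List with `a`, `b`, `alpha`, `r_squared`.
#' @export
fit_rho_e_params <- function(obs) {
  stopifnot(all(c("hu_L", "hu_H", "rho_e_ref") %in% names(obs)))
  if (nrow(obs) < 3) stop("need at least 3 inserts to fit a, b, alpha")
  X <- cbind(1, obs$hu_H, obs$hu_L)
  if (qr(X)$rank < 3) {
    stop("degenerate insert set: HU_H and HU_L are collinear across ",
         "inserts (alpha unidentifiable); widen the insert range")
  }
  fit <- stats::lm(rho_e_ref ~ hu_H + hu_L, data = obs)
  cf <- stats::coef(fit)
  a <- 1000 * (cf[["hu_H"]] + cf[["hu_L"]])
  alpha <- -1000 * cf[["hu_L"]] / a
  ss_tot <- sum((obs$rho_e_ref - mean(obs$rho_e_ref))^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / ss_tot
  se <- suppressWarnings(summary(fit)$coefficients[, "Std. Error"])
  list(a = a, b = cf[["(Intercept)"]], alpha = alpha, r_squared = r2,
       std_errors = se)
}

#' Fit the effective-atomic-number slope
#'
#' Least squares through the origin of `y = (Zeff/Zeff_w)^m - 1` on
#' `x = mu_L / rho_e - 1`, with reduced CT number
#' `mu_L = HU_L / 1000 + 1` and reference electron densities.
#'
#' @param obs Data frame with columns `hu_L`, `rho_e_ref`, `zeff_ref`.
#' @param constants A [physics_constants()] (supplies `m` and `Zeff_w`).
#' @return List with `gamma_L` and `r_squared`.
#' @export
fit_gamma_L <- function(obs, constants = physics_constants()) {
  stopifnot(all(c("hu_L", "rho_e_ref", "zeff_ref") %in% names(obs)))
  x <- (obs$hu_L / 1000 + 1) / obs$rho_e_ref - 1
  y <- (obs$zeff_ref / constants$Zeff_w)^constants$m - 1
  if (all(abs(x) < 1e-12)) {
    stop("degenerate insert set: no atomic-number contrast (all reduced ",
         "CT numbers equal the electron density)")
  }
  gamma_L <- sum(x * y) / sum(x^2)
  r2 <- if (sum(y^2) > 0) 1 - sum((y - gamma_L * x)^2) / sum(y^2) else NA_real_
  list(gamma_L = gamma_L, r_squared = r2)
}

#' Fit the two-branch mean-excitation calibration
#'
#' Per branch (soft: reference effective atomic number below the split;
#' bone: at or above it), least squares of `ln(I/Iw)` on
#' `x = (Zeff/Zeff_w)^m - 1`; the slope is `c1` and the intercept is
#' `-c0`.
#'
#' @param obs Data frame with columns `zeff_ref`, `i_ref_eV`.
#' @param constants A [physics_constants()].
#' @param ean_split Soft/bone separation (boundary goes to bone).
#' @return List with `c1_soft`, `c0_soft`, `c1_bone`, `c0_bone`,
#'   `groups` (branch of each insert) and `degenerate` flags for
#'   branches without regressor contrast (their `c1` is `NA` and `c0`
#'   is minus the mean response).
#' @export
fit_i_calibration <- function(obs, constants = physics_constants(),
                              ean_split = 8.8) {
  stopifnot(all(c("zeff_ref", "i_ref_eV") %in% names(obs)))
  grp <- ifelse(obs$zeff_ref >= ean_split, "bone", "soft")
  x_all <- (obs$zeff_ref / constants$Zeff_w)^constants$m - 1
  y_all <- log(obs$i_ref_eV / constants$Iw)
  out <- list(groups = grp, degenerate = c(soft = FALSE, bone = FALSE))
  for (g in c("soft", "bone")) {
    sel <- grp == g
    if (sum(sel) < 2) {
      stop("branch '", g, "' has fewer than 2 inserts (split at ",
           ean_split, ")")
    }
    x <- x_all[sel]; y <- y_all[sel]
    if (stats::sd(x) < 1e-12) {
      out[[paste0("c1_", g)]] <- NA_real_
      out[[paste0("c0_", g)]] <- -mean(y)
      out$degenerate[g] <- TRUE
    } else {
      fit <- stats::lm(y ~ x)
      out[[paste0("c1_", g)]] <- stats::coef(fit)[["x"]]
      out[[paste0("c0_", g)]] <- -stats::coef(fit)[["(Intercept)"]]
    }
  }
  out
}

#' Fit the full dual-energy parameter set from insert observations
#'
#' Runs [fit_rho_e_params()], [fit_gamma_L()] and [fit_i_calibration()]
#' and assembles a [dect_params()] object.
#'
#' @param obs Insert observations (see [measure_inserts()]), with
#'   columns `hu_L`, `hu_H`, `rho_e_ref`, `zeff_ref`, `i_ref_eV`.
#' @param constants A [physics_constants()].
#' @param ean_split Soft/bone separation effective atomic number.
#' @return A [dect_params()] object with per-fit R-squared values.
#' @export
fit_dect_params <- function(obs, constants = physics_constants(),
                            ean_split = 8.8) {
  f1 <- fit_rho_e_params(obs)
  f2 <- fit_gamma_L(obs, constants)
  f3 <- fit_i_calibration(obs, constants, ean_split)
  dect_params(a = f1$a, b = f1$b, alpha = f1$alpha, gamma_L = f2$gamma_L,
              c1_soft = f3$c1_soft, c0_soft = f3$c0_soft,
              c1_bone = f3$c1_bone, c0_bone = f3$c0_bone,
              m = constants$m, Iw = constants$Iw, ean_split = ean_split,
              r_squared = list(rho_e = f1$r_squared,
                               gamma_L = f2$r_squared))
}
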