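# Single-energy stoichiometric calibration and the HU -> SPR lookup table.

#' Power-mean atomic-number features of a composition
#'
#' `sum(lambda_i Z_i^n) / sum(lambda_i)` for an exponent `n`, with
#' electron-fraction weights; the two exponents of the stoichiometric
#' cross-section model (photoelectric-like 3.62, coherent-like 1.86) are
#' the usual callers.
#'
#' @param comp An [composition()] object.
#' @param n Exponent.
#' @return Dimensionless feature value.
#' @export
z_feature <- function(comp, n) {
  lam <- electron_fractions(comp)
  sum(lam * comp$Z^n)
}

#' Fit the stoichiometric cross-section model
#'
#' Fits the two-coefficient parameterization
#' `mu/mu_w = rho_e (1 + k1 Z1 + k2 Z2) / (1 + k1 Z1w + k2 Z2w)`
#' with `Zj = sum(lambda Z^nj)/sum(lambda)` to measured 120 kV CT numbers
#' of inserts with known compositions.  The relation is linear in
#' `(k1, k2)` after cross-multiplying, so the fit is exact least squares;
#' the water row is identically zero, which constrains the water residual
#' to zero by construction.
#'
#' @param obs Data frame with columns `material` and `hu_120` (>= 3
#'   non-water inserts).
#' @param materials Named list of [material()] objects covering
#'   `obs$material`.
#' @param n1,n2 Cross-section exponents (defaults 3.62 and 1.86).
#' @return An object of class `stoichiometric_model` with `k1`, `k2`,
#'   `n1`, `n2`, water features `z1_w`, `z2_w`, and a
#'   `zeff_unidentified` flag set when the insert set has no
#'   atomic-number contrast (pure-density series).
#' @export
fit_stoichiometric_model <- function(obs, materials = material_library(),
                                     n1 = 3.62, n2 = 1.86) {
  stopifnot(all(c("material", "hu_120") %in% names(obs)))
  missing <- setdiff(obs$material, names(materials))
  if (length(missing)) stop("no material spec for: ",
                            paste(missing, collapse = ", "))
  water <- get_material("water")
  z1w <- z_feature(water$composition, n1)
  z2w <- z_feature(water$composition, n2)
  rho_e <- vapply(obs$material,
                  function(nm) relative_electron_density(materials[[nm]]), 0)
  z1 <- vapply(obs$material,
               function(nm) z_feature(materials[[nm]]$composition, n1), 0)
  z2 <- vapply(obs$material,
               function(nm) z_feature(materials[[nm]]$composition, n2), 0)
  u <- obs$hu_120 / 1000 + 1
  # u (1 + k1 z1w + k2 z2w) = rho_e (1 + k1 z1 + k2 z2)
  A <- cbind(u * z1w - rho_e * z1, u * z2w - rho_e * z2)
  bvec <- rho_e - u
  keep <- rowSums(abs(A)) > 1e-12          # water-like rows are 0 = 0
  if (sum(keep) < 2 || qr(A[keep, , drop = FALSE])$rank < 2) {
    model_degenerate <- TRUE
    if (sum(keep) == 0) {
      stop("degenerate insert set: water-only observations carry no ",
           "cross-section information")
    }
    # pure-density series: any (k1, k2) along the null space fits
    k <- stats::coef(stats::lm.fit(A[keep, 1, drop = FALSE], bvec[keep]))
    k <- c(k, 0)
  } else {
    model_degenerate <- FALSE
    k <- stats::coef(stats::lm.fit(A[keep, , drop = FALSE], bvec[keep]))
  }
  model <- structure(list(k1 = unname(k[1]), k2 = unname(k[2]),
                          n1 = n1, n2 = n2, z1_w = z1w, z2_w = z2w,
                          tube = "120kV",
                          zeff_unidentified = model_degenerate),
                     class = "stoichiometric_model")
  pred <- predict_hu(model, lapply(obs$material, function(nm) materials[[nm]]))
  if (any(pred / 1000 + 1 < 0)) {
    stop("stoichiometric model predicts negative attenuation for an ",
         "insert; model invalid for this insert set")
  }
  model
}

#' Predict CT numbers from a stoichiometric model
#'
#' @param model A `stoichiometric_model`.
#' @param materials List of [material()] objects.
#' @return Numeric vector of predicted CT numbers (HU).
#' @export
predict_hu <- function(model, materials) {
  denom <- 1 + model$k1 * model$z1_w + model$k2 * model$z2_w
  vapply(materials, function(m) {
    rel <- relative_electron_density(m) *
      (1 + model$k1 * z_feature(m$composition, model$n1) +
         model$k2 * z_feature(m$composition, model$n2)) / denom
    1000 * (rel - 1)
  }, 0)
}

#' Build the single-energy CT-number-to-SPR lookup table
#'
#' Predicts a 120 kV CT number for every reference tissue with the
#' stoichiometric model, computes its Bethe SPR, and assembles a
#' piecewise-linear monotone lookup table with air (-1000 HU, SPR 0) and
#' water (0 HU, SPR 1) anchor nodes.  Non-monotone node sequences are
#' resolved by isotonic pooling (pool-adjacent-violators on the SPR
#' values ordered by HU); the adjustment is recorded.
#'
#' @param model A `stoichiometric_model` from
#'   [fit_stoichiometric_model()].
#' @param tissues Character vector of packaged reference tissue names
#'   (default [reference_tissue_names()]), or a list of [material()]s.
#' @param beam A [beam_spec()].
#' @param constants A [physics_constants()].
#' @return An object of class `sect_lut`: a data frame of nodes
#'   (`hu`, `spr`) with attributes `adjusted` (isotonic pooling applied)
#'   and `tube`.
#' @export
build_hu_spr_lut <- function(model, tissues = reference_tissue_names(),
                             beam, constants = physics_constants()) {
  mats <- if (is.character(tissues)) {
    lapply(tissues, get_material)
  } else tissues
  if (length(mats) < 2) stop("need at least 2 reference tissues")
  hu <- predict_hu(model, mats)
  spr <- vapply(mats, material_spr, 0, beam = beam, constants = constants)
  nodes <- data.frame(hu = c(-1000, 0, hu), spr = c(0, 1, spr),
                      weight = c(1e12, 1e12, rep(1, length(hu))))
  nodes <- nodes[order(nodes$hu), ]
  # collapse nodes closer than 0.5 HU (duplicated anchors / tissues)
  keep <- c(TRUE, diff(nodes$hu) > 0.5)
  nodes <- nodes[keep, ]
  rownames(nodes) <- NULL
  if (nrow(nodes) < 2) stop("fewer than 2 distinct CT-number nodes")
  adjusted <- is.unsorted(nodes$spr)
  if (adjusted) {
    # weighted pool-adjacent-violators; the anchors' large weights pin
    # the pooled values at (-1000, 0) and (0, 1)
    nodes$spr <- pava(nodes$spr, nodes$weight)
    # a tissue node pooled into an anchor's block is dropped so the
    # anchors stay exact, unique nodes
    anchor <- nodes$weight > 1
    drop <- !anchor & nodes$spr %in% nodes$spr[anchor]
    nodes <- nodes[!drop, ]
    rownames(nodes) <- NULL
  }
  nodes$weight <- NULL
  structure(nodes, class = c("sect_lut", "data.frame"),
            adjusted = adjusted, tube = model$tube)
}

# Weighted pool-adjacent-violators: least-squares non-decreasing fit.
pava <- function(y, w) {
  n <- length(y)
  val <- y; wt <- w; idx <- as.list(seq_len(n))
  k <- 1
  for (i in seq_len(n)[-1]) {
    k <- k + 1
    val[k] <- y[i]; wt[k] <- w[i]; idx[[k]] <- i
    while (k > 1 && val[k - 1] > val[k]) {
      val[k - 1] <- (wt[k - 1] * val[k - 1] + wt[k] * val[k]) /
        (wt[k - 1] + wt[k])
      wt[k - 1] <- wt[k - 1] + wt[k]
      idx[[k - 1]] <- c(idx[[k - 1]], idx[[k]])
      k <- k - 1
    }
  }
  out <- numeric(n)
  for (b in seq_len(k)) out[idx[[b]]] <- val[b]
  out
}

#' Look up SPR values in a lookup table
#'
#' Piecewise-linear interpolation between nodes; CT numbers below
#' -1000 HU clamp to SPR 0; above the last node the final segment's slope
#' is extended.
#'
#' @param lut A `sect_lut`.
#' @param hu Numeric vector (or array) of CT numbers.
#' @return SPR values with the shape of `hu`.
#' @export
lut_lookup <- function(lut, hu) {
  x <- lut$hu; y <- lut$spr
  n <- length(x)
  v <- pmax(as.numeric(hu), x[1])
  out <- stats::approx(x, y, xout = pmin(v, x[n]))$y
  above <- v > x[n]
  if (any(above)) {
    out[above] <- y[n] + final_slope(lut) * (v[above] - x[n])
  }
  out[out < 0] <- 0
  if (!is.null(dim(hu))) dim(out) <- dim(hu)
  out
}

final_slope <- function(lut) {
  n <- nrow(lut)
  (lut$spr[n] - lut$spr[n - 1]) / (lut$hu[n] - lut$hu[n - 1])
}

#' Invert a lookup table (SPR to CT number)
#'
#' Returns the CT number whose forward lookup reproduces the requested
#' SPR; SPR plateaus (pooled nodes) invert to their left edge, and SPR
#' above the last node extrapolates with the final forward segment's
#' slope so forward and inverse extrapolation agree.
#'
#' @param lut A `sect_lut`.
#' @param spr Numeric vector (or array) of SPR values (>= 0).
#' @return CT numbers with the shape of `spr`.
#' @export
invert_lut <- function(lut, spr) {
  if (any(spr < 0)) stop("SPR must be non-negative")
  y <- lut$spr; x <- lut$hu
  # generalized inverse: interpolate within the rising segments of the
  # forward curve, then send exact plateau values to their left edge
  ri <- which(diff(y) > 0)
  if (!length(ri)) stop("lookup table is flat and cannot be inverted")
  y_lo <- y[ri]; y_hi <- y[ri + 1]; x_lo <- x[ri]; x_hi <- x[ri + 1]
  v <- as.numeric(spr)
  vc <- pmin(pmax(v, y_lo[1]), y_hi[length(ri)])
  seg <- pmin(pmax(findInterval(vc, y_lo), 1), length(ri))
  out <- x_lo[seg] + (vc - y_lo[seg]) / (y_hi[seg] - y_lo[seg]) *
    (x_hi[seg] - x_lo[seg])
  for (pv in unique(y[duplicated(y)])) {
    out[v == pv] <- x[match(pv, y)]
  }
  top <- v > max(y)
  if (any(top)) {
    fs <- final_slope(lut)
    if (fs <= 0) stop("SPR above the table range is unreachable (flat top)")
    out[top] <- x[nrow(lut)] + (v[top] - y[length(y)]) / fs
  }
  if (!is.null(dim(spr))) dim(out) <- dim(spr)
  out
}

#' Write / read a lookup table as CSV
#'
#' Two-column CSV (`hu`, `spr`) with `#`-prefixed metadata header lines.
#'
#' @param lut A `sect_lut`.
#' @param path File path.
#' @return `write_lut`: `path`, invisibly.  `read_lut`: a `sect_lut`.
#' @export
write_lut <- function(lut, path) {
  hdr <- c("# single-energy CT-number-to-SPR lookup table",
           sprintf("# tube: %s", attr(lut, "tube")),
           sprintf("# isotonic_adjusted: %s", attr(lut, "adjusted")),
           "hu,spr")
  writeLines(c(hdr, sprintf("%.10g,%.10g", lut$hu, lut$spr)), path)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  tube <- sub("^# tube: ", "", grep("^# tube:", meta, value = TRUE))
  adj <- identical(sub("^# isotonic_adjusted: ", "",
                       grep("^# isotonic_adjusted:", meta, value = TRUE)),
                   "TRUE")
  nodes <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  structure(nodes, class = c("sect_lut", "data.frame"),
            adjusted = adj, tube = tube)
}
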