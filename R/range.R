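# Water-equivalent path length, virtual range-pullback measurements and
# range-shift analysis.

#' Define a ray path through a volume
#'
#' @param entry Entry point, mm (length 3).
#' @param direction Direction vector (length 3; normalized internally).
#' @param step Sampling step, mm; `NULL` defaults to a quarter of the
#'   smallest voxel spacing of the volume a function is applied to.
#' @return An object of class `ray_path`.
#' @export
ray_path <- function(entry, direction, step = NULL) {
  n <- sqrt(sum(direction^2))
  if (!is.finite(n) || n < 1e-12) stop("degenerate ray direction")
  structure(list(entry = as.numeric(entry),
                 direction = as.numeric(direction) / n, step = step),
            class = "ray_path")
}

ray_step <- function(spr, ray) {
  if (!is.null(ray$step)) ray$step else 0.25 * min(spr$spacing)
}

# Nearest-voxel SPR values at distances t (mm) along the ray; 0 outside
# the grid.
sample_ray <- function(spr, ray, t) {
  d <- dim(spr$data)
  vals <- numeric(length(t))
  p <- outer(t, ray$direction)
  idx <- matrix(0L, length(t), 3)
  ok <- rep(TRUE, length(t))
  for (a in 1:3) {
    ia <- round((ray$entry[a] + p[, a] - spr$origin[a]) / spr$spacing[a]) + 1
    ok <- ok & ia >= 1 & ia <= d[a]
    idx[, a] <- ia
  }
  if (any(ok)) vals[ok] <- spr$data[idx[ok, , drop = FALSE]]
  vals
}

#' Water-equivalent path length along a ray
#'
#' Integrates the SPR along the ray over `[from, to]` mm with
#' piecewise-constant nearest-voxel sampling on a fixed cell grid anchored
#' at the ray entry, so the integral is exactly additive over
#' concatenated segments.  Samples outside the volume contribute 0.
#'
#' @param spr An [spr_volume()].
#' @param ray A [ray_path()].
#' @param depth Integration end, mm (used when `to` is missing).
#' @param from,to Segment bounds along the ray, mm.
#' @return Water-equivalent path length in mm.
#' @export
wepl_along_ray <- function(spr, ray, depth = NULL, from = 0, to = depth) {
  if (is.null(to)) stop("provide depth or to")
  stopifnot(to >= from, from >= 0)
  if (to == from) return(0)
  s <- ray_step(spr, ray)
  j1 <- floor(from / s) + 1
  j2 <- ceiling(to / s - 1e-12)
  j <- j1:j2
  overlap <- pmin(to, j * s) - pmax(from, (j - 1) * s)
  overlap[overlap < 0] <- 0
  mids <- (j - 0.5) * s
  sum(sample_ray(spr, ray, mids) * overlap)
}

#' SPR from a range-pullback measurement
#'
#' `SPR = (R_water - R_insert) / L_insert`: the water-equivalent
#' thickness a sample removes from the beam range, per unit physical
#' thickness.
#'
#' @param meas A list (or `range_measurement`) with `r_water`,
#'   `r_insert`, `l_insert` in mm.
#' @return Dimensionless SPR.
#' @export
spr_from_range_pullback <- function(meas) {
  if (meas$l_insert <= 0) stop("sample length must be positive")
  (meas$r_water - meas$r_insert) / meas$l_insert
}

#' Simulate a range-pullback measurement of a sample
#'
#' Virtual analog of inserting a sample into a beam and measuring the
#' residual range in water: the range with the sample in place is the
#' reference water range minus the sample segment's water-equivalent
#' path length.  By construction the pullback SPR equals the path-mean
#' SPR over the sample segment.
#'
#' @param spr An [spr_volume()] containing the sample.
#' @param ray A [ray_path()] crossing the sample.
#' @param sample_extent `c(start, end)` of the sample along the ray, mm.
#' @param beam A [beam_spec()] with a finite `water_range` (mm).
#' @return An object of class `range_measurement` with `r_water`,
#'   `r_insert`, `l_insert`.
#' @export
simulate_range_measurement <- function(spr, ray, sample_extent, beam) {
  if (is.null(beam$water_range) || !is.finite(beam$water_range)) {
    stop("beam must carry a finite water_range")
  }
  l <- sample_extent[2] - sample_extent[1]
  if (l <= 0) stop("sample extent must have positive length")
  w <- wepl_along_ray(spr, ray, from = sample_extent[1], to = sample_extent[2])
  if (w > beam$water_range) {
    stop("sample WEPL (", format(w), " mm) exceeds the beam water range; ",
         "the beam stops inside the sample")
  }
  structure(list(r_water = beam$water_range,
                 r_insert = beam$water_range - w, l_insert = l),
            class = "range_measurement")
}

# Depth (mm along ray) at which the cumulative WEPL reaches target.
wepl_crossing_depth <- function(spr, ray, target, max_depth) {
  s <- ray_step(spr, ray)
  n <- ceiling(max_depth / s)
  mids <- (seq_len(n) - 0.5) * s
  v <- sample_ray(spr, ray, mids)
  cum <- cumsum(v * s)
  hit <- which(cum >= target)
  if (!length(hit)) {
    stop("target WEPL ", format(target), " mm not reached within ",
         format(max_depth), " mm along the ray")
  }
  j <- hit[1]
  before <- if (j == 1) 0 else cum[j - 1]
  (j - 1) * s + (target - before) / v[j]
}

#' Range shift between two SPR maps along a ray
#'
#' Depth at which map `a` accumulates the target water-equivalent path
#' length minus the same depth for map `b`; positive when map `a` stops
#' the beam deeper (lower SPR along the path).  This is the dose-free
#' surrogate for a planning-system range comparison.
#'
#' @param spr_a,spr_b [spr_volume()]s on a common grid.
#' @param ray A [ray_path()].
#' @param target_wepl Target water-equivalent path length, mm.
#' @param max_depth Search limit along the ray, mm.
#' @return Range shift in mm (`depth_a - depth_b`).
#' @export
range_shift <- function(spr_a, spr_b, ray, target_wepl, max_depth = 1000) {
  if (!same_grid(spr_a, spr_b)) stop("SPR volumes are on different grids")
  wepl_crossing_depth(spr_a, ray, target_wepl, max_depth) -
    wepl_crossing_depth(spr_b, ray, target_wepl, max_depth)
}
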