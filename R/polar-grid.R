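# Polar-grid helpers shared by the topography, power-map and synthetic modules.
#
# Grid convention: matrices are indexed [azimuth, radial station]; azimuths in
# degrees counter-clockwise from +X (temporal side, right-eye convention),
# radial stations in mm from the topographer axis. Elevation z is corneal
# height in mm with the apex at z = 0 and +Z toward the device, so a surface
# point is (r cos(az), r sin(az), z).

#' Construct a polar sampling grid
#'
#' @param n_az number of azimuthal samples (uniform over \[0, 360) degrees)
#' @param n_r number of radial stations
#' @param r_max outermost station radius, mm
#' @param radii optional explicit station radii (strictly increasing), mm
#' @return object of class `polar_grid` with `azimuths` (deg) and `radii` (mm)
#' @export
polar_grid <- function(n_az = 300L, n_r = 333L, r_max = 5, radii = NULL) {
  if (is.null(radii)) {
    radii <- seq(0, r_max, length.out = n_r)
  }
  if (any(diff(radii) <= 0)) stop("radial positions must be strictly increasing")
  structure(
    list(
      azimuths = seq(0, 360, length.out = n_az + 1L)[seq_len(n_az)],
      radii = as.numeric(radii)
    ),
    class = "polar_grid"
  )
}

#' @exportS3Method base::print
print.polar_grid <- function(x, ...) {
  cat(sprintf(
    "<polar_grid> %d azimuths x %d radial stations, r in [%.3g, %.3g] mm\n",
    length(x$azimuths), length(x$radii), min(x$radii), max(x$radii)
  ))
  invisible(x)
}

#' Cartesian coordinates of every polar sample
#'
#' @param grid a [polar_grid()]
#' @return list with matrices `x`, `y` (n_az x n_r), mm
#' @export
polar_to_cartesian <- function(grid) {
  th <- grid$azimuths * pi / 180
  list(
    x = outer(cos(th), grid$radii),
    y = outer(sin(th), grid$radii)
  )
}

# Catmull-Rom (cubic convolution) interpolation of a uniformly sampled vector.
# Reproduces linear data exactly; used for tensor-grid resampling.
catmull_rom_1d <- function(y, xq_idx) {
  n <- length(y)
  # pad with linear extrapolation so edge queries stay well-defined
  yp <- c(2 * y[1] - y[2], y, 2 * y[n] - y[n - 1])
  i0 <- floor(xq_idx)
  t <- xq_idx - i0
  i0 <- pmin(pmax(i0, 1L), n - 1L)
  t <- xq_idx - i0
  p0 <- yp[i0]      # index i0-1 in original
  p1 <- yp[i0 + 1]
  p2 <- yp[i0 + 2]
  p3 <- yp[i0 + 3]
  0.5 * ((2 * p1) + (-p0 + p2) * t + (2 * p0 - 5 * p1 + 4 * p2 - p3) * t^2 +
    (-p0 + 3 * p1 - 3 * p2 + p3) * t^3)
}

# Periodic cubic interpolation across azimuth (rows) at arbitrary angles.
# `values`: n_az vector sampled at uniform azimuths starting at 0 deg.
periodic_catmull_rom <- function(values, az_deg) {
  n <- length(values)
  step <- 360 / n
  u <- (az_deg %% 360) / step          # fractional index in [0, n)
  i1 <- floor(u)
  t <- u - i1
  idx <- function(k) values[((i1 + k) %% n) + 1L]
  p0 <- idx(-1)
  p1 <- idx(0)
  p2 <- idx(1)
  p3 <- idx(2)
  0.5 * ((2 * p1) + (-p0 + p2) * t + (2 * p0 - 5 * p1 + 4 * p2 - p3) * t^2 +
    (-p0 + 3 * p1 - 3 * p2 + p3) * t^3)
}

# Bicubic (separable Catmull-Rom, periodic in azimuth) sampling of a polar
# field at scattered Cartesian points. Invalid (NA) entries propagate.
interp_polar_field <- function(grid, values, xq, yq) {
  r <- sqrt(xq^2 + yq^2)
  az <- (atan2(yq, xq) * 180 / pi) %% 360
  n_az <- length(grid$azimuths)
  out <- rep(NA_real_, length(xq))
  ok <- r <= max(grid$radii) + 1e-12
  if (!any(ok)) return(out)
  # radial fractional index (grid may be non-uniform): invert by approx
  ridx <- approx(grid$radii, seq_along(grid$radii), xout = pmin(r[ok], max(grid$radii)),
    rule = 2
  )$y
  azq <- az[ok]
  # stage 1: for the 4 radial neighbours do periodic azimuthal interpolation,
  # then Catmull-Rom radially. Implemented pointwise over unique station bins.
  res <- numeric(sum(ok))
  i0 <- pmin(pmax(floor(ridx), 1L), length(grid$radii) - 1L)
  t <- ridx - i0
  vals_at <- function(j) { # azimuthal interpolation at station column j (clamped)
    j <- pmin(pmax(j, 1L), length(grid$radii))
    # group queries by column to vectorise
    v <- numeric(length(azq))
    for (jj in unique(j)) {
      sel <- which(j == jj)
      v[sel] <- periodic_catmull_rom(values[, jj], azq[sel])
    }
    v
  }
  p0 <- vals_at(i0 - 1L)
  p1 <- vals_at(i0)
  p2 <- vals_at(i0 + 1L)
  p3 <- vals_at(i0 + 2L)
  res <- 0.5 * ((2 * p1) + (-p0 + p2) * t + (2 * p0 - 5 * p1 + 4 * p2 - p3) * t^2 +
    (-p0 + 3 * p1 - 3 * p2 + p3) * t^3)
  out[ok] <- res
  out
}
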