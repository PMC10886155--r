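# Surface extension: a low-order Zernike fit fills uncovered samples out to
# the limbal radius, measured samples are retained verbatim, and a
# tangent-continuous scleral arc continues every meridian beyond the limbus.

#' Extend a measured topography to the model rim
#'
#' Fits Zernike polynomials of radial order <= 3 (10 Noll modes) to the valid
#' samples, fills every uncovered sample out to `rim_radius`, keeps measured
#' samples bit-identical, and continues each meridian beyond the rim with a
#' circular arc tangent-matched at the rim (parametric scleral continuation).
#'
#' @param record a [topo_record()]
#' @param rim_radius limbal reconstruction radius, mm (default 5.5)
#' @param extend_to lateral radius of the extension, mm (default 10.5: the
#'   anterior eye model uses at least 2.5 mm beyond the limbus; the arc
#'   cannot continue past the globe equator, which caps the extent)
#' @param scleral_radius meridional radius of the scleral arc, mm; `Inf`
#'   continues each meridian along its rim tangent
#' @param min_points_per_mode minimum valid samples per Zernike mode
#' @param scleral_step radial sampling of the extension, mm
#' @return object of class `extended_surface`: a structured polar field with
#'   `elevation` (n_az x n_station), `grid`, and a `provenance` matrix with
#'   labels "measured", "zernike" or "scleral"
#' @export
extend_surface <- function(record, rim_radius = 5.5, extend_to = 8.5,
                           scleral_radius = 12, min_points_per_mode = 10L,
                           scleral_step = 0.05) {
  stopifnot(inherits(record, "topo_record"))
  n_modes <- 10L
  n_valid <- sum(record$coverage)
  if (n_valid < min_points_per_mode * n_modes) {
    stop(
      "rank-deficient Zernike fit: ", n_valid, " valid points < ",
      min_points_per_mode * n_modes, " required for ", n_modes, " modes"
    )
  }
  az_rad <- record$grid$azimuths * pi / 180
  r_meas <- record$grid$radii
  rho <- outer(rep(1, length(az_rad)), r_meas) / rim_radius
  th <- outer(az_rad, rep(1, length(r_meas)))
  ok <- record$coverage
  A <- zernike_design(rho[ok], th[ok], n_modes)
  fit <- qr(A)
  if (fit$rank < n_modes) {
    stop("rank-deficient Zernike fit: valid samples do not constrain all ",
      n_modes, " modes")
  }
  coefs <- qr.coef(fit, record$elevation[ok])

  # station layout: measured stations inside the rim, densified Zernike
  # stations up to the rim, then scleral stations out to the model rim
  r_in <- r_meas[r_meas <= rim_radius + 1e-12]
  r_gap <- if (max(r_in) < rim_radius - 1e-9) {
    gp <- seq(min(max(r_in) + scleral_step, rim_radius), rim_radius, by = scleral_step)
    if (max(gp) < rim_radius - 1e-9) gp <- c(gp, rim_radius)
    gp
  } else {
    numeric(0)
  }
  r_scl <- seq(rim_radius + scleral_step, extend_to, by = scleral_step)
  if (max(r_scl) < extend_to - 1e-9) r_scl <- c(r_scl, extend_to)
  radii_ext <- c(r_in, r_gap, r_scl)
  n_az <- length(az_rad)
  n_st <- length(radii_ext)
  elev <- matrix(NA_real_, n_az, n_st)
  prov <- matrix("zernike", n_az, n_st)

  zern_eval <- function(r, theta) {
    drop(zernike_design(r / rim_radius, theta, n_modes) %*% coefs)
  }
  # Zernike fill inside the rim
  in_idx <- seq_len(length(r_in) + length(r_gap))
  for (i in seq_len(n_az)) {
    elev[i, in_idx] <- zern_eval(radii_ext[in_idx], rep(az_rad[i], length(in_idx)))
  }
  # measured samples retained verbatim
  meas_cols <- seq_along(r_in)
  elev[, meas_cols][ok[, seq_along(r_in)]] <-
    record$elevation[, seq_along(r_in)][ok[, seq_along(r_in)]]
  prov[, meas_cols][ok[, seq_along(r_in)]] <- "measured"

  # scleral continuation: per-meridian circle tangent-matched at the rim
  h <- 1e-5
  z_rim <- zern_eval(rep(rim_radius, n_az), az_rad)
  dz_rim <- (zern_eval(rep(rim_radius, n_az), az_rad) -
    zern_eval(rep(rim_radius - h, n_az), az_rad)) / h
  scl_idx <- seq(length(in_idx) + 1L, n_st)
  for (i in seq_len(n_az)) {
    zp <- dz_rim[i]
    if (is.finite(scleral_radius)) {
      nrm <- sqrt(1 + zp^2)
      rc <- rim_radius + scleral_radius * zp / nrm
      zc <- z_rim[i] - scleral_radius / nrm
      arg <- scleral_radius^2 - (radii_ext[scl_idx] - rc)^2
      if (any(arg <= 0)) {
        stop("scleral arc of radius ", scleral_radius,
          " mm cannot reach the model rim at ", extend_to, " mm")
      }
      elev[i, scl_idx] <- zc + sqrt(arg)
    } else {
      elev[i, scl_idx] <- z_rim[i] + zp * (radii_ext[scl_idx] - rim_radius)
    }
  }
  prov[, scl_idx] <- "scleral"

  structure(
    list(
      elevation = elev,
      grid = polar_grid(n_az, n_st, radii = radii_ext),
      provenance = prov,
      coefs = coefs,
      rim_radius = rim_radius,
      meta = record$meta
    ),
    class = "extended_surface"
  )
}

#' @exportS3Method base::print
print.extended_surface <- function(x, ...) {
  cat(sprintf(
    "<extended_surface> %d x %d polar field to %.2f mm (%.0f%% measured)\n",
    nrow(x$elevation), ncol(x$elevation), max(x$grid$radii),
    100 * mean(x$provenance == "measured")
  ))
  invisible(x)
}

#' Point cloud of an extended surface
#'
#' @param ext an [extend_surface()] result
#' @param max_r optional lateral radius cut, mm
#' @return tibble with `x`, `y`, `z` (mm) and `provenance`
#' @export
surface_points <- function(ext, max_r = NULL) {
  xy <- polar_to_cartesian(ext$grid)
  keep <- if (is.null(max_r)) {
    rep(TRUE, length(xy$x))
  } else {
    outer(rep(TRUE, nrow(ext$elevation)), ext$grid$radii <= max_r + 1e-12)
  }
  tibble(
    x = xy$x[keep], y = xy$y[keep], z = ext$elevation[keep],
    provenance = ext$provenance[keep]
  )
}
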