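# Tangential curvature / power maps and the refractive power change (RPC).
#
# Tangential (instantaneous) curvature is the meridional curvature of the
# radial elevation profile: Rt(r) = (1 + z'(r)^2)^(3/2) / |z''(r)|, evaluated
# per semi-meridian with centered finite differences; profiles are extended
# through the apex using the opposite semi-meridian so the map centre is
# well-defined.

#' Power-map configuration
#'
#' @param nh hypothetical corneal refractive index (default 1.3375)
#' @param nair refractive index of air (default 1.0)
#' @param smoothing_factor discretized-spline smoothing factor (default 4.5)
#' @return object of class `power_map_config`
#' @export
power_map_config <- function(nh = 1.3375, nair = 1.0, smoothing_factor = 4.5) {
  if (!(nh > nair) || nair < 1) stop("need nh > nair >= 1")
  structure(list(nh = nh, nair = nair, smoothing_factor = smoothing_factor),
    class = "power_map_config"
  )
}

# Generic polar map container (curvature in mm or power in dioptres).
polar_map <- function(values, grid, unit) {
  structure(
    list(values = values, valid = is.finite(values), grid = grid, unit = unit),
    class = "polar_map"
  )
}

#' @exportS3Method base::print
print.polar_map <- function(x, ...) {
  rng <- range(x$values[x$valid])
  cat(sprintf(
    "<polar_map> %d x %d [%s], range %.4g .. %.4g (%.1f%% valid)\n",
    nrow(x$values), ncol(x$values), x$unit, rng[1], rng[2], 100 * mean(x$valid)
  ))
  invisible(x)
}

# Nonuniform centered finite differences along a profile; returns d1, d2.
profile_derivs <- function(r, z) {
  n <- length(r)
  d1 <- rep(NA_real_, n)
  d2 <- rep(NA_real_, n)
  if (n < 3) return(list(d1 = d1, d2 = d2))
  i <- 2:(n - 1)
  h1 <- r[i] - r[i - 1]
  h2 <- r[i + 1] - r[i]
  d1[i] <- (-h2 / (h1 * (h1 + h2))) * z[i - 1] +
    ((h2 - h1) / (h1 * h2)) * z[i] +
    (h1 / (h2 * (h1 + h2))) * z[i + 1]
  d2[i] <- 2 * (z[i - 1] / (h1 * (h1 + h2)) - z[i] / (h1 * h2) +
    z[i + 1] / (h2 * (h1 + h2)))
  list(d1 = d1, d2 = d2)
}

#' Tangential curvature map
#'
#' @param surface a [topo_record()] or [extend_surface()] result
#' @param flat_tol curvature below which a point is marked invalid (flat)
#'   rather than given an unbounded radius, 1/mm
#' @return a `polar_map` of tangential radii Rt in mm
#' @export
tangential_curvature_map <- function(surface, flat_tol = 1e-9) {
  elev <- surface$elevation
  grid <- surface$grid
  valid <- if (!is.null(surface$coverage)) surface$coverage else is.finite(elev)
  n_az <- nrow(elev)
  if (n_az %% 2 != 0) stop("tangential curvature needs an even azimuth count")
  rt <- matrix(NA_real_, n_az, ncol(elev))
  r <- grid$radii
  half <- n_az / 2
  has_center <- abs(r[1]) < 1e-12
  for (a in seq_len(half)) {
    b <- a + half
    # full diameter profile through the apex: reversed opposite meridian,
    # then this meridian (dropping a duplicated r = 0 sample)
    rb <- if (has_center) rev(-r[-1]) else rev(-r)
    zb <- if (has_center) rev(elev[b, -1]) else rev(elev[b, ])
    vb <- if (has_center) rev(valid[b, -1]) else rev(valid[b, ])
    rr <- c(rb, r)
    zz <- c(zb, elev[a, ])
    vv <- c(vb, valid[a, ]) & is.finite(zz)
    idx_a <- seq(length(rb) + 1L, length(rr)) # samples of meridian a
    idx_b <- rev(seq_len(length(rb)))         # samples of meridian b (r>0)
    if (sum(vv) < 3) next
    rv <- rr[vv]
    zv <- zz[vv]
    d <- profile_derivs(rv, zv)
    kappa <- abs(d$d2) / (1 + d$d1^2)^1.5
    rt_prof <- rep(NA_real_, length(rr))
    rt_prof[vv] <- ifelse(kappa > flat_tol, (1 + d$d1[]^2)^1.5 / abs(d$d2), NA_real_)
    rt[a, ] <- rt_prof[idx_a]
    if (has_center) {
      rt[b, ] <- c(rt_prof[idx_a[1]], rt_prof[idx_b])
    } else {
      rt[b, ] <- rt_prof[idx_b]
    }
  }
  polar_map(rt, grid, "mm")
}

#' Tangential power map (reduced Gaussian optics)
#'
#' `Pt = (nh - nair) / Rt` with `Rt` in metres, giving dioptres.
#'
#' @param curv tangential curvature map (`polar_map`, mm)
#' @param cfg a [power_map_config()]
#' @return a `polar_map` of powers in dioptres
#' @export
tangential_power_map <- function(curv, cfg = power_map_config()) {
  stopifnot(inherits(curv, "polar_map"), curv$unit == "mm")
  rt <- curv$values
  p <- (cfg$nh - cfg$nair) / (rt / 1000)
  p[!is.finite(p) | rt <= 0] <- NA_real_
  polar_map(p, curv$grid, "D")
}

#' Smooth a polar power map
#'
#' Applies the DCT-based discretized smoothing spline with the configured
#' smoothing factor; see [smooth_map_values()].
#'
#' @param map a `polar_map`
#' @param cfg a [power_map_config()] (its `smoothing_factor` is used)
#' @param robust use robust (iteratively reweighted) smoothing
#' @return a smoothed `polar_map`
#' @export
smooth_map <- function(map, cfg = power_map_config(), robust = FALSE) {
  stopifnot(inherits(map, "polar_map"))
  sm <- smooth_map_values(map$values, s = cfg$smoothing_factor, robust = robust)
  polar_map(sm, map$grid, map$unit)
}

#' Refractive power change (RPC) map
#'
#' Elementwise post-wear minus pre-wear tangential power on the intersection
#' of the two validity masks.
#'
#' @param pre,post tangential power maps (`polar_map`, dioptres) on one grid
#' @return a `polar_map` of power change, dioptres
#' @export
rpc_map <- function(pre, post) {
  stopifnot(inherits(pre, "polar_map"), inherits(post, "polar_map"))
  if (!isTRUE(all.equal(pre$grid, post$grid))) {
    stop("pre and post power maps are on different grids")
  }
  d <- post$values - pre$values
  d[!(pre$valid & post$valid)] <- NA_real_
  out <- polar_map(d, pre$grid, "D")
  class(out) <- c("rpc_polar_map", class(out))
  out
}

#' Full topography-to-power pipeline
#'
#' Convenience wrapper: curvature, power, then smoothing.
#'
#' @param surface a [topo_record()] or extended surface
#' @param cfg a [power_map_config()]
#' @param smooth apply the discretized-spline smoother (default TRUE)
#' @return a `polar_map` of tangential power, dioptres
#' @export
power_map_pipeline <- function(surface, cfg = power_map_config(), smooth = TRUE) {
  p <- tangential_power_map(tangential_curvature_map(surface), cfg)
  if (smooth) p <- smooth_map(p, cfg)
  p
}
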