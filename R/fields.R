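# Field extraction from FEA results and resampling onto the common
# -8..8 mm Cartesian analysis grid.

#' The common Cartesian analysis grid
#'
#' Square grid from -8 to 8 mm in steps of 0.1 mm (161 x 161), with an
#' analysis mask (default: the 5.5 mm corneal disc).
#'
#' @param half_extent mm (default 8)
#' @param step mm (default 0.1)
#' @param mask_radius analysis-disc radius, mm (default 5.5)
#' @return object of class `common_grid`
#' @export
common_grid <- function(half_extent = 8, step = 0.1, mask_radius = 5.5) {
  x <- seq(-half_extent, half_extent, by = step)
  if (abs(utils::tail(x, 1) - half_extent) > 1e-9) {
    stop("half_extent must be a multiple of step")
  }
  gx <- outer(x, rep(1, length(x)))
  gy <- outer(rep(1, length(x)), x)
  structure(
    list(
      x = x, y = x, step = step,
      mask = sqrt(gx^2 + gy^2) <= mask_radius + 1e-12,
      mask_radius = mask_radius
    ),
    class = "common_grid"
  )
}

grid_map <- function(values, grid, unit = "", component = "") {
  structure(
    list(
      values = values, grid = grid, unit = unit, component = component,
      mask = grid$mask & is.finite(values)
    ),
    class = "grid_map"
  )
}

#' @exportS3Method base::print
print.grid_map <- function(x, ...) {
  rng <- range(x$values[x$mask])
  cat(sprintf(
    "<grid_map> %dx%d [%s]%s, range %.4g .. %.4g\n",
    nrow(x$values), ncol(x$values), x$unit,
    if (nzchar(x$component)) paste0(" ", x$component) else "",
    rng[1], rng[2]
  ))
  invisible(x)
}

#' Resample scattered surface values onto the common grid
#'
#' Mesh-facet interpolation: each grid point is located in the quad facets of
#' the source surface (in plan view) and interpolated isoparametrically,
#' which reproduces linear fields exactly; points outside the source surface
#' are invalid, never extrapolated. Polar maps are resampled by separable
#' cubic interpolation instead.
#'
#' @param map either a `polar_map`, or a list with `points` (n x 3 positions)
#'   `values` (n) and `facets` (quad connectivity)
#' @param grid a [common_grid()]
#' @param unit,component labels for the result
#' @return a `grid_map`
#' @export
resample_to_grid <- function(map, grid = common_grid(), unit = "", component = "") {
  gx <- outer(grid$x, rep(1, length(grid$y)))
  gy <- outer(rep(1, length(grid$x)), grid$y)
  if (inherits(map, "polar_map")) {
    vals <- map$values
    vals[!map$valid] <- NA_real_
    v <- interp_polar_field(map$grid, vals, gx, gy)
    # invalidate queries whose nearest polar samples are invalid
    v[is.nan(v)] <- NA_real_
    out <- matrix(v, nrow(gx), ncol(gx))
    return(grid_map(out, grid, if (nzchar(unit)) unit else map$unit, component))
  }
  if (is.null(map$points) || is.null(map$values) || is.null(map$facets)) {
    stop("map must be a polar_map or a list with points, values and facets")
  }
  if (nrow(map$points) < 3) stop("fewer than 3 source points")
  v <- facet_interpolate_xy(
    as.matrix(map$points), map$facets, as.numeric(map$values),
    as.vector(gx), as.vector(gy)
  )
  grid_map(matrix(v, nrow(gx), ncol(gx)), grid, unit, component)
}

#' Normalise a map to \[-1, 1\]
#'
#' Divides by the maximum absolute value over the analysis mask; the sign
#' pattern is preserved exactly. Idempotent.
#'
#' @param map a `grid_map`
#' @return normalised `grid_map`
#' @export
normalize_map <- function(map) {
  stopifnot(inherits(map, "grid_map"))
  mx <- max(abs(map$values[map$mask]), na.rm = TRUE)
  if (!is.finite(mx) || mx == 0) {
    warning("all-zero map: returned unchanged")
    map$normalized <- TRUE
    return(map)
  }
  map$values <- map$values / mx
  map$normalized <- TRUE
  map
}

voigt_invariants <- function(sig) {
  # sig: n x 6 (xx, yy, zz, xy, yz, zx), MPa
  tr <- sig[, 1] + sig[, 2] + sig[, 3]
  p <- -tr / 3
  sxx <- sig[, 1] + p
  syy <- sig[, 2] + p
  szz <- sig[, 3] + p
  mises <- sqrt(1.5 * (sxx^2 + syy^2 + szz^2 +
    2 * (sig[, 4]^2 + sig[, 5]^2 + sig[, 6]^2)))
  maxp <- vapply(seq_len(nrow(sig)), function(i) {
    S <- matrix(c(
      sig[i, 1], sig[i, 4], sig[i, 6],
      sig[i, 4], sig[i, 2], sig[i, 5],
      sig[i, 6], sig[i, 5], sig[i, 3]
    ), 3, 3)
    max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  }, 0)
  list(mises = mises, pressure = p, max_principal = maxp)
}

max_principal_log_strain <- function(hgrad) {
  # hgrad: n x 9 row-major displacement gradient H; F = I + H; ln V
  vapply(seq_len(nrow(hgrad)), function(i) {
    H <- matrix(hgrad[i, ], 3, 3, byrow = TRUE)
    FF <- diag(3) + H
    B <- FF %*% t(FF)
    ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
    max(0.5 * log(pmax(ev, 1e-300)))
  }, 0)
}

#' Extract a barometer field on the anterior eye surface
#'
#' Components: `contact_pressure` (kPa), `mises` (kPa), `pressure`
#' (kPa, positive in compression, -tr(sigma)/3), `max_principal_stress`
#' (kPa), `max_principal_log_strain` (unitless, from the left stretch of
#' the deformation gradient), `displacement_mag` (mm).
#'
#' Element quadrature means are volume-averaged to the anterior surface
#' nodes; the stress invariant is evaluated on the averaged tensor.
#'
#' @param result a [run_load_program()] result
#' @param component one of the barometer names above
#' @return list with `points` (anterior node positions), `values`, `facets`
#'   (anterior surface quads), `unit` — ready for [resample_to_grid()]
#' @export
extract_field <- function(result,
                          component = c(
                            "contact_pressure", "mises", "pressure",
                            "max_principal_stress",
                            "max_principal_log_strain", "displacement_mag"
                          )) {
  component <- match.arg(component)
  asm <- result$assembly
  ant <- asm$nsets$anterior_nodes
  pts <- asm$nodes[ant, , drop = FALSE]
  facets_local <- asm$comps$cornea$meta$anterior_quads
  unit <- "kPa"
  if (component == "displacement_mag") {
    vals <- sqrt(rowSums(result$u[ant, , drop = FALSE]^2))
    unit <- "mm"
  } else if (component == "max_principal_log_strain") {
    corn <- which(asm$elem_comp == "cornea")
    ev <- max_principal_log_strain(result$hgrad[corn, , drop = FALSE])
    vals <- elements_to_nodes_subset(asm, ev, result$volumes[corn], corn, ant)
    unit <- "unitless"
  } else if (component == "contact_pressure") {
    vals <- contact_pressure_on_master(result, ant) * 1000
  } else {
    # average the stress tensor to nodes, then take the invariant
    corn <- which(asm$elem_comp == "cornea")
    sig_n <- vapply(1:6, function(k) {
      elements_to_nodes_subset(
        asm, result$stress[corn, k], result$volumes[corn], corn, ant
      )
    }, numeric(length(ant)))
    inv <- voigt_invariants(sig_n)
    vals <- switch(component,
      mises = inv$mises,
      pressure = inv$pressure,
      max_principal_stress = inv$max_principal
    ) * 1000
  }
  list(
    points = pts, values = vals, facets = facets_local, unit = unit,
    component = component
  )
}

elements_to_nodes_subset <- function(assembly, evals, vols, elem_ids, node_ids) {
  el <- assembly$elems[elem_ids, , drop = FALSE]
  ids <- as.vector(el)
  w <- rep(vols, 8L)
  v <- rep(evals, 8L)
  num <- rowsum(w * v, ids)
  den <- rowsum(w, ids)
  out <- rep(NA_real_, nrow(assembly$nodes))
  out[as.integer(rownames(num))] <- num[, 1] / den[, 1]
  out[node_ids]
}

# normal contact traction on the cornea anterior nodes, MPa
contact_pressure_on_master <- function(result, ant_ids) {
  asm <- result$assembly
  n <- nrow(asm$nodes)
  fnode <- numeric(n)
  for (pr_name in names(result$contact$pairs)) {
    pr <- result$contact$pairs[[pr_name]]
    spec <- NULL
    for (cp in asm$contact_pairs) if (cp$name == pr_name) spec <- cp
    if (is.null(spec)) next
    if (!identical(pr_name, "lens_on_cornea") &&
      !identical(pr_name, "eyelid_on_cornea")) {
      next
    }
    act <- pr$active
    if (!length(act)) next
    mf <- spec$master_facets[pr$facet[act], , drop = FALSE]
    w <- pr$weights[act, , drop = FALSE]
    fn <- pr$force_n[act]
    for (k in 1:4) {
      acc <- rowsum(w[, k] * fn, mf[, k])
      idx <- as.integer(rownames(acc))
      fnode[idx] <- fnode[idx] + acc[, 1]
    }
  }
  areas <- facet_node_areas(asm$nodes, asm$facets$anterior_surface)
  tr <- rep(0, length(ant_ids))
  ok <- areas[ant_ids] > 0
  tr[ok] <- fnode[ant_ids][ok] / areas[ant_ids][ok]
  tr
}

#' RPC predicted by the FEA
#'
#' Builds pre- and post-wear anterior surface height maps from the FEA nodal
#' positions and displacements (the lens-wear stages only; the inflated
#' measured geometry is the pre-wear reference) by moving-least-squares
#' quadratic resampling, runs the tangential power pipeline on both and
#' returns their difference.
#'
#' @param result a [run_load_program()] result
#' @param cfg a [power_map_config()]
#' @param n_az,n_r polar resampling resolution
#' @param max_r map radius, mm
#' @return an RPC `polar_map`
#' @export
fea_rpc <- function(result, cfg = power_map_config(), n_az = 120L, n_r = 160L,
                    max_r = 5.0) {
  asm <- result$assembly
  ant <- asm$nsets$anterior_nodes
  facets <- asm$comps$cornea$meta$anterior_quads
  pre_pts <- asm$nodes[ant, , drop = FALSE]
  post_pts <- pre_pts + result$u[ant, , drop = FALSE]
  grid <- polar_grid(n_az, n_r, r_max = max_r)
  xy <- polar_to_cartesian(grid)
  # Tangential power needs curvature-faithful heights, so the pre-wear
  # surface and the (small, smooth) lens-induced shape change are resampled
  # separately with moving-least-squares quadratics; differencing two
  # independently resampled surfaces would drown the signal in resampling
  # noise. The nodal shape change at fixed (x, y) linearises the nodal
  # displacement through the local surface slope.
  u_ant <- result$u[ant, , drop = FALSE]
  # nodal slopes from local quadratic fits linearise the nodal displacement
  # into a height change at fixed (x, y)
  node_fit <- mls_quadratic_fit(pre_pts, pre_pts[, 1], pre_pts[, 2])
  delta_node <- u_ant[, 3] - u_ant[, 1] * node_fit[, 2] - u_ant[, 2] * node_fit[, 3]
  qfit <- mls_quadratic_fit(pre_pts, as.vector(xy$x), as.vector(xy$y))
  z_pre <- qfit[, 1]
  dq <- mls_quadratic_fit(
    cbind(pre_pts[, 1], pre_pts[, 2], delta_node),
    as.vector(xy$x), as.vector(xy$y)
  )
  z_post <- z_pre + dq[, 1]
  rec <- function(z) {
    topo_record(matrix(z, n_az, n_r), grid)
  }
  p_pre <- power_map_pipeline(rec(z_pre), cfg)
  p_post <- power_map_pipeline(rec(z_post), cfg)
  rpc_map(p_pre, p_post)
}

#' Export a field to CSV
#'
#' Node id, position and value with full double precision.
#'
#' @param field an [extract_field()] result
#' @param path output CSV
#' @return `path` invisibly
#' @export
write_field_csv <- function(field, path) {
  df <- data.frame(
    node = seq_len(nrow(field$points)),
    x = sprintf("%.17g", field$points[, 1]),
    y = sprintf("%.17g", field$points[, 2]),
    z = sprintf("%.17g", field$points[, 3]),
    value = sprintf("%.17g", field$values)
  )
  names(df)[5] <- field$component
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
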