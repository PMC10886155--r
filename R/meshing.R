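# Hexahedral meshing: the hex_mesh container, the butterfly (O-grid) disk
# template, nonparametric spherical-interpolation meshing of the anterior
# eye, profile-revolve meshing of the lens, and a cubed-sphere shell used
# for solver verification.

#' Hexahedral mesh container
#'
#' @param nodes numeric n x 3 matrix, mm
#' @param elems integer ne x 8 matrix of 1-based node indices (trilinear hex
#'   ordering: bottom face counter-clockwise, then top face)
#' @param nsets named list of node-index vectors
#' @param facets named list of oriented quad facets (m x 4 node indices,
#'   outward normal by the right-hand rule)
#' @param meta free-form metadata list
#' @return object of class `hex_mesh`
#' @export
hex_mesh <- function(nodes, elems, nsets = list(), facets = list(), meta = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  stopifnot(ncol(nodes) == 3, ncol(elems) == 8)
  if (max(elems) > nrow(nodes) || min(elems) < 1) stop("element indices out of range")
  structure(
    list(nodes = nodes, elems = elems, nsets = nsets, facets = facets, meta = meta),
    class = "hex_mesh"
  )
}

#' @exportS3Method base::print
print.hex_mesh <- function(x, ...) {
  cat(sprintf(
    "<hex_mesh> %d nodes, %d hex8 elements%s\n",
    nrow(x$nodes), nrow(x$elems),
    if (!is.null(x$meta$component)) paste0(" (", x$meta$component, ")") else ""
  ))
  if (length(x$nsets)) {
    cat("  node sets: ", paste(names(x$nsets), collapse = ", "), "\n", sep = "")
  }
  if (length(x$facets)) {
    cat("  facet sets: ", paste(names(x$facets), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Minimum Jacobian determinant per element at the 2x2x2 quadrature points.
hex_min_jacobians <- function(mesh) {
  hex8_min_detj(mesh$nodes, mesh$elems)
}

#' Validate a hex mesh
#'
#' Checks positive Jacobians at all quadrature points, absence of duplicate
#' nodes, and that the outer boundary is watertight (every boundary-facet
#' edge shared by exactly two boundary facets).
#'
#' @param mesh a [hex_mesh()]
#' @param tol duplicate-node tolerance, mm
#' @return invisible TRUE; stops with a diagnostic otherwise
#' @export
mesh_check <- function(mesh, tol = 1e-9) {
  bad <- which(hex_min_jacobians(mesh) <= 0)
  if (length(bad)) {
    stop("non-positive Jacobians in elements: ", paste(head(bad, 10), collapse = ", "))
  }
  key <- paste(
    round(mesh$nodes[, 1] / tol), round(mesh$nodes[, 2] / tol),
    round(mesh$nodes[, 3] / tol)
  )
  if (anyDuplicated(key)) stop("duplicate nodes within ", tol, " mm")
  bf <- boundary_facets(mesh)
  ed <- rbind(
    bf[, c(1, 2)], bf[, c(2, 3)], bf[, c(3, 4)], bf[, c(4, 1)]
  )
  ekey <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(ekey)
  if (any(cnt != 2)) stop("boundary surface is not watertight")
  invisible(TRUE)
}

# Facets of element faces that appear exactly once (the outer boundary).
# Local faces of the hex (outward-oriented for a positive-Jacobian element).
hex_face_ids <- rbind(
  c(1, 4, 3, 2), # bottom
  c(5, 6, 7, 8), # top
  c(1, 2, 6, 5),
  c(2, 3, 7, 6),
  c(3, 4, 8, 7),
  c(4, 1, 5, 8)
)

boundary_facets <- function(mesh) {
  el <- mesh$elems
  faces <- do.call(rbind, lapply(seq_len(nrow(hex_face_ids)), function(f) {
    el[, hex_face_ids[f, ], drop = FALSE]
  }))
  key <- apply(faces, 1L, function(r) paste(sort(r), collapse = "-"))
  once <- names(which(table(key) == 1))
  faces[key %in% once, , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Butterfly / O-grid disk template: central b x b structured patch surrounded
# by `rings` concentric rings of 4b elements each.

squircle_map <- function(u, v) {
  cbind(u * sqrt(1 - v^2 / 2), v * sqrt(1 - u^2 / 2))
}

#' O-grid (butterfly) disk template
#'
#' @param base element base `b`: the central patch is b x b elements
#' @param rings number of surrounding rings
#' @return list: `xy` (param coordinates in the unit disc), `quads`
#'   (counter-clockwise), `rings` (list of node-id loops, innermost =
#'   patch boundary), `param_radius` per node
#' @export
disk_ogrid <- function(base = 4L, rings = 30L) {
  b <- as.integer(base)
  stopifnot(b >= 2, rings >= 1)
  rho0 <- max(0.2, b / (b + rings))
  u <- seq(-1, 1, length.out = b + 1L)
  pid <- matrix(seq_len((b + 1L)^2), b + 1L, b + 1L)
  UV <- cbind(rep(u, b + 1L), rep(u, each = b + 1L))
  xy <- rho0 * squircle_map(UV[, 1], UV[, 2])
  quads <- matrix(0L, b^2, 4L)
  q <- 0L
  for (j in seq_len(b)) {
    for (i in seq_len(b)) {
      q <- q + 1L
      quads[q, ] <- c(pid[i, j], pid[i + 1L, j], pid[i + 1L, j + 1L], pid[i, j + 1L])
    }
  }
  # patch boundary loop, counter-clockwise starting at corner (-1, -1)
  loop0 <- c(
    pid[1:b, 1],
    pid[b + 1L, 1:b],
    pid[(b + 1L):2, b + 1L],
    pid[1L, (b + 1L):2]
  )
  th0 <- atan2(xy[loop0, 2], xy[loop0, 1])
  n_loop <- length(loop0) # 4b
  # uniform target angles, same starting direction, strictly increasing
  th_start <- th0[1]
  th_unif <- th_start + 2 * pi * (seq_len(n_loop) - 1L) / n_loop
  th0_mono <- th0
  for (k in 2:n_loop) {
    while (th0_mono[k] < th0_mono[k - 1]) th0_mono[k] <- th0_mono[k] + 2 * pi
  }
  loops <- list(loop0)
  next_id <- (b + 1L)^2
  for (k in seq_len(rings)) {
    t <- k / rings
    th <- (1 - t) * th0_mono + t * th_unif
    rho <- rho0 + (1 - rho0) * k / rings
    ids <- next_id + seq_len(n_loop)
    next_id <- next_id + n_loop
    xy <- rbind(xy, cbind(rho * cos(th), rho * sin(th)))
    inner <- loops[[k]]
    nq <- matrix(0L, n_loop, 4L)
    for (j in seq_len(n_loop)) {
      jn <- if (j == n_loop) 1L else j + 1L
      nq[j, ] <- c(inner[j], ids[j], ids[jn], inner[jn])
    }
    quads <- rbind(quads, nq)
    loops[[k + 1L]] <- ids
  }
  list(
    xy = xy, quads = quads, rings = loops,
    param_radius = sqrt(rowSums(xy^2))
  )
}

# Extrude a disk template's two (or more) node sheets into stacked hexes.
stack_sheets_to_hex <- function(quads, n_sheet_nodes, layers) {
  ne <- nrow(quads)
  elems <- matrix(0L, ne * layers, 8L)
  for (l in seq_len(layers)) {
    off_b <- (l - 1L) * n_sheet_nodes
    off_t <- l * n_sheet_nodes
    rows <- (l - 1L) * ne + seq_len(ne)
    elems[rows, ] <- cbind(quads + off_b, quads + off_t)
  }
  elems
}

# ---------------------------------------------------------------------------
# Spherical-interpolation template mapping

#' Map a surface onto template directions by spherical interpolation
#'
#' Converts a structured polar surface into spherical coordinates about an
#' interior origin and cubically interpolates its radius at each queried
#' (azimuth, polar-angle) direction: first along each meridian, then
#' periodically across azimuth.
#'
#' @param ext an [extend_surface()] result (structured polar surface)
#' @param azimuth,polar query directions, radians (polar angle from +Z)
#' @param origin 3-vector of the spherical origin, mm
#' @return radii at the query directions, mm
#' @export
spherical_template_map <- function(ext, azimuth, polar, origin) {
  az_s <- ext$grid$azimuths * pi / 180
  n_az <- length(az_s)
  xy <- polar_to_cartesian(ext$grid)
  X <- xy$x - origin[1]
  Y <- xy$y - origin[2]
  Z <- ext$elevation - origin[3]
  R <- sqrt(X^2 + Y^2 + Z^2)
  POL <- atan2(sqrt(X^2 + Y^2), Z)
  pol_max <- min(POL[, ncol(POL)])
  if (any(polar > pol_max + 1e-9)) {
    stop("query direction outside the surface angular support (max polar ",
      round(pol_max, 4), " rad)")
  }
  # stage 1: per-meridian cubic interpolation of radius vs polar angle
  rad_at <- matrix(NA_real_, n_az, length(polar))
  for (a in seq_len(n_az)) {
    rad_at[a, ] <- splinefun(POL[a, ], R[a, ], method = "fmm")(polar)
  }
  # stage 2: periodic cubic interpolation across azimuth per query
  out <- numeric(length(polar))
  for (q in seq_along(polar)) {
    out[q] <- periodic_catmull_rom(rad_at[, q], azimuth[q] * 180 / pi)
  }
  out
}

#' Mesh preset parameters
#'
#' `desk` targets roughly 4-6k corneal elements for interactive use; `paper`
#' reproduces the clinical-study density (16,400 corneal elements).
#'
#' @param name `"desk"` or `"paper"`
#' @return list of meshing parameters
#' @export
mesh_preset <- function(name = c("desk", "paper")) {
  name <- match.arg(name)
  if (name == "desk") {
    list(
      cornea_base = 8L, cornea_rings = 30L, cornea_layers = 5L,
      lens_base = 4L, lens_rings = 30L, lens_layers = 2L,
      eyelid_nx = 51L, eyelid_ny = 41L
    )
  } else {
    list(
      cornea_base = 20L, cornea_rings = 36L, cornea_layers = 5L,
      lens_base = 4L, lens_rings = 30L, lens_layers = 2L,
      eyelid_nx = 51L, eyelid_ny = 41L
    )
  }
}

#' Build the anterior-eye hexahedral mesh
#'
#' Anterior nodes come from [spherical_template_map()] applied to an O-grid
#' hemisphere template; posterior nodes are offset inward along the local
#' surface normal by the wall thickness, which varies linearly from the
#' central corneal thickness at the apex to `cct + 0.18` mm at the limbal
#' radius (constant beyond); the wall is divided into through-thickness
#' element layers. The rim is the fixed boundary; the posterior surface
#' carries the IOP.
#'
#' @param ext an [extend_surface()] result covering >= 8 mm lateral radius
#' @param cct central corneal thickness, mm
#' @param layers through-thickness element layers (default 5)
#' @param base,rings O-grid template parameters (see [mesh_preset()])
#' @param limbal_radius radius at which the wall reaches its peripheral
#'   thickness, mm
#' @param peripheral_increment added wall thickness at the limbus, mm
#' @param scleral_factor stiffness multiplier of the scleral continuation
#'   beyond the limbus (ramped over `scleral_ramp` mm); the anterior eye
#'   beyond the limbus is scleral tissue, roughly an order of magnitude
#'   stiffer than the cornea
#' @param scleral_ramp ramp width of the corneo-scleral transition, mm
#' @return a `hex_mesh` with node sets `rim_fixed`, `anterior_nodes` and
#'   facet sets `anterior_surface`, `inner_wall`; element-wise stiffness
#'   scale in `meta$e_scale`
#' @export
build_cornea_mesh <- function(ext, cct, layers = 5L, base = 8L, rings = 30L,
                              limbal_radius = 5.5, peripheral_increment = 0.18,
                              scleral_factor = 10, scleral_ramp = 0.8,
                              mesh_radius = 8.2) {
  stopifnot(inherits(ext, "extended_surface"))
  if (max(ext$grid$radii) < 8) stop("extended surface must reach 8 mm lateral radius")
  apex_z <- ext$elevation[1, which.min(abs(ext$grid$radii))]
  origin <- c(0, 0, apex_z - 7.8)
  tpl <- disk_ogrid(base, rings)
  # angular support: a small margin inside the surface rim
  xy <- polar_to_cartesian(ext$grid)
  Z <- ext$elevation - origin[3]
  rim_col <- which.min(abs(ext$grid$radii - mesh_radius))
  pol_rim <- min(atan2(
    sqrt(xy$x[, rim_col]^2 + xy$y[, rim_col]^2), Z[, rim_col]
  ))
  pol <- tpl$param_radius * (pol_rim * 0.995)
  azi <- atan2(tpl$xy[, 2], tpl$xy[, 1])
  rad <- spherical_template_map(ext, azi, pol, origin)
  dirs <- cbind(sin(pol) * cos(azi), sin(pol) * sin(azi), cos(pol))
  ant <- sweep(dirs * rad, 2L, origin, `+`)
  # outward nodal normals averaged from template quad facets, then
  # Laplacian-smoothed so the inward thickness offset cannot fold where the
  # reconstructed surface has local curvature kinks
  nrm <- quad_vertex_normals(ant, tpl$quads)
  flip <- rowSums(nrm * dirs) < 0
  nrm[flip, ] <- -nrm[flip, ]
  nrm <- smooth_vertex_normals(nrm, tpl$quads, rounds = 3L)
  # blend toward the spherical direction: a pure-normal offset folds where
  # the measured-to-extrapolated transition has a surface crease, while the
  # radial direction is always fold-free for a star-shaped surface
  nrm <- 0.7 * nrm + 0.3 * dirs
  nrm <- nrm / sqrt(rowSums(nrm^2))
  r_lat <- sqrt(ant[, 1]^2 + ant[, 2]^2)
  thick <- cct + peripheral_increment * pmin(r_lat / limbal_radius, 1)
  n_sheet <- nrow(ant)
  nodes <- do.call(rbind, lapply(0:layers, function(l) {
    ant - nrm * (thick * l / layers)
  }))
  elems <- stack_sheets_to_hex(tpl$quads, n_sheet, layers)
  # reorder so the bottom face of each hex is the deeper sheet
  elems <- elems[, c(5, 6, 7, 8, 1, 2, 3, 4)]
  outer_loop <- tpl$rings[[length(tpl$rings)]]
  rim_fixed <- unlist(lapply(0:layers, function(l) outer_loop + l * n_sheet))
  anterior_facets <- tpl$quads # outward = +normal side (anterior sheet offset 0)
  posterior_facets <- tpl$quads[, c(1, 4, 3, 2)] + layers * n_sheet
  # corneo-scleral stiffness ramp per element (by centroid lateral radius)
  ec_lat <- vapply(seq_len(nrow(elems)), function(e) {
    nd <- nodes[elems[e, ], , drop = FALSE]
    sqrt(mean(nd[, 1])^2 + mean(nd[, 2])^2)
  }, 0)
  ramp <- pmin(pmax((ec_lat - limbal_radius) / scleral_ramp, 0), 1)
  e_scale <- 1 + (scleral_factor - 1) * ramp
  mesh <- hex_mesh(
    nodes = nodes, elems = elems,
    nsets = list(
      rim_fixed = rim_fixed,
      anterior_nodes = seq_len(n_sheet)
    ),
    facets = list(
      anterior_surface = anterior_facets,
      inner_wall = posterior_facets
    ),
    meta = list(
      component = "cornea", cct = cct, origin = origin,
      template = list(base = base, rings = rings, layers = layers),
      anterior_quads = tpl$quads, e_scale = e_scale
    )
  )
  bad <- which(hex_min_jacobians(mesh) <= 0)
  if (length(bad)) {
    stop("cornea mesh has inverted elements: ", paste(head(bad, 10), collapse = ", "))
  }
  mesh
}

quad_vertex_normals <- function(pts, quads) {
  nrm <- matrix(0, nrow(pts), 3L)
  a <- pts[quads[, 1], , drop = FALSE]
  b <- pts[quads[, 2], , drop = FALSE]
  c_ <- pts[quads[, 3], , drop = FALSE]
  d <- pts[quads[, 4], , drop = FALSE]
  fn <- vec_cross(c_ - a, d - b) # diagonal cross product (robust for quads)
  all_idx <- c(quads[, 1], quads[, 2], quads[, 3], quads[, 4])
  all_fn <- rbind(fn, fn, fn, fn)
  acc <- rowsum(all_fn, all_idx)
  nrm[as.integer(rownames(acc)), ] <- acc
  nrm / pmax(sqrt(rowSums(nrm^2)), 1e-300)
}

vec_cross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

# average each node's normal with its edge neighbours (renormalised)
smooth_vertex_normals <- function(nrm, quads, rounds = 2L) {
  edges <- rbind(
    quads[, c(1, 2)], quads[, c(2, 3)], quads[, c(3, 4)], quads[, c(4, 1)]
  )
  from <- c(edges[, 1], edges[, 2])
  to <- c(edges[, 2], edges[, 1])
  for (k in seq_len(rounds)) {
    acc <- rowsum(nrm[to, , drop = FALSE], from)
    idx <- as.integer(rownames(acc))
    cnt <- as.numeric(table(from)[as.character(idx)])
    sm <- nrm
    sm[idx, ] <- (nrm[idx, ] + acc / cnt) / 2
    nrm <- sm / pmax(sqrt(rowSums(sm^2)), 1e-300)
  }
  nrm
}
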