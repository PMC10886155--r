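# Reverse-geometry rigid lens: design container, arc-wise profile
# construction, and the revolved O-grid lens mesh.

#' Reverse-geometry lens design
#'
#' Defaults are the study lens: 10.60 mm diameter, 0.22 mm centre thickness,
#' back surface base 8.80 mm (back optic zone diameter 6.00 mm), reverse
#' 6.80 mm, alignment 7.80 and 8.00 mm, peripheral 11.50 mm; front curves
#' 8.70, 8.10 and 4.00 mm from centre to edge.
#'
#' @param back_radii back-zone curvature radii, mm (base, reverse,
#'   alignment 1, alignment 2, peripheral)
#' @param back_widths radial zone widths, mm; must sum to `diameter / 2`
#' @param front_radii front-zone curvature radii, mm (three zones)
#' @param front_widths front radial zone widths, mm; sum to `diameter / 2`
#' @param centre_thickness mm
#' @param diameter total lens diameter, mm
#' @return object of class `lens_design`
#' @export
lens_design <- function(back_radii = c(8.80, 6.80, 7.80, 8.00, 11.50),
                        back_widths = c(3.00, 0.60, 0.80, 0.60, 0.30),
                        front_radii = c(8.70, 8.10, 4.00),
                        front_widths = c(3.50, 1.30, 0.50),
                        centre_thickness = 0.22,
                        diameter = 10.60) {
  if (centre_thickness <= 0) stop("centre thickness must be positive")
  if (any(back_radii <= 0) || any(front_radii <= 0)) stop("all radii must be positive")
  if (abs(sum(back_widths) - diameter / 2) > 1e-9) {
    stop("back zone widths sum to ", sum(back_widths), " mm but diameter/2 is ",
      diameter / 2, " mm")
  }
  if (abs(sum(front_widths) - diameter / 2) > 1e-9) {
    stop("front zone widths sum to ", sum(front_widths), " mm but diameter/2 is ",
      diameter / 2, " mm")
  }
  structure(
    list(
      back = list(radius = back_radii, width = back_widths),
      front = list(radius = front_radii, width = front_widths),
      centre_thickness = centre_thickness,
      diameter = diameter,
      bozd = 2 * back_widths[1]
    ),
    class = "lens_design"
  )
}

#' @exportS3Method base::print
print.lens_design <- function(x, ...) {
  cat(sprintf(
    "<lens_design> %.2f mm diameter, CT %.2f mm, BOZD %.2f mm\n  back radii: %s mm\n  front radii: %s mm\n",
    x$diameter, x$centre_thickness, x$bozd,
    paste(sprintf("%.2f", x$back$radius), collapse = "/"),
    paste(sprintf("%.2f", x$front$radius), collapse = "/")
  ))
  invisible(x)
}

# One surface profile from zone arcs, computed in sag space (sag s(r)
# increases from the apex). Axis-centred arcs are sag-matched (C0); a zone
# whose curvature radius cannot span its outer radius from the axis is
# continued as a tangent (C1) arc with an off-axis centre. In the lens frame
# (+Z away from the eye, back apex at z = 0) the surfaces mate the convex
# cornea from above: z_back(r) = -s_back(r), z_front(r) = ct - s_front(r).
profile_arcs <- function(radii, widths, z0) {
  r_edges <- cumsum(c(0, widths))
  arcs <- list()
  z_j <- z0
  m_j <- 0
  for (i in seq_along(radii)) {
    R <- radii[i]
    r0 <- r_edges[i]
    r1 <- r_edges[i + 1]
    if (R > r1 * 1.02) {
      cz <- z_j + sqrt(R^2 - r0^2)
      arcs[[i]] <- list(type = "axis", R = R, cz = cz, r0 = r0, r1 = r1)
      z_j <- cz - sqrt(R^2 - r1^2)
      m_j <- r1 / sqrt(R^2 - r1^2)
    } else {
      nrm <- sqrt(1 + m_j^2)
      cr <- r0 - R * m_j / nrm
      cz <- z_j + R / nrm
      if (R^2 - (r1 - cr)^2 <= 0) {
        stop("zone ", i, " (radius ", R, " mm) cannot sag-match: impossible geometry")
      }
      arcs[[i]] <- list(type = "offset", R = R, cr = cr, cz = cz, r0 = r0, r1 = r1)
      z_j <- cz - sqrt(R^2 - (r1 - cr)^2)
      m_j <- (r1 - cr) / sqrt(R^2 - (r1 - cr)^2)
    }
  }
  list(arcs = arcs, r_edges = r_edges)
}

eval_arcs <- function(prof, r) {
  z <- rep(NA_real_, length(r))
  for (a in prof$arcs) {
    sel <- r >= a$r0 - 1e-12 & r <= a$r1 + 1e-12 & is.na(z)
    if (!any(sel)) next
    if (a$type == "axis") {
      z[sel] <- a$cz - sqrt(a$R^2 - r[sel]^2)
    } else {
      z[sel] <- a$cz - sqrt(a$R^2 - (r[sel] - a$cr)^2)
    }
  }
  z
}

#' Construct the lens cross-section profile
#'
#' Back profile from the five back-zone arcs (sag-matched, C0), front profile
#' from the three front arcs starting `centre_thickness` above the back apex;
#' the profile is closed by a straight edge segment.
#'
#' @param design a [lens_design()]
#' @param n_samples radial samples per returned polyline
#' @return object of class `lens_profile`: functions `back(r)`, `front(r)`
#'   (sag, mm), sampled polylines, and junction radii
#' @export
build_lens_profile <- function(design, n_samples = 201L) {
  stopifnot(inherits(design, "lens_design"))
  half <- design$diameter / 2
  ct <- design$centre_thickness
  back <- profile_arcs(design$back$radius, design$back$width, 0)
  front <- profile_arcs(design$front$radius, design$front$width, 0)
  r <- seq(0, half, length.out = n_samples)
  zb <- -eval_arcs(back, r)
  zf <- ct - eval_arcs(front, r)
  if (any(zf - zb <= 0)) {
    stop("front surface intersects back surface: impossible lens geometry")
  }
  structure(
    list(
      back_fun = function(r) -eval_arcs(back, r),
      front_fun = function(r) ct - eval_arcs(front, r),
      back = cbind(r = r, z = zb),
      front = cbind(r = r, z = zf),
      back_junctions = back$r_edges,
      front_junctions = front$r_edges,
      design = design
    ),
    class = "lens_profile"
  )
}

#' Build the lens hexahedral mesh
#'
#' The O-grid disk template (central `element_base` x `element_base` patch
#' surrounded by `rings` rings) is swept onto the revolved lens profile with
#' `layers` through-thickness element layers. Element count per layer is
#' `element_base^2 + 4 * element_base * rings`.
#'
#' @param design a [lens_design()]
#' @param element_base central-patch element base (default 4)
#' @param rings number of rings (default 30)
#' @param layers through-thickness layers (default 2)
#' @return a `hex_mesh` with facet sets `lens_back`, `lens_front` and node
#'   sets `lens_back_nodes`, `lens_front_nodes`
#' @export
build_lens_mesh <- function(design, element_base = 4L, rings = 30L, layers = 2L) {
  prof <- build_lens_profile(design)
  tpl <- disk_ogrid(element_base, rings)
  half <- design$diameter / 2
  r <- tpl$param_radius * half
  zb <- prof$back_fun(r)
  zf <- prof$front_fun(r)
  n_sheet <- nrow(tpl$xy)
  xy <- tpl$xy * half
  nodes <- do.call(rbind, lapply(0:layers, function(l) {
    cbind(xy[, 1], xy[, 2], zb + (zf - zb) * l / layers)
  }))
  elems <- stack_sheets_to_hex(tpl$quads, n_sheet, layers)
  back_facets <- tpl$quads[, c(1, 4, 3, 2)] # outward normal toward the eye (-z)
  front_facets <- tpl$quads + layers * n_sheet
  mesh <- hex_mesh(
    nodes = nodes, elems = elems,
    nsets = list(
      lens_back_nodes = seq_len(n_sheet),
      lens_front_nodes = layers * n_sheet + seq_len(n_sheet)
    ),
    facets = list(lens_back = back_facets, lens_front = front_facets),
    meta = list(
      component = "lens", design = design,
      template = list(base = element_base, rings = rings, layers = layers),
      back_quads = tpl$quads
    )
  )
  bad <- which(hex_min_jacobians(mesh) <= 0)
  if (length(bad)) {
    stop("lens mesh has inverted elements after sweeping: ",
      paste(head(bad, 10), collapse = ", "))
  }
  mesh
}
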