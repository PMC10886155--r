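# Eyelid boundary detection from topography coverage footprints, and the
# two-layer eyelid solid that drapes over the anterior eye.

#' Eyelid boundary parabolas
#'
#' Second-order lid edge curves `y = a x^2 + b x + c` (mm). The upper lid
#' opens downward (a < 0, c > 0), the lower upward (a > 0, c < 0).
#'
#' @param upper,lower named numeric `(a, b, c)`
#' @param landmarks optional tibble of landmark points used for the fit
#' @return object of class `eyelid_boundary`
#' @export
eyelid_boundary <- function(upper, lower, landmarks = NULL) {
  upper <- stats::setNames(as.numeric(upper), c("a", "b", "c"))
  lower <- stats::setNames(as.numeric(lower), c("a", "b", "c"))
  if (!(upper["a"] < 0 && lower["a"] > 0)) {
    stop("lid concavity invalid: need upper a < 0 and lower a > 0")
  }
  if (!(upper["c"] > 0 && lower["c"] < 0)) {
    stop("lid vertices invalid: need upper c > 0 > lower c")
  }
  structure(
    list(upper = upper, lower = lower, landmarks = landmarks, detected = TRUE),
    class = "eyelid_boundary"
  )
}

#' Cohort-mean eyelid parabolas
#'
#' Mean second-order lid fits of the clinical cohort, per laterality.
#'
#' @param eye `"right"` or `"left"`
#' @return list with `upper` and `lower` `(a, b, c)` coefficient vectors
#' @export
eyelid_reference_parabolas <- function(eye = c("right", "left")) {
  eye <- match.arg(eye)
  if (eye == "right") {
    list(
      upper = c(a = -0.0832, b = -0.0262, c = 3.5809),
      lower = c(a = 0.0842, b = 0.0163, c = -3.9734)
    )
  } else {
    list(
      upper = c(a = -0.0864, b = 0.0256, c = 3.6564),
      lower = c(a = 0.0868, b = -0.0206, c = -3.9902)
    )
  }
}

#' @exportS3Method base::print
print.eyelid_boundary <- function(x, ...) {
  if (!isTRUE(x$detected)) {
    cat("<eyelid_boundary> no lid detected\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<eyelid_boundary> upper y = %.4f x^2 + %.4f x + %.4f; lower y = %.4f x^2 + %.4f x + %.4f\n",
    x$upper["a"], x$upper["b"], x$upper["c"],
    x$lower["a"], x$lower["b"], x$lower["c"]
  ))
  invisible(x)
}

# Histogram of boundary-point radii about a centre, fixed bin width from 0.
lid_radius_histogram <- function(radii, bin = 0.3) {
  breaks <- seq(0, max(radii) + bin, by = bin)
  counts <- table(cut(radii, breaks, right = FALSE))
  tibble(
    lo = breaks[-length(breaks)], hi = breaks[-1],
    count = as.integer(counts)
  )
}

#' Detect eyelid boundary parabolas from a coverage mask
#'
#' The outermost valid sample of each semi-meridian gives the footprint
#' boundary; its geometric centre is computed and the boundary-point radii
#' about that centre are binned in a fixed-width histogram. Points in the
#' most frequent (non device-rim) bins are the lid-edge landmarks; they are
#' split into upper and lower sets about the centre and a least-squares
#' parabola is fitted per lid.
#'
#' @param mask logical coverage matrix (n_az x n_r)
#' @param grid the matching [polar_grid()]
#' @param bin histogram bin size, mm (default 0.3)
#' @param n_bins number of top-count bins retained as landmarks (default 4)
#' @param rim_tol device-rim exclusion tolerance, mm: boundary points within
#'   this distance (from the map centre) of the largest boundary radius are
#'   treated as device-limited, not lid-limited
#' @return an [eyelid_boundary()]; or an object with `detected = FALSE` when
#'   the footprint shows no lid truncation
#' @export
detect_eyelid_boundary <- function(mask, grid, bin = 0.3, n_bins = 4L,
                                   rim_tol = 0.15) {
  n_az <- nrow(mask)
  rmax <- apply(mask, 1L, function(m) if (any(m)) max(grid$radii[m]) else NA_real_)
  okaz <- which(is.finite(rmax))
  if (length(okaz) < 8) stop("coverage mask is too sparse for boundary detection")
  th <- grid$azimuths[okaz] * pi / 180
  bx <- rmax[okaz] * cos(th)
  by <- rmax[okaz] * sin(th)
  r_map <- rmax[okaz]
  device_r <- max(r_map)
  lid_pt <- r_map < device_r - rim_tol
  if (!any(lid_pt)) {
    return(structure(
      list(upper = NULL, lower = NULL, landmarks = NULL, detected = FALSE),
      class = "eyelid_boundary"
    ))
  }
  cx <- mean(bx)
  cy <- mean(by)
  rad <- sqrt((bx - cx)^2 + (by - cy)^2)
  hist <- lid_radius_histogram(rad[lid_pt], bin)
  keep_bins <- head(order(hist$count, decreasing = TRUE), n_bins)
  keep_bins <- keep_bins[hist$count[keep_bins] > 0]
  in_top <- rep(FALSE, length(rad))
  for (k in keep_bins) {
    in_top <- in_top | (rad >= hist$lo[k] & rad < hist$hi[k])
  }
  landmark <- lid_pt & in_top
  pts <- tibble(
    x = bx[landmark], y = by[landmark],
    radius = rad[landmark],
    lid = ifelse(by[landmark] > cy, "upper", "lower")
  )
  fit_lid <- function(sub, name) {
    if (nrow(sub) < 3) {
      stop("fewer than 3 landmark points for the ", name, " lid")
    }
    # least squares with one outlier-rejection pass (eyelash slit gaps pull
    # isolated boundary points radially inward off the lid curve)
    fit <- lm(y ~ I(x^2) + x, data = sub)
    res <- stats::residuals(fit)
    s <- stats::mad(res)
    keep <- abs(res) <= max(3 * s, 1e-6)
    if (sum(keep) >= 3 && any(!keep)) {
      fit <- lm(y ~ I(x^2) + x, data = sub[keep, , drop = FALSE])
    }
    coef(fit)[c(2, 3, 1)]
  }
  up <- fit_lid(pts[pts$lid == "upper", ], "upper")
  lo <- fit_lid(pts[pts$lid == "lower", ], "lower")
  eyelid_boundary(upper = up, lower = lo, landmarks = pts)
}

#' Build the two-layer eyelid solid mesh
#'
#' A closed-eye eyelid: upper and lower lids meshed as one continuous
#' surface following the anterior eye shape. The mid-surface grid spans the
#' lid-covered square uniformly (odd step counts put nodes on the X and Y
#' axes); it is offset outward along the local surface normal by a clearance
#' gap (plus a standoff accommodating the lens) and extruded by the lid
#' thickness in two element layers of 8-node hexahedra.
#'
#' @param boundary an [eyelid_boundary()] (recorded in the mesh metadata)
#' @param anterior an [extend_surface()] result
#' @param thickness lid thickness, mm (default 0.5)
#' @param nx,ny grid steps in X and Y (defaults 51 and 41, both odd)
#' @param half_width lateral half-extent of the lid sheet, mm
#' @param clearance initial gap between lid back surface and what it drapes
#'   over, mm
#' @param standoff extra offset accommodating the lens between lid and eye,
#'   mm (lens centre thickness plus tear gap)
#' @param lens optional seated lens `hex_mesh`; the lid back surface is
#'   lifted (smoothly) wherever needed to clear the lens front surface by
#'   `clearance`
#' @return a `hex_mesh` with node sets `eyelid_back`, `eyelid_outer`,
#'   `eyelid_perimeter` and facet sets `eyelid_back`, `eyelid_outer`
#' @export
build_eyelid_mesh <- function(boundary, anterior, thickness = 0.5,
                              nx = 51L, ny = 41L, half_width = 5.8,
                              clearance = 0.05, standoff = 0.3, lens = NULL) {
  stopifnot(inherits(anterior, "extended_surface"))
  xs <- seq(-half_width, half_width, length.out = nx)
  ys <- seq(-half_width, half_width, length.out = ny)
  gx <- outer(xs, rep(1, ny))
  gy <- outer(rep(1, nx), ys)
  gz <- matrix(
    interp_polar_field(anterior$grid, anterior$elevation, gx, gy),
    nx, ny
  )
  if (anyNA(gz)) {
    stop("anterior surface does not cover the eyelid sheet extent (",
      half_width, " mm)")
  }
  # outward surface normals from the structured sheet
  dzdx <- gz
  dzdy <- gz
  dzdx[2:(nx - 1), ] <- (gz[3:nx, ] - gz[1:(nx - 2), ]) / (xs[3] - xs[1])
  dzdx[c(1, nx), ] <- dzdx[c(2, nx - 1), ]
  dzdy[, 2:(ny - 1)] <- (gz[, 3:ny] - gz[, 1:(ny - 2)]) / (ys[3] - ys[1])
  dzdy[, c(1, ny)] <- dzdy[, c(2, ny - 1)]
  nrm <- sqrt(dzdx^2 + dzdy^2 + 1)
  nhat <- list(x = -dzdx / nrm, y = -dzdy / nrm, z = 1 / nrm)
  offs <- clearance + standoff
  # lift the sheet wherever the seated lens front pokes through
  lift <- matrix(0, nx, ny)
  if (!is.null(lens)) {
    b0x <- gx + offs * nhat$x
    b0y <- gy + offs * nhat$y
    b0z <- gz + offs * nhat$z
    lens_top <- facet_interpolate_xy(
      lens$nodes, lens$facets$lens_front, lens$nodes[, 3],
      as.vector(b0x), as.vector(b0y)
    )
    need <- matrix(lens_top + clearance - as.vector(b0z), nx, ny)
    need[!is.finite(need)] <- 0
    lift <- gaussian_filter2(pmax(need, 0), sigma = 1.5)
    lift <- pmax(lift, matrix(pmax(need, 0), nx, ny))
  }
  levels <- offs + thickness * (0:2) / 2
  nid <- function(i, j, l) (l - 1L) * nx * ny + (j - 1L) * nx + i
  nodes <- matrix(NA_real_, nx * ny * 3L, 3L)
  for (l in 1:3) {
    d <- levels[l]
    idx <- nid(rep(seq_len(nx), ny), rep(seq_len(ny), each = nx), l)
    nodes[idx, ] <- cbind(
      as.vector(gx + d * nhat$x),
      as.vector(gy + d * nhat$y),
      as.vector(gz + d * nhat$z + lift)
    )
  }
  elems <- matrix(0L, (nx - 1L) * (ny - 1L) * 2L, 8L)
  e <- 0L
  for (l in 1:2) {
    for (j in seq_len(ny - 1L)) {
      for (i in seq_len(nx - 1L)) {
        e <- e + 1L
        elems[e, ] <- c(
          nid(i, j, l), nid(i + 1L, j, l), nid(i + 1L, j + 1L, l), nid(i, j + 1L, l),
          nid(i, j, l + 1L), nid(i + 1L, j, l + 1L), nid(i + 1L, j + 1L, l + 1L),
          nid(i, j + 1L, l + 1L)
        )
      }
    }
  }
  back_nodes <- nid(rep(seq_len(nx), ny), rep(seq_len(ny), each = nx), 1L)
  outer_nodes <- nid(rep(seq_len(nx), ny), rep(seq_len(ny), each = nx), 3L)
  per <- unique(c(
    nid(rep(c(1L, nx), each = ny), rep(seq_len(ny), 2), rep(1L, 2 * ny)),
    nid(rep(seq_len(nx), 2), rep(c(1L, ny), each = nx), rep(1L, 2 * nx))
  ))
  perimeter <- unique(unlist(lapply(1:3, function(l) per + (l - 1L) * nx * ny)))
  quad_grid <- function(l) {
    qs <- matrix(0L, (nx - 1L) * (ny - 1L), 4L)
    q <- 0L
    for (j in seq_len(ny - 1L)) {
      for (i in seq_len(nx - 1L)) {
        q <- q + 1L
        qs[q, ] <- c(nid(i, j, l), nid(i + 1L, j, l), nid(i + 1L, j + 1L, l), nid(i, j + 1L, l))
      }
    }
    qs
  }
  back_f <- quad_grid(1L)[, c(1, 4, 3, 2)] # outward normal toward the eye (-z side)
  outer_f <- quad_grid(3L)                 # outward normal away from the eye
  mesh <- hex_mesh(
    nodes = nodes, elems = elems,
    nsets = list(
      eyelid_back = back_nodes, eyelid_outer = outer_nodes,
      eyelid_perimeter = perimeter
    ),
    facets = list(eyelid_back = back_f, eyelid_outer = outer_f),
    meta = list(component = "eyelid", boundary = boundary, thickness = thickness)
  )
  bad <- which(hex_min_jacobians(mesh) <= 0)
  if (length(bad)) {
    stop("eyelid mesh has inverted elements: ", paste(head(bad, 10), collapse = ", "))
  }
  mesh
}
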