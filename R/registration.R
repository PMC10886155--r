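# Rigid transforms and constrained ICP lens seating.

#' Compose a rigid transform
#'
#' The rotation matrix follows the printed yaw-pitch-roll element layout used
#' for lens registration, with angles `alpha`, `beta`, `gamma` and a
#' translation `(xt, yt, zt)`.
#'
#' @param alpha,beta,gamma rotation angles, radians
#' @param xt,yt,zt translation components, mm
#' @return object of class `rigid_transform` with elements `R` (3x3) and `t`
#' @export
compose_transform <- function(alpha = 0, beta = 0, gamma = 0,
                              xt = 0, yt = 0, zt = 0) {
  ca <- cos(alpha); sa <- sin(alpha)
  cb <- cos(beta); sb <- sin(beta)
  cg <- cos(gamma); sg <- sin(gamma)
  R <- rbind(
    c(ca * cb, ca * sb * sg - sa * cg, ca * sb * cg + sa * sg),
    c(sa * cb, sa * sb * sg + ca * cg, sa * sb * cg - ca * sg),
    c(-sb, cb * sg, cb * cg)
  )
  structure(
    list(
      R = R, t = c(xt, yt, zt),
      angles = c(alpha = alpha, beta = beta, gamma = gamma)
    ),
    class = "rigid_transform"
  )
}

rigid_from_Rt <- function(R, t) {
  beta <- asin(pmin(pmax(-R[3, 1], -1), 1))
  alpha <- atan2(R[2, 1], R[1, 1])
  gamma <- atan2(R[3, 2], R[3, 3])
  structure(
    list(R = R, t = as.numeric(t),
      angles = c(alpha = alpha, beta = beta, gamma = gamma)),
    class = "rigid_transform"
  )
}

#' @exportS3Method base::print
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> angles (%.4g, %.4g, %.4g) rad; t = (%.4g, %.4g, %.4g) mm\n",
    x$angles[1], x$angles[2], x$angles[3], x$t[1], x$t[2], x$t[3]
  ))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param points n x 3 matrix, mm
#' @param transform a [compose_transform()] result
#' @return transformed n x 3 matrix (`R x + t` per point)
#' @export
apply_transform <- function(points, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  sweep(points %*% t(transform$R), 2L, transform$t, `+`)
}

#' Invert a rigid transform
#'
#' @param transform a `rigid_transform`
#' @return the inverse `rigid_transform`
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$R)
  rigid_from_Rt(Rt, -Rt %*% transform$t)
}

# Best-fit rigid motion P -> Q (Kabsch, SVD).
kabsch <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- t(P - rep(cp, each = nrow(P))) %*% (Q - rep(cq, each = nrow(Q)))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cq - R %*% cp
  list(R = R, t = as.numeric(t))
}

# clamp a rigid step: rotation angle <= max_rot (rad), |t| <= max_trans
clamp_rigid <- function(R, t, max_rot, max_trans) {
  tr <- (sum(diag(R)) - 1) / 2
  ang <- acos(pmin(pmax(tr, -1), 1))
  if (ang > max_rot && ang > 1e-15) {
    # scale the rotation via axis-angle
    w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    w <- w / max(sqrt(sum(w^2)), 1e-300)
    a <- max_rot
    K <- rbind(
      c(0, -w[3], w[2]),
      c(w[3], 0, -w[1]),
      c(-w[2], w[1], 0)
    )
    R <- diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
  }
  nt <- sqrt(sum(t^2))
  if (nt > max_trans) t <- t * max_trans / nt
  list(R = R, t = t)
}

#' Rigid registration of a point set onto a reference surface cloud
#'
#' Constrained point-to-point ICP: each iteration pairs the moving points
#' (or a subset used for correspondence) with their nearest reference
#' points, computes the best rigid fit (SVD), clamps it to small per-step
#' and total bounds, and accepts the step only if the RMS normal distance
#' does not increase, so the objective sequence is monotone non-increasing.
#' With `lift = TRUE` any penetrating pose (negative signed gap along the
#' reference normals) is projected outward along the mean surface normal.
#'
#' @param points moving point set, n x 3, mm
#' @param Q reference point cloud, m x 3
#' @param QN outward unit normals of `Q`
#' @param subset row indices of `points` used for correspondences
#' @param max_iter iteration cap (default 50)
#' @param step_trans,step_rot per-iteration clamp (mm, rad)
#' @param total_trans,total_rot total excursion clamp (mm, rad)
#' @param tol stop when the objective improves by less than this, mm
#' @param lift enforce non-penetration by outward projection
#' @param point_to_plane use point-to-plane targets
#' @return list: `points` (registered), `R`, `t` (accumulated rigid motion),
#'   `report` (tibble of per-iteration objective), `converged`, `n_iter`
#' @export
icp_register <- function(points, Q, QN, subset = seq_len(nrow(points)),
                         max_iter = 50L,
                         step_trans = 0.05, step_rot = 0.25 * pi / 180,
                         total_trans = 1.0, total_rot = 5 * pi / 180,
                         tol = 1e-6, lift = TRUE, point_to_plane = FALSE) {
  nodes <- points
  R_acc <- diag(3)
  t_acc <- c(0, 0, 0)
  objective <- function(nds) {
    P <- nds[subset, , drop = FALSE]
    nn <- nn_index(P, Q)
    gap <- rowSums((P - Q[nn, , drop = FALSE]) * QN[nn, , drop = FALSE])
    list(value = sqrt(mean(gap^2)), nn = nn, gap = gap)
  }
  lift_if_penetrating <- function(nds, ob) {
    mg <- min(ob$gap)
    shift <- c(0, 0, 0)
    if (lift && mg < 0) {
      nbar <- colMeans(QN[ob$nn, , drop = FALSE])
      nbar <- nbar / sqrt(sum(nbar^2))
      shift <- (-mg + 1e-9) * nbar
      nds <- sweep(nds, 2L, shift, `+`)
      ob <- objective(nds)
    }
    list(nds = nds, ob = ob, shift = shift)
  }
  ob <- objective(nodes)
  lifted <- lift_if_penetrating(nodes, ob)
  nodes <- lifted$nds
  ob <- lifted$ob
  t_acc <- t_acc + lifted$shift
  hist <- numeric(0)
  hist[1] <- ob$value
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    P <- nodes[subset, , drop = FALSE]
    targets <- if (point_to_plane) {
      P - ob$gap * QN[ob$nn, , drop = FALSE]
    } else {
      Q[ob$nn, , drop = FALSE]
    }
    step <- kabsch(P, targets)
    step <- clamp_rigid(step$R, step$t, step_rot, step_trans)
    # candidate steps: the full clamped step at decreasing damping, then the
    # step with its mean-normal translation removed (a pure slide/tilt move
    # that the non-penetration lift cannot cancel)
    nbar <- colMeans(QN[ob$nn, , drop = FALSE])
    nbar <- nbar / sqrt(sum(nbar^2))
    t_lat <- step$t - sum(step$t * nbar) * nbar
    trials <- list(
      list(R = step$R, t = step$t, damp = 1),
      list(R = step$R, t = step$t, damp = 0.5),
      list(R = step$R, t = step$t, damp = 0.25),
      list(R = step$R, t = step$t, damp = 0.1),
      list(R = step$R, t = t_lat, damp = 1),
      list(R = step$R, t = t_lat, damp = 0.25)
    )
    improved <- FALSE
    for (tr_ in trials) {
      damp <- tr_$damp
      Rs <- rot_fraction(tr_$R, damp)
      ts <- tr_$t * damp
      # total-excursion clamp: shrink the step if it would exceed the bounds
      tot <- clamp_rigid(Rs %*% R_acc, as.numeric(Rs %*% t_acc) + ts,
        total_rot, total_trans)
      Rs_eff <- tot$R %*% t(R_acc)
      ts_eff <- tot$t - as.numeric(Rs_eff %*% t_acc)
      cand <- sweep(nodes %*% t(Rs_eff), 2L, ts_eff, `+`)
      ob_cand <- objective(cand)
      lifted <- lift_if_penetrating(cand, ob_cand)
      if (lifted$ob$value < ob$value - 1e-14) {
        nodes <- lifted$nds
        ob <- lifted$ob
        R_acc <- Rs_eff %*% R_acc
        t_acc <- as.numeric(Rs_eff %*% t_acc) + ts_eff + lifted$shift
        improved <- TRUE
        break
      }
    }
    hist[it + 1L] <- ob$value
    if (!improved) {
      hist <- hist[seq_len(it)]
      converged <- TRUE
      break
    }
    if (hist[it] - hist[it + 1L] < tol) {
      converged <- TRUE
      break
    }
  }
  list(
    points = nodes, R = R_acc, t = t_acc,
    report = tibble(iteration = seq_along(hist) - 1L, objective = hist),
    converged = converged, n_iter = length(hist) - 1L
  )
}

#' Seat a lens on the cornea by constrained ICP
#'
#' The lens is first offset laterally by the clinically detected
#' decentration and dropped onto the corneal surface; constrained ICP
#' ([icp_register()]) then minimises the RMS normal distance between the
#' lens back surface and a dense corneal surface sample, subject to
#' non-penetration (final minimum signed clearance >= -1e-6 mm).
#'
#' @param lens a lens `hex_mesh` (from [build_lens_mesh()])
#' @param decentration `(dx, dy)` clinical decentration, mm
#' @param ext corneal [extend_surface()] result
#' @param max_iter ICP iteration cap (default 50)
#' @param step_trans,step_rot per-iteration clamp (mm, rad)
#' @param total_trans,total_rot total ICP excursion clamp (mm, rad)
#' @param tol stop when the objective improves by less than this, mm
#' @param standoff initial apex clearance, mm
#' @param initial_pose when FALSE the lens mesh is taken to be already in
#'   the eye frame (e.g. a perturbed seated pose) and the initial placement
#'   is skipped
#' @param point_to_plane use point-to-plane residuals for the objective
#' @return list: `mesh` (seated lens), `transform` (accumulated
#'   [compose_transform()]-style rigid transform), `report` (tibble of
#'   per-iteration objective), `converged`
#' @export
seat_lens <- function(lens, decentration, ext, max_iter = 50L,
                      step_trans = 0.05, step_rot = 0.25 * pi / 180,
                      total_trans = 1.0, total_rot = 5 * pi / 180,
                      tol = 1e-6, standoff = 0.02, initial_pose = TRUE,
                      point_to_plane = FALSE) {
  stopifnot(inherits(lens, "hex_mesh"), inherits(ext, "extended_surface"))
  half <- lens$meta$design$diameter / 2
  # dense corneal sample with outward normals over the lens footprint
  samp <- cornea_surface_sample(ext, max_r = half + 1.2)
  # initial pose: apex over the decentred position, resting standoff above
  z0 <- interp_polar_field(
    ext$grid, ext$elevation, decentration[1], decentration[2]
  )
  nodes <- lens$nodes
  if (initial_pose) {
    nodes[, 1] <- nodes[, 1] + decentration[1]
    nodes[, 2] <- nodes[, 2] + decentration[2]
    nodes[, 3] <- nodes[, 3] + z0 + standoff
  }
  reg <- icp_register(
    nodes, samp$pts, samp$normals,
    subset = lens$nsets$lens_back_nodes,
    max_iter = max_iter, step_trans = step_trans, step_rot = step_rot,
    total_trans = total_trans, total_rot = total_rot, tol = tol,
    lift = TRUE, point_to_plane = point_to_plane
  )
  out_mesh <- lens
  out_mesh$nodes <- reg$points
  t0 <- if (initial_pose) c(decentration[1], decentration[2], z0 + standoff) else c(0, 0, 0)
  tf <- rigid_from_Rt(reg$R, as.numeric(reg$R %*% t0) + reg$t)
  list(
    mesh = out_mesh,
    transform = tf,
    report = reg$report,
    converged = reg$converged,
    n_iter = reg$n_iter
  )
}

rot_fraction <- function(R, f) {
  if (f >= 1) return(R)
  tr <- (sum(diag(R)) - 1) / 2
  ang <- acos(pmin(pmax(tr, -1), 1))
  if (ang < 1e-15) return(diag(3))
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  w <- w / max(sqrt(sum(w^2)), 1e-300)
  a <- ang * f
  K <- rbind(c(0, -w[3], w[2]), c(w[3], 0, -w[1]), c(-w[2], w[1], 0))
  diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
}

# Dense sample of the corneal surface with outward normals.
cornea_surface_sample <- function(ext, max_r = 6.5, az_stride = 1L, r_stride = 1L) {
  grid <- ext$grid
  keep_r <- which(grid$radii <= max_r)
  keep_r <- keep_r[seq(1, length(keep_r), by = r_stride)]
  keep_a <- seq(1, length(grid$azimuths), by = az_stride)
  th <- grid$azimuths[keep_a] * pi / 180
  r <- grid$radii[keep_r]
  x <- outer(cos(th), r)
  y <- outer(sin(th), r)
  z <- ext$elevation[keep_a, keep_r, drop = FALSE]
  # normals from radial/azimuthal tangents of the structured sheet
  full <- ext$elevation
  dr <- c(diff(grid$radii)[1], diff(grid$radii))
  dzdr <- t(apply(full, 1L, function(p) {
    c(diff(p)[1] / dr[2], diff(p) / dr[-1])
  }))
  dzdr <- dzdr[keep_a, keep_r, drop = FALSE]
  thm <- matrix(th, length(th), length(r))
  # surface gradient in Cartesian x, y (axisymmetric-dominant approximation
  # augmented with the azimuthal derivative)
  daz <- 2 * pi / length(grid$azimuths)
  dzda <- (full[c(2:nrow(full), 1), ] - full[c(nrow(full), 1:(nrow(full) - 1)), ]) / (2 * daz)
  dzda <- dzda[keep_a, keep_r, drop = FALSE]
  rm_ <- matrix(r, length(th), length(r), byrow = TRUE)
  eps <- 1e-9
  dzdx <- cos(thm) * dzdr - sin(thm) * dzda / pmax(rm_, eps)
  dzdy <- sin(thm) * dzdr + cos(thm) * dzda / pmax(rm_, eps)
  nn <- sqrt(dzdx^2 + dzdy^2 + 1)
  list(
    pts = cbind(as.vector(x), as.vector(y), as.vector(z)),
    normals = cbind(
      as.vector(-dzdx / nn), as.vector(-dzdy / nn), as.vector(1 / nn)
    )
  )
}
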