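# Implicit small-strain finite-element engine (B-bar hex8, penalty contact)
# with the staged Ortho-K load program. Units: mm, N, MPa.

MMHG_TO_MPA <- 133.322387415e-6

#' Linear elastic material model
#'
#' @param E Young's modulus, MPa
#' @param nu Poisson ratio (0 < nu < 0.5)
#' @param density kg/m^3 (metadata; the quasi-static solver ignores inertia)
#' @return object of class `material_model`
#' @export
material_model <- function(E, nu = 0.49, density = 1000) {
  if (E <= 0) stop("Young's modulus must be positive")
  if (nu <= 0 || nu >= 0.5) stop("Poisson ratio must be in (0, 0.5)")
  structure(list(E = E, nu = nu, density = density, kind = "linear_elastic"),
    class = "material_model"
  )
}

#' Age-dependent corneal Young's modulus
#'
#' `E = 0.0032 * age + 0.2` MPa.
#'
#' @param age age in years (> 0)
#' @return Young's modulus, MPa
#' @export
young_modulus_from_age <- function(age) {
  if (any(age <= 0)) stop("age must be positive")
  0.0032 * age + 0.2
}

#' Standard material presets
#'
#' Cornea: age-dependent modulus, nu = 0.49, water density. Lens (rigid gas
#' permeable fluorosilicone acrylate): E = 1500 MPa, nu = 0.49, 1270 kg/m^3.
#' Eyelid: E = 1.73 MPa, nu = 0.49, water density.
#'
#' @param component `"cornea"`, `"lens"` or `"eyelid"`
#' @param age patient age, years (cornea only)
#' @return a [material_model()]
#' @export
material_preset <- function(component = c("cornea", "lens", "eyelid"), age = 18) {
  component <- match.arg(component)
  switch(component,
    cornea = material_model(young_modulus_from_age(age), 0.49, 1000),
    lens = material_model(1500, 0.49, 1270),
    eyelid = material_model(1.73, 0.49, 1000)
  )
}

#' The staged load program
#'
#' Ordered steps of the contact simulation: stress-free iterations, IOP
#' inflation in ten equal increments, quasi-static lid settle at the blink
#' pressure, tear-film surface traction on the lens back, and closed-lid
#' pressure. Pressures in mmHg except the tear traction (mPa, applied
#' literally as a uniform attractive normal traction).
#'
#' @param iop_mmhg intra-ocular pressure, mmHg
#' @param iop_increments equal IOP load increments (default 10)
#' @param eyelid_pressure_mmhg blink/closure lid pressure (default 8.0)
#' @param tear_tension_mpa tear traction on the lens back, mPa (default 43.6)
#' @param tol relative out-of-balance force tolerance
#' @param max_newton Newton/contact iteration cap per step
#' @return object of class `load_program`
#' @export
load_program <- function(iop_mmhg = 15, iop_increments = 10L,
                         eyelid_pressure_mmhg = 8.0, tear_tension_mpa = 43.6,
                         tol = 5e-3, max_newton = 30L) {
  if (iop_mmhg < 0 || eyelid_pressure_mmhg < 0) stop("pressures must be >= 0")
  structure(
    list(
      steps = c(
        "stress_free_iterations", "iop_inflation", "blink_settle",
        "tear_surface_tension", "eyelid_closure"
      ),
      iop_mmhg = iop_mmhg, iop_increments = iop_increments,
      eyelid_pressure_mmhg = eyelid_pressure_mmhg,
      tear_tension_mpa = tear_tension_mpa,
      tol = tol, max_newton = max_newton
    ),
    class = "load_program"
  )
}

# ---------------------------------------------------------------------------
# assembly helpers

# Assemble the global stiffness. An optional cache (an environment created
# by make_stiffness_cache()) keeps the sparsity pattern and the
# triplet-to-slot mapping so repeated assemblies on the same mesh topology
# only refill the numeric values.
assemble_stiffness <- function(nodes, elems, E, nu, cache = NULL, sig0 = NULL) {
  n3 <- 3 * nrow(nodes)
  tr <- hex8_assemble(nodes, elems, E, nu, sig0)
  if (is.null(cache)) {
    return(Matrix::sparseMatrix(
      i = as.numeric(tr$i) + 1, j = as.numeric(tr$j) + 1, x = as.numeric(tr$v),
      dims = c(n3, n3)
    ))
  }
  if (is.null(cache$map)) {
    K <- Matrix::sparseMatrix(
      i = as.numeric(tr$i) + 1, j = as.numeric(tr$j) + 1, x = as.numeric(tr$v),
      dims = c(n3, n3)
    )
    nz_col <- rep(seq_len(n3) - 1, diff(K@p))
    nzkey <- K@i + n3 * nz_col
    trkey <- as.numeric(tr$i) + n3 * as.numeric(tr$j)
    cache$map <- findInterval(trkey, nzkey)
    cache$pattern <- K
    return(K)
  }
  K <- cache$pattern
  K@x <- as.numeric(accum_by_index(
    as.numeric(tr$v), as.integer(cache$map), length(K@x)
  ))
  K
}

make_stiffness_cache <- function() new.env(parent = emptyenv())

# Consistent (lumped-by-triangle) nodal forces of a pressure p applied on an
# oriented facet set; positive p pushes against the surface (along the
# inward -outward-normal direction).
facet_pressure_forces <- function(nodes, facets, p, n_nodes = nrow(nodes)) {
  f <- matrix(0, n_nodes, 3L)
  a <- nodes[facets[, 1], , drop = FALSE]
  b <- nodes[facets[, 2], , drop = FALSE]
  c_ <- nodes[facets[, 3], , drop = FALSE]
  d <- nodes[facets[, 4], , drop = FALSE]
  add_tri <- function(f, p1, p2, p3, ids) {
    an <- vec_cross(p2 - p1, p3 - p1) / 2 # area-weighted outward normal
    contrib <- -p * an / 3
    for (k in 1:3) {
      acc <- rowsum(contrib, ids[, k])
      idx <- as.integer(rownames(acc))
      f[idx, ] <- f[idx, ] + acc
    }
    f
  }
  f <- add_tri(f, a, b, c_, cbind(facets[, 1], facets[, 2], facets[, 3]))
  f <- add_tri(f, a, c_, d, cbind(facets[, 1], facets[, 3], facets[, 4]))
  f
}

# Tributary (lumped) areas of the nodes of an oriented facet set.
facet_node_areas <- function(nodes, facets, n_nodes = nrow(nodes)) {
  area <- numeric(n_nodes)
  a <- nodes[facets[, 1], , drop = FALSE]
  b <- nodes[facets[, 2], , drop = FALSE]
  c_ <- nodes[facets[, 3], , drop = FALSE]
  d <- nodes[facets[, 4], , drop = FALSE]
  t1 <- sqrt(rowSums(vec_cross(b - a, c_ - a)^2)) / 2
  t2 <- sqrt(rowSums(vec_cross(c_ - a, d - a)^2)) / 2
  for (k in 1:4) {
    w <- (t1 + t2) / 4
    acc <- rowsum(w, facets[, k])
    idx <- as.integer(rownames(acc))
    area[idx] <- area[idx] + acc[, 1]
  }
  area
}

# ---------------------------------------------------------------------------
# linear solve with fixed dofs

chol_factor <- function(A) {
  Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, super = TRUE)
}

solve_linear <- function(K, f, fixed_dofs, u0 = NULL) {
  n <- nrow(K)
  free <- setdiff(seq_len(n), fixed_dofs)
  u <- if (is.null(u0)) numeric(n) else u0
  rhs <- f[free] - K[free, fixed_dofs, drop = FALSE] %*% u[fixed_dofs]
  u[free] <- as.numeric(Matrix::solve(chol_factor(K[free, free]), rhs))
  u
}

#' Find the stress-free (unloaded) geometry of an inflated mesh
#'
#' Iterative inverse inflation: the candidate unloaded geometry is updated by
#' the displacement mismatch until inflating it by the IOP reproduces the
#' measured geometry within tolerance (max nodal error).
#'
#' @param mesh a cornea `hex_mesh` whose nodes are the measured (inflated)
#'   geometry, with `rim_fixed` node set and `inner_wall` facet set
#' @param material cornea [material_model()]
#' @param iop_mmhg IOP, mmHg
#' @param tol max nodal error, mm (default 1e-4)
#' @param max_iter iteration cap (default 30)
#' @return list: `mesh` (stress-free geometry), `residuals` (per-iteration
#'   max error, mm), `converged`, `inflate` (function returning the inflated
#'   displacement field of the final stress-free mesh)
#' @export
find_stress_free_geometry <- function(mesh, material, iop_mmhg, tol = 1e-4,
                                      max_iter = 30L) {
  if (iop_mmhg < 0) stop("IOP must be >= 0")
  target <- mesh$nodes
  if (iop_mmhg == 0) {
    return(list(
      mesh = mesh, residuals = numeric(0), converged = TRUE,
      u_inflate = matrix(0, nrow(target), 3L)
    ))
  }
  p <- iop_mmhg * MMHG_TO_MPA
  fixed <- dof_ids(mesh$nsets$rim_fixed)
  ne <- nrow(mesh$elems)
  scale <- if (!is.null(mesh$meta$e_scale)) mesh$meta$e_scale else rep(1, ne)
  Ev <- material$E * scale
  nuv <- rep(material$nu, ne)
  # fixed-point shrink iteration with Anderson acceleration (depth 3):
  # the inflation-mismatch map can have mixed-sign sensitivity modes, which
  # scalar relaxation cannot damp
  X0 <- target
  residuals <- numeric(0)
  u <- NULL
  cache <- make_stiffness_cache()
  hist_x <- list()
  hist_m <- list()
  depth <- 3L
  beta_mix <- 0.8
  sig_prev <- NULL
  for (it in seq_len(max_iter)) {
    # lagged stress-stiffening: the previous iterate's inflation stress
    # supplies the membrane geometric stiffness, which stabilises locally
    # flat (bending-soft) patches of the reconstructed surface
    K <- assemble_stiffness(X0, mesh$elems, Ev, nuv, cache, sig0 = sig_prev)
    fext <- facet_pressure_forces(X0, mesh$facets$inner_wall, p)
    u <- matrix(solve_linear(K, as.vector(t(fext)), fixed), ncol = 3L, byrow = TRUE)
    sig_prev <- hex8_recover(X0, mesh$elems, Ev, nuv, u)$stress
    inflated <- X0 + u
    mismatch <- inflated - target
    err <- max(sqrt(rowSums(mismatch^2)))
    residuals <- c(residuals, err)
    if (err < tol) {
      out <- mesh
      out$nodes <- X0
      return(list(
        mesh = out, residuals = residuals, converged = TRUE, u_inflate = u,
        stress = sig_prev
      ))
    }
    hist_x[[length(hist_x) + 1L]] <- as.vector(X0)
    hist_m[[length(hist_m) + 1L]] <- as.vector(mismatch)
    nh <- length(hist_x)
    if (nh >= 2L) {
      use <- seq.int(2L, nh)
      dM <- vapply(use, function(j) hist_m[[j]] - hist_m[[j - 1L]],
        numeric(length(hist_m[[1L]])))
      dX <- vapply(use, function(j) hist_x[[j]] - hist_x[[j - 1L]],
        numeric(length(hist_x[[1L]])))
      gam <- tryCatch(
        qr.solve(crossprod(dM) + 1e-12 * diag(ncol(dM)),
          crossprod(dM, hist_m[[nh]])),
        error = function(e) NULL
      )
      if (is.null(gam) || any(!is.finite(gam))) {
        X0 <- X0 - beta_mix * mismatch
      } else {
        x_new <- hist_x[[nh]] - dX %*% gam -
          beta_mix * (hist_m[[nh]] - dM %*% gam)
        X0 <- matrix(as.numeric(x_new), ncol = 3L)
      }
    } else {
      X0 <- X0 - 0.5 * mismatch
    }
    if (length(hist_x) > depth + 1L) {
      hist_x <- hist_x[-1L]
      hist_m <- hist_m[-1L]
    }
  }
  stop(
    "stress-free geometry did not converge in ", max_iter,
    " iterations (last residual ", signif(utils::tail(residuals, 1), 3), " mm)"
  )
}

dof_ids <- function(node_ids) {
  as.vector(t(cbind(3 * node_ids - 2, 3 * node_ids - 1, 3 * node_ids)))
}
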