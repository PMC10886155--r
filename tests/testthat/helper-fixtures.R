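# Shared fixtures: all synthetic, generated in code at test time.

# reduced polar grid for fast unit tests
small_grid <- function(n_az = 120L, n_r = 160L, r_max = 5.4) {
  polar_grid(n_az, n_r, r_max = r_max)
}

# spherical cap topography of radius R (apex at z = 0)
sphere_record <- function(R = 7.5, grid = small_grid()) {
  r2 <- outer(rep(1, length(grid$azimuths)), grid$radii^2)
  z <- -(r2 / (R * (1 + sqrt(1 - r2 / R^2))))
  topo_record(z, grid)
}

# fast cohort spec on a reduced grid (metadata sampling is grid-independent)
small_spec <- function(n = 3L, seed = 1L, ...) {
  cohort_spec(n, seed = seed, grid = small_grid(), ...)
}

# wrap a plain matrix as a grid-map for metric tests
as_grid_map <- function(values, mask = NULL, grid = NULL, component = "") {
  if (is.null(mask)) mask <- is.finite(values)
  structure(
    list(values = values, mask = mask, grid = grid, unit = "", component = component),
    class = "grid_map"
  )
}

# coarse cornea mesh for solver unit tests
coarse_cornea <- function(seed = 7L, base = 4L, rings = 12L, layers = 3L) {
  spec <- small_spec(1, seed = seed)
  p <- generate_patient(spec, 1)
  ext <- extend_surface(p$topography)
  list(
    mesh = build_cornea_mesh(ext, cct = p$patient$cct, base = base,
      rings = rings, layers = layers),
    patient = p$patient, ext = ext
  )
}

expect_monotone_nonincreasing <- function(x, tol = 1e-12) {
  expect_true(all(diff(x) <= tol))
}
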