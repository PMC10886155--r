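test_that("the age-modulus law evaluates exactly", {
  expect_equal(young_modulus_from_age(18), 0.2576)
  expect_equal(young_modulus_from_age(38), 0.3216)
  expect_equal(young_modulus_from_age(1e-9), 0.2, tolerance = 1e-6)
  expect_error(young_modulus_from_age(0), "positive")
  expect_error(material_model(1, nu = 0.5), "Poisson")
})

test_that("a single element under uniform traction carries exact stress", {
  nodes <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  nodes <- nodes[c(1, 2, 4, 3, 5, 6, 8, 7), ]
  elems <- matrix(1:8, 1)
  K <- okfea:::assemble_stiffness(nodes, elems, 10, 0.49)
  f <- matrix(0, 8, 3)
  f[5:8, 3] <- 2 / 4 # sigma_zz = 2 MPa over unit area
  fixed <- c(3 * (1:4), 1, 2, 3 * 2 - 1)
  u <- okfea:::solve_linear(K, as.vector(t(f)), fixed)
  rec <- okfea:::hex8_recover(nodes, elems, 10, 0.49,
    matrix(u, ncol = 3, byrow = TRUE))
  expect_equal(rec$stress[1, 3], 2, tolerance = 1e-13)
  expect_lt(max(abs(rec$stress[1, -3])), 1e-12)
})

test_that("zero load gives zero displacement and stress", {
  mesh <- mesh_spherical_shell(11.5, 12.05, n = 4L, layers = 2L)
  ne <- nrow(mesh$elems)
  K <- okfea:::assemble_stiffness(mesh$nodes, mesh$elems, rep(0.25, ne), rep(0.49, ne))
  u <- okfea:::solve_linear(K, numeric(3 * nrow(mesh$nodes)), 1:6)
  expect_equal(max(abs(u)), 0)
})

lame_errors <- function(n, layers) {
  a <- 11.5; b <- 12.05; E <- 0.25; nu <- 0.49; p <- 0.002
  mesh <- mesh_spherical_shell(a, b, n = n, layers = layers)
  ne <- nrow(mesh$elems)
  nd <- mesh$nodes
  K <- okfea:::assemble_stiffness(nd, mesh$elems, rep(E, ne), rep(nu, ne))
  f <- okfea:::facet_pressure_forces(nd, mesh$facets$inner_wall, p)
  pick <- function(dir) which.max(nd %*% dir / sqrt(rowSums(nd^2)))
  n1 <- pick(c(1, 0, 0)); n2 <- pick(c(0, 1, 0)); n3 <- pick(c(0, 0, 1))
  fixed <- c(3 * n1 - 1, 3 * n1, 3 * n2 - 2, 3 * n2, 3 * n3 - 2, 3 * n3 - 1)
  u <- okfea:::solve_linear(K, as.vector(t(f)), fixed)
  U <- matrix(u, ncol = 3, byrow = TRUE)
  r <- sqrt(rowSums(nd^2))
  ur <- rowSums(U * nd / r)
  uexact <- function(r) p * a^3 / (b^3 - a^3) / E * ((1 - 2 * nu) * r + (1 + nu) * b^3 / (2 * r^2))
  inner <- abs(r - a) < 1e-9
  rec <- okfea:::hex8_recover(nd, mesh$elems, rep(E, ne), rep(nu, ne), U)
  ec <- t(vapply(seq_len(ne), function(e) colMeans(nd[mesh$elems[e, ], ]), numeric(3)))
  rc <- sqrt(rowSums(ec^2))
  hoop <- vapply(seq_len(ne), function(i) {
    s <- rec$stress[i, ]
    S <- matrix(c(s[1], s[4], s[6], s[4], s[2], s[5], s[6], s[5], s[3]), 3, 3)
    nr <- ec[i, ] / rc[i]
    (sum(diag(S)) - drop(t(nr) %*% S %*% nr)) / 2
  }, 0)
  hexact <- p * a^3 * (b^3 + 2 * rc^3) / (2 * rc^3 * (b^3 - a^3))
  # global equilibrium: residual at free dofs is at solver precision
  res <- as.numeric(K %*% u) - as.vector(t(f))
  free <- setdiff(seq_len(3 * nrow(nd)), fixed)
  equil <- sqrt(sum(res[free]^2)) / sqrt(sum(f^2))
  list(
    u_err = abs(mean(ur[inner]) - uexact(a)) / uexact(a),
    hoop_err = mean(abs(hoop - hexact) / hexact),
    equil = equil
  )
}

test_that("the Lame thick-sphere benchmark converges under refinement", {
  e1 <- lame_errors(4L, 2L)
  e2 <- lame_errors(6L, 2L)
  e3 <- lame_errors(8L, 2L)
  expect_lt(e2$u_err, e1$u_err)
  expect_lt(e3$u_err, e2$u_err)
  expect_lt(e2$hoop_err, e1$hoop_err)
  expect_lt(e3$hoop_err, e2$hoop_err)
  expect_lt(e3$equil, 1e-6)
})

test_that("stress-free recovery is the identity at zero IOP and converges", {
  fix <- coarse_cornea(seed = 7, base = 4L, rings = 10L, layers = 3L)
  mat <- material_preset("cornea", age = fix$patient$age)
  sf0 <- find_stress_free_geometry(fix$mesh, mat, 0)
  expect_identical(sf0$mesh$nodes, fix$mesh$nodes)
  sf <- find_stress_free_geometry(fix$mesh, mat, 15)
  expect_true(sf$converged)
  expect_lte(length(sf$residuals), 30L)
  expect_lt(utils::tail(sf$residuals, 1), 1e-4)
  # residuals settle monotonically after the first iterations
  tail_res <- utils::tail(sf$residuals, max(length(sf$residuals) - 3L, 2L))
  expect_monotone_nonincreasing(tail_res, tol = 1e-6)
})

test_that("stress and strain invariants are the analytic ones", {
  # uniaxial sigma_zz = 3: mises = 3, pressure = -1, max principal = 3
  s <- matrix(c(0, 0, 3, 0, 0, 0), 1)
  inv <- okfea:::voigt_invariants(s)
  expect_equal(inv$mises, 3)
  expect_equal(inv$pressure, -1)
  expect_equal(inv$max_principal, 3)
  # hydrostatic sigma I: mises = 0, pressure = -sigma
  h <- matrix(c(-2, -2, -2, 0, 0, 0), 1)
  invh <- okfea:::voigt_invariants(h)
  expect_equal(invh$mises, 0)
  expect_equal(invh$pressure, 2)
  # uniform stretch lambda along z: max principal log strain = ln(lambda)
  lam <- 1.07
  Hg <- matrix(c(0, 0, 0, 0, 0, 0, 0, 0, lam - 1), 1, byrow = TRUE)
  expect_equal(okfea:::max_principal_log_strain(Hg), log(lam), tolerance = 1e-12)
})

test_that("scalar invariants are frame-indifferent", {
  set.seed(8)
  S <- crossprod(matrix(rnorm(9), 3)) - diag(3)
  sv <- matrix(c(S[1, 1], S[2, 2], S[3, 3], S[1, 2], S[2, 3], S[3, 1]), 1)
  inv <- okfea:::voigt_invariants(sv)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  Sr <- Q %*% S %*% t(Q)
  svr <- matrix(c(Sr[1, 1], Sr[2, 2], Sr[3, 3], Sr[1, 2], Sr[2, 3], Sr[3, 1]), 1)
  invr <- okfea:::voigt_invariants(svr)
  expect_equal(inv$mises, invr$mises, tolerance = 1e-9)
  expect_equal(inv$pressure, invr$pressure, tolerance = 1e-9)
  expect_equal(inv$max_principal, invr$max_principal, tolerance = 1e-9)
})

test_that("rigid displacement fields produce a null FEA RPC", {
  fix <- coarse_cornea(seed = 7, base = 6L, rings = 16L, layers = 2L)
  mesh <- fix$mesh
  fake_asm <- list(
    nodes = mesh$nodes,
    nsets = list(anterior_nodes = mesh$nsets$anterior_nodes),
    comps = list(cornea = mesh)
  )
  tf <- compose_transform(0, 0, 0.02 * pi / 180, 0.005, -0.003, 0.008)
  moved <- apply_transform(mesh$nodes, tf)
  result <- list(assembly = fake_asm, u = moved - mesh$nodes)
  rpc <- fea_rpc(result, max_r = 4.5)
  expect_true(any(rpc$valid))
  # scattered-node resampling bounds the achievable null: see the methods
  # vignette on curvature-sensitivity of the FEA RPC
  expect_lt(max(abs(rpc$values[rpc$valid])), 0.25)
  # zero displacement: exactly zero map
  result0 <- list(assembly = fake_asm, u = 0 * mesh$nodes)
  rpc0 <- fea_rpc(result0, max_r = 4.5)
  expect_equal(max(abs(rpc0$values[rpc0$valid])), 0)
})
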