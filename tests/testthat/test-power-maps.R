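test_that("the power pipeline reproduces closed forms on spheres", {
  rec <- sphere_record(7.5)
  curv <- tangential_curvature_map(rec)
  expect_lt(max(abs(curv$values[curv$valid] - 7.5)), 1e-4)
  pm <- tangential_power_map(curv)
  expect_lt(max(abs(pm$values[pm$valid] - 45)), 0.01)
  # 6.75 mm -> 50 D
  rec2 <- sphere_record(6.75)
  pm2 <- tangential_power_map(tangential_curvature_map(rec2))
  expect_lt(max(abs(pm2$values[pm2$valid] - 50)), 0.01)
})

test_that("tangential curvature matches the paraboloid closed form", {
  g <- small_grid(60, 120, r_max = 4)
  r2 <- outer(rep(1, 60), g$radii^2)
  rec <- topo_record(-r2 / (2 * 7.8), g)
  curv <- tangential_curvature_map(rec)
  rt_exp <- outer(rep(1, 60), 7.8 * (1 + (g$radii / 7.8)^2)^1.5)
  dev <- abs(curv$values - rt_exp)
  expect_lt(max(dev[curv$valid]), 1e-3)
})

test_that("degenerate meridians are invalid, never an exception", {
  g <- small_grid(24, 30)
  z <- matrix(NA_real_, 24, 30)
  z[1, 1:2] <- 0 # fewer than 3 valid stations everywhere
  cov <- is.finite(z)
  rec <- topo_record(z, g, coverage = cov)
  curv <- tangential_curvature_map(rec)
  expect_true(all(!curv$valid))
  # a flat profile is marked invalid (not infinite)
  recf <- topo_record(matrix(0, 24, 30), g)
  curvf <- tangential_curvature_map(recf)
  expect_true(all(!curvf$valid))
})

test_that("config invariants are enforced", {
  expect_error(power_map_config(nh = 1.0), "nh > nair")
  expect_error(power_map_config(nair = 0.5), "nh > nair")
})

test_that("the smoother is exact in its limits and linear", {
  g <- small_grid(40, 50)
  rec <- sphere_record(7.6, g)
  pm <- tangential_power_map(tangential_curvature_map(rec))
  # s -> 0: identity
  s0 <- smooth_map(pm, power_map_config(smoothing_factor = 0))
  expect_equal(s0$values, pm$values)
  # constant map unchanged for any s
  const <- pm
  const$values[const$valid] <- 42
  sc <- smooth_map(const, power_map_config(smoothing_factor = 4.5))
  expect_lt(max(abs(sc$values[sc$valid] - 42)), 1e-5)
  # superposition in non-robust mode
  a <- matrix(rnorm(30 * 40), 30)
  b <- matrix(rnorm(30 * 40), 30)
  sa <- smooth_map_values(a, s = 4.5)
  sb <- smooth_map_values(b, s = 4.5)
  sab <- smooth_map_values(a + b, s = 4.5)
  expect_lt(max(abs(sab - (sa + sb))), 1e-6)
})

test_that("smoothing reduces noise against the clean map (Monte-Carlo)", {
  g <- small_grid(60, 80)
  rec <- sphere_record(7.5, g)
  clean <- tangential_power_map(tangential_curvature_map(rec))
  wins <- 0L
  for (s in 1:10) {
    set.seed(100 + s)
    noisy <- clean
    noisy$values <- clean$values + matrix(rnorm(length(clean$values), 0, 0.5),
      nrow(clean$values))
    sm <- smooth_map(noisy, power_map_config(smoothing_factor = 4.5))
    ok <- sm$valid & clean$valid
    rms_in <- sqrt(mean((noisy$values[ok] - clean$values[ok])^2))
    rms_out <- sqrt(mean((sm$values[ok] - clean$values[ok])^2))
    if (rms_out < rms_in) wins <- wins + 1L
  }
  expect_equal(wins, 10L)
})

test_that("RPC maps are differences with anti-symmetry", {
  rec <- sphere_record(7.5)
  pm <- tangential_power_map(tangential_curvature_map(rec))
  zero <- rpc_map(pm, pm)
  expect_equal(max(abs(zero$values[zero$valid])), 0)
  # uniform 44 -> 41 D gives a uniform -3 D map
  p44 <- pm
  p44$values[] <- 44
  p41 <- pm
  p41$values[] <- 41
  d <- rpc_map(p44, p41)
  expect_true(all(abs(d$values[d$valid] + 3) < 1e-12))
  # swapping the arguments negates the map
  a <- pm
  a$values <- pm$values + matrix(runif(length(pm$values)), nrow(pm$values))
  fwd <- rpc_map(pm, a)
  bwd <- rpc_map(a, pm)
  expect_equal(fwd$values, -bwd$values)
  # mismatched grids are an error
  other <- tangential_power_map(tangential_curvature_map(sphere_record(7.5, small_grid(24, 30))))
  expect_error(rpc_map(pm, other), "different grids")
})

test_that("zone detection is symmetric, equivariant, and fails loudly", {
  spec <- small_spec(1, seed = 21)
  pre <- generate_patient(spec, 1)$topography
  base <- orthok_effect(-3, 1.5, 2.6, decentration = c(0, 0))
  rpc0 <- rpc_map(
    power_map_pipeline(pre),
    power_map_pipeline(apply_orthok_effect(pre, base))
  )
  z0 <- detect_zones(rpc0)
  expect_true(z0$treatment_zone)
  expect_lt(sqrt(sum(z0$decentration^2)), 0.05)
  # equivariance under translation of the effect
  shift <- c(0.4, 0.3)
  rpc1 <- rpc_map(
    power_map_pipeline(pre),
    power_map_pipeline(apply_orthok_effect(
      pre, orthok_effect(-3, 1.5, 2.6, decentration = shift)
    ))
  )
  z1 <- detect_zones(rpc1)
  expect_lt(sqrt(sum((z1$decentration - z0$decentration - shift)^2)), 0.1)
  # all-positive RPC: explicit no-treatment-zone result
  pos <- rpc0
  pos$values <- abs(pos$values) + 0.5
  expect_false(detect_zones(pos)$treatment_zone)
})
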