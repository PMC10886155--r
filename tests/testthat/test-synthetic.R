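test_that("patient generation is deterministic and respects the cohort spec", {
  spec <- small_spec(5, seed = 11)
  a <- generate_patient(spec, 2)
  b <- generate_patient(spec, 2)
  expect_identical(a$topography$elevation, b$topography$elevation)
  expect_identical(a$patient, b$patient)
  # different indices give different eyes
  c_ <- generate_patient(spec, 3)
  expect_false(identical(a$topography$elevation, c_$topography$elevation))
  # the caller's RNG stream is untouched
  set.seed(99)
  before <- rnorm(3)
  set.seed(99)
  invisible(generate_patient(spec, 1))
  expect_identical(rnorm(3), before)
})

test_that("degenerate cohort distributions collapse to their means", {
  spec <- small_spec(4, seed = 2,
    age = c(14.1, 0), iop = c(15, 0), cct = c(0.554, 0)
  )
  for (i in 1:4) {
    p <- generate_patient(spec, i)$patient
    expect_equal(p$age, 14.1)
    expect_equal(p$iop, 15)
    expect_equal(p$cct, 0.554)
  }
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(0), "n must be")
  expect_error(small_spec(3, age = c(14, -1)), "sd >= 0")
  expect_error(small_spec(3, decentration_sd = -0.1), "decentration_sd")
})

test_that("sampled CCT matches the stated normal (Monte-Carlo)", {
  spec <- small_spec(400, seed = 31)
  cct <- vapply(seq_len(400), function(i) generate_patient(spec, i)$patient$cct, 0)
  se <- 0.033 / sqrt(400)
  expect_lt(abs(mean(cct) - 0.554), 3 * se)
})

test_that("pre-wear surfaces are star-shaped domes", {
  spec <- small_spec(2, seed = 5)
  p <- generate_patient(spec, 1)
  # elevation strictly decreases along every semi-meridian
  expect_true(all(apply(p$topography$elevation, 1L, function(z) all(diff(z) < 0))))
})

test_that("a zero-magnitude effect is the identity", {
  spec <- small_spec(1, seed = 3)
  pre <- generate_patient(spec, 1)$topography
  eff <- orthok_effect(0, 0, 2.6)
  expect_identical(apply_orthok_effect(pre, eff), pre)
})

test_that("the imposed effect hits the requested central power change", {
  pre <- generate_patient(small_spec(1, seed = 3), 1)$topography
  eff <- orthok_effect(-3, 1.5, 2.6, decentration = c(0, 0))
  post <- apply_orthok_effect(pre, eff)
  rpc <- rpc_map(power_map_pipeline(pre), power_map_pipeline(post))
  centre <- mean(rpc$values[, 1], na.rm = TRUE)
  expect_gt(centre, -4)
  expect_lt(centre, -2)
})

test_that("the effect conserves the surface outside its support", {
  spec <- small_spec(1, seed = 9)
  pre <- generate_patient(spec, 1)$topography
  eff <- orthok_effect(-2.5, 1.2, 2.5, decentration = c(0.4, -0.2),
    transition_width = 0.6)
  post <- apply_orthok_effect(pre, eff)
  xy <- polar_to_cartesian(pre$grid)
  rho <- sqrt((xy$x - 0.4)^2 + (xy$y + 0.2)^2)
  outside <- rho > 2.5 + 2 * 0.6
  dz <- abs(post$elevation - pre$elevation)
  expect_lt(max(dz[outside]), 1e-4 * 1e-3) # < 0.1 nm, i.e. exactly conserved
  # elevation change is smooth and non-trivial inside
  expect_gt(max(dz[!outside]), 1e-3)
})

test_that("effects reaching beyond the measured radius are rejected", {
  spec <- small_spec(1, seed = 9)
  pre <- generate_patient(spec, 1)$topography
  expect_error(
    apply_orthok_effect(pre, orthok_effect(-3, 1.5, 4.5, decentration = c(0.5, 0))),
    "beyond the measured radius"
  )
})

test_that("coverage masks follow the lid parabolas", {
  g <- small_grid()
  tab <- eyelid_reference_parabolas("right")
  b <- eyelid_boundary(tab$upper, tab$lower)
  # no-lid configuration: lids far outside the disc
  far <- eyelid_boundary(c(-0.05, 0, 50), c(0.05, 0, -50))
  m_full <- generate_coverage_mask(far, g, n_slits = 0)
  expect_true(all(m_full))
  # zero slits: exactly the analytic lid-bounded region
  m0 <- generate_coverage_mask(b, g, n_slits = 0)
  xy <- polar_to_cartesian(g)
  expected <- (sqrt(xy$x^2 + xy$y^2) <= max(g$radii) + 1e-12) &
    (xy$y <= tab$upper["a"] * xy$x^2 + tab$upper["b"] * xy$x + tab$upper["c"]) &
    (xy$y >= tab$lower["a"] * xy$x^2 + tab$lower["b"] * xy$x + tab$lower["c"])
  expect_identical(m0, expected)
  # slits only remove samples, deterministically per seed
  m1 <- generate_coverage_mask(b, g, n_slits = 5, seed = 4)
  m2 <- generate_coverage_mask(b, g, n_slits = 5, seed = 4)
  expect_identical(m1, m2)
  expect_true(all(m0[!m1] | !m0[!m1])) # removed cells were inside or outside
  expect_true(sum(m1) < sum(m0))
  # an aperture that misses the disc entirely is an error
  degenerate <- structure(
    list(upper = c(a = -0.05, b = 0, c = -20), lower = c(a = 0.05, b = 0, c = -40),
      detected = TRUE),
    class = "eyelid_boundary"
  )
  expect_error(generate_coverage_mask(degenerate, g), "aperture")
})

test_that("correlated validation fields hit the requested correlation", {
  g <- common_grid(mask_radius = 5)
  base <- matrix(rnorm(161 * 161), 161)
  rpc <- as_grid_map(okfea:::gaussian_filter2(base, 4))
  rpc$mask <- g$mask
  rpc$grid <- g
  class(rpc) <- "grid_map"
  for (rho in c(-1, -0.5, 0.5, 1)) {
    fld <- generate_correlated_field(rpc, rho, seed = 7)
    m <- rpc$mask & is.finite(fld$values)
    expect_equal(stats::cor(rpc$values[m], fld$values[m]), rho, tolerance = 1e-6)
  }
  flat <- rpc
  flat$values[] <- 1
  expect_error(generate_correlated_field(flat, 0.5), "constant")
})
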