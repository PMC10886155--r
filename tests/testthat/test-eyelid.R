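test_that("cohort-mean lid parabolas are recovered from their own masks", {
  g <- small_grid(300, 200)
  tab <- eyelid_reference_parabolas("right")
  b <- eyelid_boundary(tab$upper, tab$lower)
  for (slits in c(0L, 6L)) {
    m <- generate_coverage_mask(b, g, n_slits = slits, seed = 3)
    det <- detect_eyelid_boundary(m, g)
    expect_true(det$detected)
    expect_lt(max(abs(det$upper - tab$upper) / abs(tab$upper)), 0.05)
    expect_lt(max(abs(det$lower - tab$lower) / abs(tab$lower)), 0.05)
  }
})

test_that("full-disc coverage reports no lid", {
  g <- small_grid(60, 50)
  m <- matrix(TRUE, 60, 50)
  det <- detect_eyelid_boundary(m, g)
  expect_false(det$detected)
})

test_that("radius histogram bins at 0.3 mm from zero", {
  h <- okfea:::lid_radius_histogram(rep(5.0, 40), bin = 0.3)
  hit <- h[h$count > 0, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$lo, 4.8)
  expect_equal(hit$hi, 5.1)
  expect_equal(hit$count, 40L)
})

test_that("lid landmark selection is rotation-invariant about the centre", {
  # radii about the centre are unchanged by rigid rotation of the mask
  set.seed(4)
  radii <- runif(200, 3, 5)
  h1 <- okfea:::lid_radius_histogram(radii, 0.3)
  h2 <- okfea:::lid_radius_histogram(sample(radii), 0.3)
  expect_identical(h1$count, h2$count)
})

test_that("the eyelid solid has the stated structure", {
  spec <- small_spec(1, seed = 12)
  case <- generate_case(spec, 1)
  ext <- extend_surface(case$pre)
  mesh <- build_eyelid_mesh(case$boundary, ext)
  expect_equal(nrow(mesh$elems), 50L * 40L * 2L) # 4000 elements
  expect_equal(nrow(mesh$nodes), 51L * 41L * 3L) # 6273 nodes
  expect_true(all(okfea:::hex_min_jacobians(mesh) > 0))
  # local thickness along the extrusion normal is 0.5 mm +/- 1%
  back <- mesh$nodes[mesh$nsets$eyelid_back, ]
  outer_ <- mesh$nodes[mesh$nsets$eyelid_outer, ]
  thick <- sqrt(rowSums((outer_ - back)^2))
  expect_true(all(abs(thick - 0.5) <= 0.005))
  # perimeter node set has all three sheets of the boundary
  expect_equal(length(mesh$nsets$eyelid_perimeter), 3L * (2L * 51L + 2L * 41L - 4L))
})

test_that("inverted eyelid elements are reported", {
  spec <- small_spec(1, seed = 12)
  case <- generate_case(spec, 1)
  ext <- extend_surface(case$pre)
  expect_error(
    build_eyelid_mesh(case$boundary, ext, thickness = -0.5),
    "inverted"
  )
})
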