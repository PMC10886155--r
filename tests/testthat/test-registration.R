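test_that("rigid transforms follow the printed element layout", {
  tf <- compose_transform()
  expect_equal(tf$R, diag(3))
  expect_equal(tf$t, c(0, 0, 0))
  a <- 0.1; b <- -0.2; g <- 0.3
  tf2 <- compose_transform(a, b, g)
  # independent elementwise evaluation of the printed matrix
  R_exp <- matrix(c(
    cos(a) * cos(b),
    cos(a) * sin(b) * sin(g) - sin(a) * cos(g),
    cos(a) * sin(b) * cos(g) + sin(a) * sin(g),
    sin(a) * cos(b),
    sin(a) * sin(b) * sin(g) + cos(a) * cos(g),
    sin(a) * sin(b) * cos(g) - cos(a) * sin(g),
    -sin(b),
    cos(b) * sin(g),
    cos(b) * cos(g)
  ), nrow = 3, byrow = TRUE)
  expect_equal(tf2$R, R_exp, tolerance = 1e-15)
})

test_that("rigid transforms are orthonormal isometries", {
  set.seed(3)
  for (k in 1:20) {
    ang <- runif(3, -pi, pi)
    tf <- compose_transform(ang[1], ang[2], ang[3], runif(1), runif(1), runif(1))
    expect_lt(max(abs(t(tf$R) %*% tf$R - diag(3))), 1e-12)
    expect_equal(det(tf$R), 1, tolerance = 1e-12)
    pts <- matrix(rnorm(30), 10)
    moved <- apply_transform(pts, tf)
    expect_lt(max(abs(dist(moved) - dist(pts))), 1e-12)
    back <- apply_transform(moved, invert_transform(tf))
    expect_lt(max(abs(back - pts)), 1e-12)
  }
  # pure translation
  tr <- compose_transform(xt = 1, yt = 2, zt = 3)
  expect_equal(apply_transform(matrix(0, 1, 3), tr), matrix(c(1, 2, 3), 1))
})

test_that("ICP recovers a known perturbation of a seated pose", {
  spec <- small_spec(1, seed = 5)
  p <- generate_patient(spec, 1)
  ext <- extend_surface(p$topography)
  lens <- build_lens_mesh(p$lens)
  seat <- seat_lens(lens, c(0.3, -0.2), ext)
  expect_monotone_nonincreasing(seat$report$objective)
  back <- seat$mesh$nodes[lens$nsets$lens_back_nodes, ]
  qn <- okfea:::quad_vertex_normals(seat$mesh$nodes, seat$mesh$meta$back_quads)
  qn <- qn[lens$nsets$lens_back_nodes, ]
  qn[qn[, 3] < 0, ] <- -qn[qn[, 3] < 0, ]
  ctr <- colMeans(back)
  for (dirv in list(c(2, -1, 2) / 3, c(1, 1, 1) / sqrt(3), c(0, 0, 1))) {
    R <- compose_transform(gamma = 1 * pi / 180)$R
    P <- sweep(sweep(back, 2, ctr) %*% t(R), 2, ctr + 0.3 * dirv, `+`)
    reg <- icp_register(P, back, qn, lift = FALSE)
    expect_lte(reg$n_iter, 50L)
    expect_monotone_nonincreasing(reg$report$objective)
    expect_lt(sqrt(mean(rowSums((reg$points - back)^2))), 1e-3)
  }
})

test_that("seating a centred lens on a symmetric cornea stays centred", {
  rec <- sphere_record(7.7, small_grid())
  ext <- extend_surface(rec)
  lens <- build_lens_mesh(lens_design())
  seat <- seat_lens(lens, c(0, 0), ext)
  expect_lt(abs(seat$transform$t[1]), 1e-3)
  expect_lt(abs(seat$transform$t[2]), 1e-3)
  expect_monotone_nonincreasing(seat$report$objective)
  # non-penetration: signed clearance of the seated back surface
  samp <- okfea:::cornea_surface_sample(ext, max_r = 6.5)
  back <- seat$mesh$nodes[lens$nsets$lens_back_nodes, ]
  nn <- okfea:::nn_index(back, samp$pts)
  gaps <- rowSums((back - samp$pts[nn, ]) * samp$normals[nn, ])
  expect_gt(min(gaps), -1e-6)
})
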