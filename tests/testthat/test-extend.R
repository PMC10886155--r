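test_that("a plane extends to a plane", {
  g <- small_grid(60, 80, r_max = 5)
  rec <- topo_record(matrix(0, 60, 80), g)
  ext <- extend_surface(rec, scleral_radius = Inf)
  expect_lt(max(abs(ext$elevation)), 1e-12)
  expect_true(all(c("measured", "zernike", "scleral") %in% ext$provenance))
})

test_that("measured samples are retained verbatim", {
  spec <- small_spec(1, seed = 6)
  case <- generate_case(spec, 1)
  ext <- extend_surface(case$pre)
  meas <- ext$provenance == "measured"
  n_meas_r <- sum(case$pre$grid$radii <= ext$rim_radius)
  src <- case$pre$elevation[, seq_len(n_meas_r)]
  cov <- case$pre$coverage[, seq_len(n_meas_r)]
  expect_identical(ext$elevation[, seq_len(n_meas_r)][cov], src[cov])
  expect_identical(unname(meas[, seq_len(n_meas_r)]), unname(cov))
})

test_that("Zernike extrapolation matches a brute-force polynomial oracle", {
  # sphere measured to 5 mm; both fits extrapolate the 5.0-5.5 mm annulus
  g <- small_grid(80, 100, r_max = 5)
  rec <- sphere_record(7.8, g)
  ext <- extend_surface(rec)
  # oracle: least-squares fit of all 10 cubic monomials on the measured points
  xy <- polar_to_cartesian(g)
  vx <- as.vector(xy$x)
  vy <- as.vector(xy$y)
  X <- cbind(1, vx, vy, vx^2, vx * vy, vy^2, vx^3, vx^2 * vy, vx * vy^2, vy^3)
  cf <- qr.coef(qr(X, LAPACK = TRUE), as.vector(rec$elevation))
  ann_cols <- which(ext$grid$radii > 5 & ext$grid$radii <= 5.5)
  axy <- polar_to_cartesian(ext$grid)
  rr2 <- outer(rep(1, 80), pmin(ext$grid$radii, 7.5)^2)
  truth <- -(outer(rep(1, 80), ext$grid$radii^2) /
    (7.8 * (1 + sqrt(1 - rr2 / 7.8^2))))
  ax <- as.vector(axy$x)
  ay <- as.vector(axy$y)
  pred_oracle <- matrix(
    cbind(1, ax, ay, ax^2, ax * ay, ay^2, ax^3, ax^2 * ay, ax * ay^2, ay^3) %*% cf,
    nrow = 80
  )
  err_ext <- max(abs(ext$elevation[, ann_cols] - truth[, ann_cols]))
  err_oracle <- max(abs(pred_oracle[, ann_cols] - truth[, ann_cols]))
  expect_lte(err_ext, err_oracle * (1 + 1e-6))
})

test_that("the scleral continuation is tangent-continuous and long enough", {
  spec <- small_spec(1, seed = 8)
  pre <- generate_patient(spec, 1)$topography
  ext <- extend_surface(pre)
  expect_gte(max(ext$grid$radii), 8.0)
  # slope continuity across the rim per meridian
  i_rim <- which.min(abs(ext$grid$radii - ext$rim_radius))
  r <- ext$grid$radii
  for (a in c(1, 20, 47)) {
    s_in <- (ext$elevation[a, i_rim] - ext$elevation[a, i_rim - 1]) /
      (r[i_rim] - r[i_rim - 1])
    s_out <- (ext$elevation[a, i_rim + 1] - ext$elevation[a, i_rim]) /
      (r[i_rim + 1] - r[i_rim])
    expect_lt(abs(s_in - s_out), 0.05)
  }
})

test_that("rank-deficient fits are refused rather than extrapolated", {
  g <- small_grid(40, 50, r_max = 5)
  rec <- sphere_record(7.8, g)
  rec$coverage[, ] <- FALSE
  rec$coverage[1:2, 1:10] <- TRUE # too few points for 10 modes
  expect_error(extend_surface(rec), "rank-deficient")
})
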