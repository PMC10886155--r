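test_that("mesh-facet resampling reproduces linear fields exactly", {
  # planar quad sheet with a linear field
  xs <- seq(-3, 3, by = 0.5)
  nodes <- as.matrix(expand.grid(x = xs, y = xs))
  nodes <- cbind(nodes, 0)
  nid <- function(i, j) (j - 1L) * length(xs) + i
  quads <- do.call(rbind, lapply(seq_len(length(xs) - 1L), function(j) {
    t(vapply(seq_len(length(xs) - 1L), function(i) {
      c(nid(i, j), nid(i + 1L, j), nid(i + 1L, j + 1L), nid(i, j + 1L))
    }, integer(4)))
  }))
  vals <- 2 * nodes[, 1] + 3 * nodes[, 2]
  g <- common_grid(half_extent = 4, step = 0.25, mask_radius = 4)
  out <- resample_to_grid(list(points = nodes, values = vals, facets = quads), g)
  gx <- outer(g$x, rep(1, length(g$y)))
  gy <- outer(rep(1, length(g$x)), g$y)
  inside <- abs(gx) <= 3 & abs(gy) <= 3
  expect_lt(max(abs(out$values[inside] - (2 * gx + 3 * gy)[inside])), 1e-9)
  # outside the source: invalid, never extrapolated
  expect_true(all(is.na(out$values[abs(gx) > 3.01 | abs(gy) > 3.01])))
  expect_error(
    resample_to_grid(list(points = nodes[1:2, ], values = vals[1:2], facets = quads), g),
    "fewer than 3"
  )
})

test_that("normalisation is idempotent and sign-preserving", {
  g <- common_grid(mask_radius = 5)
  v <- matrix(rnorm(161^2), 161) * 5
  m <- as_grid_map(v, g$mask, g)
  n1 <- normalize_map(m)
  expect_equal(max(abs(n1$values[n1$mask])), 1)
  expect_identical(sign(n1$values), sign(v))
  n2 <- normalize_map(n1)
  expect_equal(n2$values, n1$values)
  zero <- as_grid_map(matrix(0, 161, 161), g$mask, g)
  expect_warning(normalize_map(zero), "all-zero")
})

test_that("the NCC surface matches the direct evaluation", {
  set.seed(5)
  worst <- 0
  for (k in 1:25) {
    f <- matrix(rnorm(81), 9)
    tt <- matrix(rnorm(81), 9)
    cm <- ncc_map(as_grid_map(tt), as_grid_map(f), min_overlap = 4L)
    dir <- ncc_direct(f, tt, min_overlap = 4L)
    both <- !is.na(cm$surface) & !is.na(dir)
    worst <- max(worst, max(abs(cm$surface - dir)[both]))
  }
  expect_lt(worst, 1e-10)
})

test_that("NCC has the expected fixed points and invariances", {
  set.seed(6)
  v <- okfea:::gaussian_filter2(matrix(rnorm(41 * 41), 41), 3)
  a <- as_grid_map(v)
  self <- ncc_map(a, a, min_overlap = 9L)
  expect_equal(self$zero_lag, 1, tolerance = 1e-10)
  neg <- ncc_map(a, as_grid_map(-v), min_overlap = 9L)
  expect_equal(neg$zero_lag, -1, tolerance = 1e-10)
  # invariant under positive affine rescaling of either map
  aff <- ncc_map(a, as_grid_map(3.7 * v + 2), min_overlap = 9L)
  both <- !is.na(self$surface) & !is.na(aff$surface)
  expect_lt(max(abs(self$surface - aff$surface)[both]), 1e-9)
  expect_error(ncc_map(as_grid_map(matrix(1, 41, 41)), a), "zero-variance")
})

test_that("the SSIM map matches direct evaluation and closed forms", {
  set.seed(7)
  worst <- 0
  for (k in 1:5) {
    x <- matrix(runif(625), 25)
    y <- matrix(runif(625), 25)
    worst <- max(worst, max(abs(ssim_map(x, y) - ssim_direct(x, y)), na.rm = TRUE))
  }
  expect_lt(worst, 1e-10)
  # identity and symmetry
  x <- matrix(runif(625), 25)
  sxx <- ssim_map(x, x)
  expect_equal(max(abs(sxx[!is.na(sxx)] - 1)), 0, tolerance = 1e-12)
  y <- matrix(runif(625), 25)
  expect_equal(ssim_map(x, y), ssim_map(y, x), tolerance = 1e-14)
  # constant x, y = x + 0.1: c = s = 1, SSIM = luminance term
  xc <- matrix(0.4, 11, 11)
  yc <- xc + 0.1
  p <- ssim_params()
  l_exp <- (2 * 0.4 * 0.5 + p$C1) / (0.4^2 + 0.5^2 + p$C1)
  s_mid <- ssim_map(xc, yc, p)[6, 6]
  expect_equal(s_mid, l_exp, tolerance = 1e-10)
  expect_error(ssim_map(matrix(0, 5, 5), matrix(0, 5, 5), ssim_params(window_size = 11)),
    "window larger")
})

test_that("band classification uses half-open edges and exact totals", {
  m <- matrix(TRUE, 10, 10)
  for (case in list(
    list(v = 0.5, band = "moderate"),
    list(v = 0.7, band = "strong"),
    list(v = -0.39, band = "weak"),
    list(v = 0.4, band = "moderate"),
    list(v = 0.6, band = "strong")
  )) {
    b <- classify_areas(matrix(case$v, 10, 10), m)
    expect_equal(b$area_pct[b$band == case$band], 100)
  }
  set.seed(2)
  b <- classify_areas(matrix(runif(100, -1, 1), 10), m)
  expect_identical(sum(b$area_pct), 100)
  expect_error(classify_areas(matrix(0.5, 2, 2), matrix(FALSE, 2, 2)), "empty")
})

test_that("cohort summaries behave under degenerate and identical inputs", {
  one <- tibble::tibble(
    metric = rep(c("ncc", "ssim"), each = 3),
    band = factor(rep(c("weak", "moderate", "strong"), 2),
      levels = c("weak", "moderate", "strong")),
    area_pct = c(80, 15, 5, 60, 30, 10),
    component = "mises"
  )
  # identical cohorts: no pair rejects
  s2 <- cohort_summary(list(one, one, one))
  expect_true(all(s2$table$sd_pct == 0))
  other <- dplyr::mutate(one, component = "pressure")
  s3 <- cohort_summary(list(
    dplyr::bind_rows(one, other), dplyr::bind_rows(one, other)
  ))
  expect_true(all(s3$pairwise$p_value > 0.05))
  # n = 1: SD undefined
  s1 <- cohort_summary(list(one))
  expect_true(all(is.na(s1$table$sd_pct)))
  # mismatched barometer sets
  expect_error(cohort_summary(list(one, other)), "mismatched")
})

test_that("KS normality screening accepts normal samples (Monte-Carlo)", {
  ok <- 0L
  for (s in 1:50) {
    set.seed(s)
    x <- rnorm(200)
    p <- suppressWarnings(ks.test((x - mean(x)) / sd(x), "pnorm")$p.value)
    if (p > 0.05) ok <- ok + 1L
  }
  expect_gte(ok / 50, 0.9)
})

test_that("comparisons bundle NCC and SSIM band tables", {
  g <- common_grid(mask_radius = 5)
  set.seed(11)
  v <- okfea:::gaussian_filter2(matrix(rnorm(161^2), 161), 5)
  rpc <- normalize_map(as_grid_map(v, g$mask, g, component = "rpc"))
  fld <- normalize_map(as_grid_map(
    okfea:::gaussian_filter2(matrix(rnorm(161^2), 161), 5),
    g$mask, g, component = "mises"
  ))
  cmp <- compare_maps(rpc, fld)
  expect_setequal(unique(cmp$bands$metric), c("ncc", "ssim"))
  sums <- tapply(cmp$bands$area_pct, cmp$bands$metric, sum)
  expect_equal(as.numeric(sums), c(100, 100), tolerance = 1e-9)
  td <- tidy_comparison(cmp)
  expect_true("component" %in% names(td))
})
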