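test_that("the text dialect round-trips losslessly", {
  spec <- small_spec(1, seed = 4)
  case <- generate_case(spec, 1)
  rec <- case$pre # includes lid-truncated coverage
  path <- withr::local_tempfile(fileext = ".topo")
  write_topography(rec, path)
  back <- read_topography(path, mirror_left = FALSE)
  expect_equal(back$elevation, rec$elevation)
  expect_identical(back$coverage, rec$coverage)
  expect_equal(back$grid$radii, rec$grid$radii)
  expect_equal(back$meta$simk_flat, rec$meta$simk_flat)
})

test_that("the default clinical dialect declares a 300 x 333 grid", {
  spec <- cohort_spec(1, seed = 1)
  rec <- generate_patient(spec, 1)$topography
  expect_equal(dim(rec$elevation), c(300L, 333L))
  path <- withr::local_tempfile(fileext = ".topo")
  write_topography(rec, path)
  back <- read_topography(path, mirror_left = FALSE)
  expect_equal(dim(back$elevation), c(300L, 333L))
})

test_that("malformed dialect files give named diagnostics", {
  rec <- sphere_record(7.8, small_grid(24, 30))
  path <- withr::local_tempfile(fileext = ".topo")
  write_topography(rec, path)
  lines <- readLines(path)
  # truncated: drop the coverage section
  trunc <- withr::local_tempfile()
  writeLines(lines[seq_len(which(lines == "COVERAGE") - 1L)], trunc)
  expect_error(read_topography(trunc), "COVERAGE")
  # dimension mismatch in the radii line
  bad <- lines
  bad[which(bad == "RADII") + 1L] <- "0 1 2"
  badf <- withr::local_tempfile()
  writeLines(bad, badf)
  expect_error(read_topography(badf), "dimension mismatch")
  # non-monotone radii
  bad2 <- lines
  rl <- which(bad2 == "RADII") + 1L
  rr <- rev(strsplit(bad2[rl], " ")[[1]])
  bad2[rl] <- paste(rr, collapse = " ")
  badf2 <- withr::local_tempfile()
  writeLines(bad2, badf2)
  expect_error(read_topography(badf2), "monotone")
  # unparseable numbers
  bad3 <- lines
  el <- which(bad3 == "ELEVATION") + 1L
  bad3[el] <- sub("^[-0-9.e+]+", "bogus", bad3[el])
  badf3 <- withr::local_tempfile()
  writeLines(bad3, badf3)
  expect_error(read_topography(badf3), "unparseable")
  # not a dialect file at all
  plain <- withr::local_tempfile()
  writeLines("hello", plain)
  expect_error(read_topography(plain), "OKFEA-TOPO")
})

test_that("left eyes are mirrored into the right-eye frame at ingest", {
  g <- small_grid(60, 40)
  # a surface with a known left-right asymmetry: tilt in x
  xy <- polar_to_cartesian(g)
  z <- -(xy$x^2 + xy$y^2) / 16 + 0.01 * xy$x
  rec <- topo_record(z, g, meta = list(eye = "left"))
  path <- withr::local_tempfile()
  write_topography(rec, path)
  mirrored <- read_topography(path)
  # x -> -x: the tilt sign flips
  zq <- okfea:::interp_polar_field(g, mirrored$elevation, 2, 0.5)
  zq_expected <- -(4 + 0.25) / 16 + 0.01 * (-2)
  expect_equal(zq, zq_expected, tolerance = 1e-6)
  expect_true(isTRUE(mirrored$meta$mirrored))
})

test_that("polar-cartesian round trip reproduces sampled elevations", {
  rec <- sphere_record(7.7, small_grid())
  xy <- polar_to_cartesian(rec$grid)
  zq <- okfea:::interp_polar_field(
    rec$grid, rec$elevation, as.vector(xy$x), as.vector(xy$y)
  )
  expect_lt(max(abs(zq - as.vector(rec$elevation))), 1e-9)
})
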