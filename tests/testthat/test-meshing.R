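test_that("the O-grid disk template has the documented counts", {
  for (b in c(4L, 6L)) {
    for (rings in c(8L, 30L)) {
      tpl <- disk_ogrid(b, rings)
      expect_equal(nrow(tpl$quads), b^2 + 4L * b * rings)
      expect_equal(nrow(tpl$xy), (b + 1L)^2 + 4L * b * rings)
    }
  }
})

test_that("spherical template mapping is exact on spheres and ellipsoids", {
  g <- small_grid(120, 160, r_max = 5)
  rec <- sphere_record(7.8, g)
  ext <- extend_surface(rec)
  origin <- c(0, 0, -7.8)
  azi <- seq(0, 2 * pi, length.out = 37)[-37]
  pol <- rep(0.3, length(azi))
  rad <- spherical_template_map(ext, azi, pol, origin)
  expect_lt(max(abs(rad - 7.8)), 1e-6)
  # ellipsoid: analytic radius oracle
  a <- 7.5; b <- 7.9; cc <- 7.6
  xy <- polar_to_cartesian(g)
  zel <- cc * sqrt(pmax(1 - xy$x^2 / a^2 - xy$y^2 / b^2, 0)) - cc
  recel <- topo_record(zel, g)
  extel <- extend_surface(recel)
  pol2 <- seq(0.05, 0.55, length.out = 36)
  azi2 <- seq(0.1, 2 * pi, length.out = 36)
  rad2 <- spherical_template_map(extel, azi2, pol2, c(0, 0, -cc))
  dir <- cbind(sin(pol2) * cos(azi2), sin(pol2) * sin(azi2), cos(pol2))
  r_true <- 1 / sqrt((dir[, 1] / a)^2 + (dir[, 2] / b)^2 + (dir[, 3] / cc)^2)
  expect_lt(max(abs(rad2 - r_true) / r_true), 1e-4)
  # out-of-support queries are refused
  expect_error(spherical_template_map(ext, 0, 1.5, origin), "angular support")
})

test_that("the cornea mesh respects the thickness law and counts", {
  fix <- coarse_cornea(seed = 7, base = 4L, rings = 10L, layers = 4L)
  mesh <- fix$mesh
  expect_equal(nrow(mesh$elems), (16L + 160L) * 4L)
  ant <- mesh$nodes[mesh$nsets$anterior_nodes, ]
  n_sheet <- length(mesh$nsets$anterior_nodes)
  post <- mesh$nodes[4L * n_sheet + seq_len(n_sheet), ]
  thick <- sqrt(rowSums((ant - post)^2))
  r_lat <- sqrt(ant[, 1]^2 + ant[, 2]^2)
  expected <- fix$patient$cct + 0.18 * pmin(r_lat / 5.5, 1)
  expect_lt(max(abs(thick - expected)), 1e-9)
  # apex node carries exactly the central corneal thickness
  apex <- which.min(r_lat)
  expect_equal(thick[apex], fix$patient$cct, tolerance = 1e-3)
  # thickness at half the limbal radius: cct + 0.09 mm
  half <- which.min(abs(r_lat - 2.75))
  expect_equal(thick[half], fix$patient$cct + 0.18 * r_lat[half] / 5.5,
    tolerance = 1e-9)
  # anterior nodes reproduce the input surface
  zq <- okfea:::interp_polar_field(fix$ext$grid, fix$ext$elevation,
    ant[, 1], ant[, 2])
  expect_lt(stats::median(abs(ant[, 3] - zq)), 1e-3)
})

test_that("mesh presets give the documented element counts", {
  desk <- mesh_preset("desk")
  expect_equal(
    (desk$cornea_base^2 + 4 * desk$cornea_base * desk$cornea_rings) * desk$cornea_layers,
    5120
  )
  paper <- mesh_preset("paper")
  expect_equal(
    (paper$cornea_base^2 + 4 * paper$cornea_base * paper$cornea_rings) * paper$cornea_layers,
    16400
  )
})

test_that("the lens profile is continuous with the stated centre thickness", {
  prof <- build_lens_profile(lens_design())
  # C0 at every back junction
  for (rj in prof$back_junctions[-c(1, length(prof$back_junctions))]) {
    gap <- abs(prof$back_fun(rj - 1e-9) - prof$back_fun(rj + 1e-9))
    expect_lt(gap, 1e-6)
  }
  for (rj in prof$front_junctions[-c(1, length(prof$front_junctions))]) {
    gap <- abs(prof$front_fun(rj - 1e-9) - prof$front_fun(rj + 1e-9))
    expect_lt(gap, 1e-6)
  }
  expect_equal(prof$front_fun(0) - prof$back_fun(0), 0.22)
  # positive thickness across the chord
  r <- seq(0, 5.3, length.out = 201)
  expect_true(all(prof$front_fun(r) - prof$back_fun(r) > 0))
})

test_that("invalid lens designs are rejected", {
  expect_error(lens_design(back_widths = c(3, 0.6, 0.8, 0.6, 0.2)), "sum to")
  expect_error(lens_design(centre_thickness = 0), "thickness")
  expect_error(lens_design(front_radii = c(8.7, -1, 4)), "radii")
})

test_that("the lens mesh matches the combinatorial counts and the profile", {
  mesh <- build_lens_mesh(lens_design(), element_base = 4L, rings = 30L, layers = 2L)
  expect_equal(nrow(mesh$elems), 2L * (16L + 480L))
  prof <- build_lens_profile(lens_design())
  back <- mesh$nodes[mesh$nsets$lens_back_nodes, ]
  r <- sqrt(back[, 1]^2 + back[, 2]^2)
  expect_lt(max(abs(back[, 3] - prof$back_fun(r))), 1e-6)
  front <- mesh$nodes[mesh$nsets$lens_front_nodes, ]
  rf <- sqrt(front[, 1]^2 + front[, 2]^2)
  expect_lt(max(abs(front[, 3] - prof$front_fun(rf))), 1e-6)
  mesh_check(mesh)
  # 90-degree rotation maps the node set onto itself
  rot <- cbind(-mesh$nodes[, 2], mesh$nodes[, 1], mesh$nodes[, 3])
  key <- function(m) sort(paste(round(m[, 1], 6), round(m[, 2], 6), round(m[, 3], 6)))
  expect_identical(key(rot), key(mesh$nodes))
})

test_that("meshes pass validity checks", {
  shell <- mesh_spherical_shell(11.5, 12.05, n = 6L, layers = 2L)
  expect_true(mesh_check(shell))
  fix <- coarse_cornea(seed = 7, base = 4L, rings = 8L, layers = 2L)
  expect_true(mesh_check(fix$mesh))
})

test_that("mesh exports write the declared sections", {
  mesh <- build_lens_mesh(lens_design(), element_base = 4L, rings = 6L)
  inp <- withr::local_tempfile(fileext = ".inp")
  write_inp(mesh, inp)
  txt <- readLines(inp)
  expect_true(any(grepl("^\\*NODE", txt)))
  expect_true(any(grepl("TYPE=C3D8", txt)))
  expect_true(any(grepl("NSET=LENS_BACK_NODES", txt)))
  vtk <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(mesh, vtk, point_data = list(z = mesh$nodes[, 3]))
  vt <- readLines(vtk)
  expect_true(any(grepl("UNSTRUCTURED_GRID", vt)))
  expect_true(any(grepl("CELL_TYPES", vt)))
})
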