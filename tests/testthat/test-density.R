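test_that("binarisation is a fixed threshold with idempotence", {
  z <- voxel_volume(array(0, dim = c(8, 8, 8)), 0.1)
  expect_true(all(binarise(z, 0.5)$values == 0))
  set.seed(1)
  g <- voxel_volume(array(runif(16^3), dim = c(16, 16, 16)), 0.1)
  b <- binarise(g, 0.4)
  expect_equal(sum(b$values), sum(g$values >= 0.4))   # count oracle
  expect_identical(binarise(b, 0.5)$values, b$values) # idempotent
  gg <- g; gg$values[5] <- NaN
  expect_error(binarise(gg, 0.4), "1 non-finite")
})

test_that("downsampling to BV/TV conserves bone volume and spacing", {
  set.seed(2)
  v <- (array(runif(32^3), dim = c(32, 32, 32)) > 0.5) * 1
  vol <- voxel_volume(v, 0.082, binary = TRUE)
  f <- downsample_to_bvtv(vol, 2L)
  expect_equal(f$spacing, 0.164)
  expect_equal(mean(f$values), mean(v))    # exact for divisible shapes
  # brute-force block means on a 3D checkerboard
  idx <- as.matrix(expand.grid(1:8, 1:8, 1:8))
  cb <- array((rowSums(idx) %% 2), dim = c(8, 8, 8))
  fc <- downsample_to_bvtv(voxel_volume(cb, 0.1, binary = TRUE), 2L)
  expect_true(all(abs(fc$values - 0.5) < 1e-12))
  solid <- downsample_to_bvtv(
    voxel_volume(array(1, dim = c(8, 8, 8)), 0.1, binary = TRUE), 2L)
  expect_true(all(solid$values == 1))
  expect_error(downsample_to_bvtv(voxel_volume(array(0.5, dim = c(4, 4, 4)),
                                               0.1), 2L),
               "binary")
})

test_that("element moduli follow E = c * BV/TV with a floor", {
  mesh <- solid_cube_mesh(4)
  uniform <- structure(list(values = array(1, dim = c(10, 10, 10)),
                            spacing = 0.5, origin = c(0, 0, 0)),
                       class = "density_field")
  m <- assign_element_moduli(mesh, uniform, material_map(100.5))
  expect_true(all(abs(m$E - 100.5) < 1e-12))
  void <- uniform; void$values[] <- 0
  m0 <- assign_element_moduli(mesh, void, material_map(100.5, 0.1))
  expect_true(all(m0$E == 0.1))     # floor rule
  # linear-gradient field vs dense volume-weighted sampling, within 2%
  grad <- uniform
  grad$values <- array(rep((0:9 + 0.5) / 10, each = 100),
                       dim = c(10, 10, 10))
  grad$values <- aperm(grad$values, c(3, 2, 1))  # gradient along x
  mg <- assign_element_moduli(mesh, grad, material_map(100, 1e-6))
  # dense oracle: average the field over each element by brute sampling
  for (e in c(1, 7, 20)) {
    nodes <- mesh$nodes[mesh$elements[e, ], ]
    s <- seq(0.05, 0.95, by = 0.1)
    pts <- as.matrix(expand.grid(s, s, s))
    pts <- pts[rowSums(pts) <= 1, ]   # inside the unit tet
    xyz <- t(nodes[1, ] + t(pts %*% (nodes[2:4, ] - rep(1, 3) %o%
                                       nodes[1, ])))
    ex <- mean(100 * pmin(0.95, pmax(0.05, xyz[, 1] / 5)))
    expect_equal(mg$E[e], ex, tolerance = 0.02 * ex + 1.5)
  }
  # monotone and linear in c as the floor vanishes
  m1 <- assign_element_moduli(mesh, grad, material_map(100, 1e-9))
  m2 <- assign_element_moduli(mesh, grad, material_map(200, 1e-9))
  expect_true(all(m2$E >= m1$E))
  expect_equal(m2$E, 2 * m1$E, tolerance = 1e-9)
  expect_error(assign_element_moduli(solid_cube_mesh(2, "pmma"), uniform,
                                     material_map()),
               "no bone")
})
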