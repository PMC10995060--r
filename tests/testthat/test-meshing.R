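test_that("structured meshing fills cubes with six conforming tets", {
  mesh <- solid_cube_mesh(10)
  expect_equal(nrow(mesh$elements), 6000)     # 10^3 cubes x 6
  vols <- ocgraft:::tet_signed_volumes(mesh$nodes, mesh$elements)
  expect_gt(min(vols), 0)
  expect_equal(sum(vols), 1000)               # exact volume conservation
  # determinism
  mesh2 <- solid_cube_mesh(10)
  expect_identical(mesh$nodes, mesh2$nodes)
  expect_identical(mesh$elements, mesh2$elements)
  expect_error(mesh_labelled_volume(
    label_volume(array(0L, dim = c(4, 4, 4)), 1, c(bone = 1L))),
    "no non-void")
})

test_that("cylinder meshes match analytic volume and wall area", {
  m <- mesh_cylinder(5, 10, edge = 1)
  vol <- sum(ocgraft:::tet_signed_volumes(m$nodes, m$elements))
  expect_lt(abs(vol - pi * 25 * 10) / (pi * 25 * 10), 0.05)
  expect_lt(abs(patch_area(m, "wall_body") - pi * 10 * 10) / (pi * 100),
            0.08)
})

test_that("patches select oriented boundary faces", {
  mesh <- solid_cube_mesh(5)
  mesh <- extract_patch(mesh, "bone", "void",
                        predicate = function(cn, n) n[, 3] > 0.9,
                        name = "top")
  expect_equal(nrow(mesh$patches$top$tri), 2 * 25)  # 2 triangles per face
  g <- ocgraft:::face_normals_areas(mesh$nodes, mesh$patches$top$tri)
  expect_true(all(g$normal[, 3] > 0.999))           # outward +z
  expect_error(extract_patch(mesh, "bone", "void",
                             predicate = function(cn, n) rep(FALSE, nrow(cn)),
                             name = "none"),
               "predicate")
})

test_that("quality report matches hand-computed single-cube values", {
  mesh <- solid_cube_mesh(1)
  q <- mesh_quality_report(mesh)
  expect_equal(q$n_elements, 6)
  # independent brute force: aspect = longest edge x largest face area
  # over three volumes, per element
  aspects <- vapply(seq_len(6), function(e) {
    nd <- mesh$nodes[mesh$elements[e, ], ]
    combs <- utils::combn(4, 2)
    emax <- max(apply(combs, 2, function(cb)
      sqrt(sum((nd[cb[1], ] - nd[cb[2], ])^2))))
    fmax <- max(apply(utils::combn(4, 3), 2, function(f) {
      v1 <- nd[f[2], ] - nd[f[1], ]; v2 <- nd[f[3], ] - nd[f[1], ]
      sqrt(sum(c(v1[2] * v2[3] - v1[3] * v2[2],
                 v1[3] * v2[1] - v1[1] * v2[3],
                 v1[1] * v2[2] - v1[2] * v2[1])^2)) / 2
    }))
    vol <- abs(det(cbind(nd[2, ] - nd[1, ], nd[3, ] - nd[1, ],
                         nd[4, ] - nd[1, ]))) / 6
    emax * fmax / (3 * vol)
  }, numeric(1))
  expect_equal(q$aspect[["max"]], max(aspects), tolerance = 1e-12)
  expect_true(q$edge[["median"]] >= 0.75 && q$edge[["median"]] <= 1.25)
  expect_error(mesh_quality_report(list(elements = NULL)), "empty")
})

test_that("meshes survive rigid transforms and merging", {
  a <- solid_cube_mesh(3)
  b <- transform_mesh(solid_cube_mesh(3), translate = c(10, 0, 0),
                      rotation = matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3))
  vols_b <- ocgraft:::tet_signed_volumes(b$nodes, b$elements)
  expect_gt(min(vols_b), 0)
  ab <- combine_meshes(a, b)
  expect_equal(nrow(ab$elements), 2 * nrow(a$elements))
  expect_equal(sum(ocgraft:::tet_signed_volumes(ab$nodes, ab$elements)),
               2 * 27)
})
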