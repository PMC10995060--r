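test_that("uniaxial bar reproduces EA/L and the series-bar compliance", {
  mats <- region_materials(bone = list(kind = "linear_elastic",
                                       E = 100, nu = 0.3))
  bar <- bar_stiffness(solid_cube_mesh(10), mats)
  expect_equal(bar$k, 100 * 100 / 10, tolerance = 1e-3)   # EA/L
  # two-material series bar: 5 mm at E1 over 5 mm at E2
  lv <- label_volume(array(rep(c(1L, 2L), each = 10 * 10 * 5),
                           dim = c(10, 10, 10)), 1,
                     c(stiff = 1L, soft = 2L))
  m2 <- mesh_labelled_volume(lv, mesh_settings(1.0))
  mats2 <- region_materials(stiff = list(kind = "linear_elastic",
                                         E = 200, nu = 1e-9),
                            soft = list(kind = "linear_elastic",
                                        E = 50, nu = 1e-9))
  k2 <- bar_stiffness(m2, mats2)$k
  k_oracle <- 1 / (5 / (200 * 100) + 5 / (50 * 100))
  expect_equal(k2, k_oracle, tolerance = 1e-3)
})

test_that("the patch test passes to machine precision", {
  mesh <- solid_cube_mesh(4)
  A <- matrix(c(1e-3, 2e-4, -1e-4, 3e-4, -5e-4, 2e-4, 1e-4, 2e-4, 8e-4),
              3, 3, byrow = TRUE)
  ft <- ocgraft:::tet_face_table(mesh)
  bnodes <- unique(as.vector(
    ft$faces[!(ft$key %in% ft$key[duplicated(ft$key)]), ]))
  ub <- mesh$nodes[bnodes, ] %*% t(A)
  cons <- lapply(seq_along(bnodes), function(i)
    prescribed_nodes(bnodes[i], ub[i, ], name = paste0("b", i)))
  mats <- region_materials(bone = list(kind = "linear_elastic",
                                       E = 100, nu = 0.3))
  sol <- solve_linear_static(mesh, mats, cons)
  expect_lt(max(abs(sol$u - mesh$nodes %*% t(A))), 1e-12)
})

test_that("neo-Hookean matches its small-strain linearisation", {
  K <- 16.67; G <- 1.37
  Eeq <- 9 * K * G / (3 * K + G)
  nueq <- (3 * K - 2 * G) / (6 * K + 2 * G)
  lv <- label_volume(array(1L, dim = c(5, 5, 5)), 1, c(cart = 1L))
  mesh <- mesh_labelled_volume(lv, mesh_settings(1.0))
  matsL <- region_materials(cart = list(kind = "linear_elastic",
                                        E = Eeq, nu = nueq))
  matsN <- region_materials(cart = list(kind = "neo_hookean", K = K, G = G))
  linear <- bar_stiffness(mesh, matsL, d = 0.005)  # 0.1% strain
  modN <- fe_model(mesh, matsN, linear$cons)
  solN <- solve_nonlinear_static(modN,
                                 data.frame(lambda = c(0.5, 1),
                                            allowance = 0))
  FL <- linear$sol$reactions$platen$force[3]
  FN <- solN$reactions$platen$force[3]
  expect_lt(abs(FN - FL) / abs(FL), 0.01)
})

test_that("the nonlinear solver reduces to the linear one without contact", {
  mats <- region_materials(bone = list(kind = "linear_elastic",
                                       E = 80, nu = 0.3))
  mesh <- solid_cube_mesh(5)
  lin <- bar_stiffness(mesh, mats)
  mod <- fe_model(mesh, mats, lin$cons)
  sol <- solve_nonlinear_static(mod, data.frame(lambda = 1, allowance = 0),
                                rel_tol = 1e-10, abs_tol = 1e-8)
  expect_lt(max(abs(sol$u_vec - lin$sol$u_vec)) /
              max(abs(lin$sol$u_vec)), 1e-6)
})

test_that("kinematic couplings move patches rigidly and report reactions", {
  mesh <- solid_cube_mesh(4)
  mesh <- extract_patch(mesh, "bone", "void",
                        function(cn, n) n[, 3] > 0.9, name = "top")
  mesh <- extract_patch(mesh, "bone", "void",
                        function(cn, n) n[, 3] < -0.9, name = "bot")
  mats <- region_materials(bone = list(kind = "linear_elastic",
                                       E = 100, nu = 0.3))
  ref <- c(2, 2, 4)
  # prescribed translation: patch nodes translate exactly
  sol <- solve_linear_static(mesh, mats, list(
    encastre(patch = "bot", name = "base"),
    kinematic_coupling("top", ref, displacement = c(0, 0, -1),
                       name = "pl")))
  top_nodes <- ocgraft:::patch_nodes(mesh, "top")
  expect_true(all(abs(sol$u[top_nodes, 3] + 1) < 1e-12))
  expect_true(all(abs(sol$u[top_nodes, 1:2]) < 1e-12))
  # prescribed finite rotation: exact rigid rotation of the patch
  th <- 0.3
  sol_r <- solve_linear_static(mesh, mats, list(
    encastre(patch = "bot", name = "base"),
    kinematic_coupling("top", ref, displacement = c(0, 0, 0),
                       rotation = c(th, 0, 0), name = "pl")))
  R <- ocgraft:::rodrigues(c(th, 0, 0))
  r0 <- sweep(mesh$nodes[top_nodes, ], 2, ref)
  u_exact <- r0 %*% t(R) - r0
  expect_lt(max(abs(sol_r$u[top_nodes, ] - u_exact)), 1e-12)
  # reaction bookkeeping: coupling reaction balances the encastre
  expect_equal(sol$reactions$pl$force + sol$reactions$base$force,
               c(0, 0, 0), tolerance = 1e-8)
  # degenerate coupling patch is rejected
  expect_error(apply_kinematic_coupling(mesh, "top",
                                        ref_point = mesh$nodes[top_nodes[1], ]),
               NA)
})

test_that("frictionless contact carries the applied load", {
  mod <- stacked_blocks_model(load = 50, mu = 0)
  sol <- solve_nonlinear_static(mod, data.frame(lambda = c(0.5, 1),
                                                allowance = 0))
  ct <- sol$contact[[1]]
  expect_lt(abs(sum(ct$Fn) - 50) / 50, 0.005)
  expect_equal(sol$reactions$base$force[3], 50, tolerance = 0.01)
  # tangential tractions vanish at mu = 0
  expect_lt(max(abs(ct$t_vec)), 1e-3 * max(ct$Fn))
})

test_that("rigid rotation of the whole model leaves force magnitudes", {
  mats <- region_materials(bone = list(kind = "linear_elastic",
                                       E = 100, nu = 0.3))
  mesh <- solid_cube_mesh(4)
  mesh <- extract_patch(mesh, "bone", "void",
                        function(cn, n) n[, 3] > 0.9, name = "top")
  mesh <- extract_patch(mesh, "bone", "void",
                        function(cn, n) n[, 3] < -0.9, name = "bot")
  base_cons <- function(m, dvec) list(
    encastre(patch = "bot", name = "base"),
    kinematic_coupling("top", c(2, 2, 4), displacement = dvec,
                       name = "pl"))
  s1 <- solve_linear_static(mesh, mats, base_cons(mesh, c(0, 0, -0.5)))
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  mr <- transform_mesh(mesh, rotation = R, centre = c(2, 2, 0))
  # same load expressed in the rotated frame
  cons_r <- list(
    encastre(patch = "bot", name = "base"),
    kinematic_coupling("top", as.numeric(R %*% (c(2, 2, 4) - c(2, 2, 0))) +
                         c(2, 2, 0),
                       displacement = as.numeric(R %*% c(0, 0, -0.5)),
                       name = "pl"))
  s2 <- solve_linear_static(mr, mats, cons_r)
  f1 <- sqrt(sum(s1$reactions$pl$force^2))
  f2 <- sqrt(sum(s2$reactions$pl$force^2))
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("unconstrained models raise a singular-system error", {
  mats <- region_materials(bone = list(kind = "linear_elastic",
                                       E = 100, nu = 0.3))
  mesh <- solid_cube_mesh(3)
  expect_error(solve_linear_static(mesh, mats, list()),
               "singular|null-space")
})
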