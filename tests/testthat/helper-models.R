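# shared small fixtures, built in code

suppressPackageStartupMessages(library(Matrix))

# solid single-region cube, n mm on edge, 1 mm elements
solid_cube_mesh <- function(n = 10, region = "bone") {
  lv <- label_volume(array(1L, dim = c(n, n, n)), spacing = 1,
                     labels = stats::setNames(1L, region))
  mesh_labelled_volume(lv, mesh_settings(1.0))
}

# roller-BC uniaxial bar: bottom z fixed, top z prescribed, lateral free
# (two pins kill in-plane rigid modes); returns |F|/d
bar_stiffness <- function(mesh, materials, d = 1) {
  nd <- mesh$nodes
  zmin <- min(nd[, 3]); zmax <- max(nd[, 3])
  bot <- which(abs(nd[, 3] - zmin) < 1e-9)
  top <- which(abs(nd[, 3] - zmax) < 1e-9)
  c1 <- bot[which.min(nd[bot, 1] + nd[bot, 2])]
  c2 <- bot[which.max(nd[bot, 1] - nd[bot, 2])]
  cons <- list(prescribed_nodes(bot, c(NA, NA, 0), name = "base"),
               prescribed_nodes(top, c(NA, NA, -d), name = "platen"),
               prescribed_nodes(c1, c(0, 0, NA), name = "p1"),
               prescribed_nodes(c2, c(NA, 0, NA), name = "p2"))
  sol <- solve_linear_static(mesh, materials, cons)
  list(k = abs(sol$reactions$platen$force[3]) / d, sol = sol,
       cons = cons, top = top, bot = bot)
}

# two stacked 6x6x3 blocks touching at z = 3, frictionless contact,
# force-controlled load on the upper block
stacked_blocks_model <- function(load = 50, mu = 0, E = 100) {
  mk <- function(dz0) {
    lv <- label_volume(array(1L, dim = c(6, 6, 3)), spacing = 1,
                       labels = c(bone = 1L))
    transform_mesh(mesh_labelled_volume(lv, mesh_settings(1.0)),
                   translate = c(0, 0, dz0))
  }
  lower <- mk(0); upper <- mk(3)
  lower <- extract_patch(lower, "bone", "void",
                         function(cn, n) n[, 3] > 0.9, name = "low_top")
  lower <- extract_patch(lower, "bone", "void",
                         function(cn, n) n[, 3] < -0.9, name = "low_bot")
  upper <- extract_patch(upper, "bone", "void",
                         function(cn, n) n[, 3] < -0.9, name = "up_bot")
  upper <- extract_patch(upper, "bone", "void",
                         function(cn, n) n[, 3] > 0.9, name = "up_top")
  mm <- combine_meshes(lower, upper)
  mats <- region_materials(bone = list(kind = "linear_elastic",
                                       E = E, nu = 0.3))
  cons <- list(encastre(patch = "low_bot", name = "base"),
               kinematic_coupling("up_top", ref_point = c(2.5, 2.5, 6),
                                  displacement = c(0, 0, NA),
                                  force = c(0, 0, -load), name = "load"))
  fe_model(mm, mats, cons, list(contact_pair("up_bot", "low_top", mu = mu)))
}

# standard small push-in pair: spacing/geometry of the cadaveric protocol
push_pair_fixture <- function(host_bvtv = 0.6, graft_bvtv = 0.7,
                              seed = 11, geom = graft_geometry()) {
  generate_graft_host_pair(
    trabecular_params(host_bvtv, seed = seed),
    trabecular_params(graft_bvtv, seed = seed + 1),
    geom, spacing = 0.164, margin = 2)
}

# offset rasterised disc patch (for sensel arithmetic)
disc_map <- function(radius_mm, pitch = 1.27, ox = 0, oy = 0, value = 1) {
  n <- ceiling(2 * radius_mm / pitch) + 6
  cx <- (n + 1) / 2 + ox; cy <- (n + 1) / 2 + oy
  v <- outer(1:n, 1:n, function(i, j)
    (((i - cx)^2 + (j - cy)^2) <= (radius_mm / pitch)^2) * value)
  pressure_map(v, pitch)
}
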