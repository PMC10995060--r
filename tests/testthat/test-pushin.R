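# small shared push-in fixtures (built once per file)
geom_std <- graft_geometry()
pair_std <- push_pair_fixture(geom = geom_std)
map_std <- material_map(100.5)

test_that("interference prestress equilibrates with Lame-level pressure", {
  # homogeneous near-solid bodies so the thick-walled-cylinder estimate
  # applies
  geom <- graft_geometry(hole_depth = 12, graft_length = 10)
  pair <- generate_graft_host_pair(trabecular_params(0.95, seed = 21),
                                   trabecular_params(0.95, seed = 22),
                                   geom, spacing = 0.164)
  prot <- push_in_protocol(mu_bone_bone = 0, mu_cartilage_bone = 0)
  pim <- build_push_in_model(pair, map_std, prot, mesh_settings(1.5),
                             materials = linearised_materials(),
                             seat = "flush")
  ps <- graft_insertion_prestress(pim, n_steps = 3)
  E <- 0.95 * 100.5
  r <- geom$hole_diameter / 2
  b <- r + 2           # lateral bone margin
  p_lame <- 0.075 * E * (b^2 - r^2) / (2 * r * b^2)
  expect_lt(abs(ps$mean_wall_pressure - p_lame) / p_lame, 0.3)
  expect_gt(ps$mean_wall_pressure, 0)
})

test_that("push-in force vanishes without interference or friction", {
  geom0 <- graft_geometry(graft_diameter = 6.35, hole_diameter = 6.35,
                          hole_depth = 12, graft_length = 10)
  pair0 <- generate_graft_host_pair(trabecular_params(0.6, seed = 31),
                                    trabecular_params(0.6, seed = 32),
                                    geom0, spacing = 0.164)
  prot0 <- push_in_protocol(mu_bone_bone = 0, mu_cartilage_bone = 0)
  pim0 <- build_push_in_model(pair0, map_std, prot0, mesh_settings(1.5),
                              materials = linearised_materials(),
                              seat = "flush")
  res0 <- run_push_in_test(pim0, prot0, n_steps = 3)
  expect_lt(abs(res0$force_at_full), 1)
})

test_that("seating metadata reports the drill/graft length mismatch", {
  # drill 11.1 mm vs 10 mm graft: fully seated flush offset is -1.1 mm
  geom_m <- graft_geometry(hole_depth = 11.1, graft_length = 10)
  pair_m <- generate_graft_host_pair(trabecular_params(0.6, seed = 41),
                                     trabecular_params(0.7, seed = 42),
                                     geom_m, spacing = 0.164)
  expect_equal(pair_m$meta$flush_offset_seated, -1.1)
  pim_m <- build_push_in_model(pair_m, map_std, push_in_protocol(),
                               mesh_settings(1.0),
                               materials = linearised_materials())
  ps_m <- graft_insertion_prestress(pim_m, n_steps = 3)
  # the meshed model reproduces it to within element quantisation
  expect_lt(abs(ps_m$flush_offset - (-1.1)), 0.75)
  expect_lt(ps_m$flush_offset, 0)
})

test_that("push-in force is penalty-insensitive at the default", {
  prot <- push_in_protocol()
  f <- vapply(c(1500, 3000), function(kn) {
    pim <- build_push_in_model(pair_std, map_std, prot, mesh_settings(1.8),
                               materials = linearised_materials(),
                               normal_penalty = kn)
    run_push_in_test(pim, prot, n_steps = 3)$force_at_full
  }, numeric(1))
  expect_lt(abs(f[2] - f[1]) / f[1], 0.02)
})
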