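test_that("trabecular phantoms hit the target bone volume fraction", {
  p <- trabecular_params(0.818, correlation_length = 0.5, seed = 3)
  v <- generate_trabecular_volume(c(32, 32, 32), 0.082, p)
  achieved <- sum(v$values) / length(v$values)   # brute-force voxel count
  expect_true(achieved >= 0.808 && achieved <= 0.828)
  # determinism: same parameters and seed reproduce voxel-for-voxel
  v2 <- generate_trabecular_volume(c(32, 32, 32), 0.082, p)
  expect_identical(v$values, v2$values)
  # near-solid limit
  vs <- generate_trabecular_volume(c(16, 16, 16), 0.082,
                                   trabecular_params(0.999, seed = 1))
  expect_gte(mean(vs$values), 0.99)
})

test_that("depth gradient shapes per-slice density without moving the mean", {
  p <- trabecular_params(0.6, depth_gradient = -0.05, seed = 9)
  v <- generate_trabecular_volume(c(24, 24, 32), 0.164, p)
  slice_means <- apply(v$values, 3, mean)
  expect_lt(mean(v$values) - 0.6, 0.01)
  fit <- stats::coef(stats::lm(slice_means ~ I((seq_len(32) - 1) * 0.164)))
  expect_equal(unname(fit[2]), -0.05, tolerance = 0.05)
  # unreachable slice target is an invalid-parameter error
  expect_error(generate_trabecular_volume(
    c(16, 16, 64), 0.164, trabecular_params(0.9, depth_gradient = -0.2,
                                            seed = 1)),
    "invalid")
})

test_that("condyle specimens are labelled, potted and density-controlled", {
  sp <- generate_condyle_specimen(trabecular_params(0.6, seed = 4),
                                  endcap_thickness = 5,
                                  shape = c(32, 32, 80), spacing = 0.164)
  expect_setequal(label_names_present(sp$labels), c("void", "bone", "pmma"))
  # cap slice count follows round(thickness / spacing)
  ncap <- sp$labels$meta$endcap_slices
  expect_true(ncap %in% c(30L, 31L))
  # bone-region BV/TV equals the target within 0.01 (count oracle)
  bone_mask <- sp$labels$values == sp$labels$labels[["bone"]]
  expect_lt(abs(sum(sp$micro$values[bone_mask]) / sum(bone_mask) - 0.6),
            0.01)
  # every voxel carries exactly one label by construction
  expect_true(all(sp$labels$values %in% c(0L, unname(sp$labels$labels))))
})

test_that("graft/host pairs carry the interference and hole geometry", {
  geom <- graft_geometry()       # 6.5 into 6.35, 10 mm
  pair <- push_pair_fixture(geom = geom)
  expect_equal(pair$meta$diametral_interference, 0.15)
  # hole voxel volume close to the analytic cylinder
  hole_region <- pair$host$labels$values == 0L
  # restrict to the drilled depth below the articular surface
  nz_hole <- round(geom$hole_depth / 0.164)
  nvox <- sum(hole_region[, , seq_len(nz_hole)])
  analytic <- pi * (geom$hole_diameter / 2)^2 * geom$hole_depth / 0.164^3
  expect_lt(abs(nvox - analytic) / analytic, 0.05)
  # same generator parameters give identical statistics in both bodies
  g2 <- generate_graft_host_pair(trabecular_params(0.6, seed = 77),
                                 trabecular_params(0.6, seed = 77),
                                 geom, spacing = 0.164)
  host_b <- mean(g2$host$micro$values[g2$host$labels$values == 1L])
  graft_b <- mean(g2$graft$micro$values[g2$graft$labels$values == 4L])
  expect_lt(abs(host_b - graft_b), 0.03)
})

test_that("pseudo-observations add seeded noise around the forward model", {
  truth <- c(a = 100, b = 150, c = 210)
  o0 <- generate_pseudo_observations(truth, noise_sd = 0, seed = 2)
  expect_equal(o0$value, unname(truth))
  o1 <- generate_pseudo_observations(truth, noise_sd = 10, seed = 2)
  o2 <- generate_pseudo_observations(truth, noise_sd = 10, seed = 2)
  expect_identical(o1, o2)
  # Monte-Carlo: sample SD of the residuals in a factor-2 band at n = 6
  tr6 <- rep(100, 6)
  sds <- vapply(1:40, function(s)
    stats::sd(generate_pseudo_observations(tr6, 10, seed = s)$value - 100),
    numeric(1))
  expect_gt(mean(sds), 5)
  expect_lt(mean(sds), 20)
})
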