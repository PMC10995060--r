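test_that("rasterisation conserves load and matches dense quadrature", {
  # uniform pressure disc: total sensel load equals p x area
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  r <- 9
  pts <- rbind(c(0, 0), cbind(r * cos(th), r * sin(th)))
  tri <- cbind(1, 2:41, c(3:41, 2))
  field <- list(xy = pts, tri = tri, pressure = rep(2, nrow(pts)))
  m <- rasterise_to_sensels(field, pitch = 1.27)
  load <- sum(m$values) * m$pitch^2
  polyA <- 0.5 * 40 * r^2 * sin(2 * pi / 40)   # polygon area
  expect_lt(abs(load - 2 * polyA) / (2 * polyA), 1e-9)
  # Hertz-like radial profile on a well-shaped fine triangulation vs a
  # dense quadrature oracle, sensel by sensel away from the patch edge
  pfun <- function(x, y) pmax(0, 1 - (x^2 + y^2) / r^2)
  g <- seq(-9.5, 9.5, by = 0.6)
  gx <- as.matrix(expand.grid(g, g))
  ng <- length(g)
  idx <- function(i, j) (j - 1) * ng + i
  tg <- NULL
  for (i in seq_len(ng - 1)) for (j in seq_len(ng - 1)) {
    tg <- rbind(tg, c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  field2 <- list(xy = gx, tri = tg, pressure = pfun(gx[, 1], gx[, 2]))
  m2 <- rasterise_to_sensels(field2, pitch = 1.27, subdiv = 2)
  m2o <- rasterise_to_sensels(field2, pitch = 1.27, subdiv = 12)
  ii <- (seq_len(nrow(m2$values)) - 1) * 1.27 + m2$origin[1]
  jj <- (seq_len(ncol(m2$values)) - 1) * 1.27 + m2$origin[2]
  rr2 <- outer(ii^2, jj^2, "+")
  inner <- which(rr2 < (r - 2 * 1.27)^2)
  expect_lt(max(abs(m2$values[inner] - m2o$values[inner]) /
                  max(m2o$values)), 0.02)
  expect_warning(rasterise_to_sensels(list(xy = NULL, tri = NULL,
                                           pressure = numeric(0))),
                 "empty")
})

test_that("contact area counts active sensels times sensel area", {
  empty <- pressure_map(matrix(0, 4, 4), 1.27)
  expect_equal(contact_area(empty)$area_mm2, 0)
  m <- disc_map(5)
  ca <- contact_area(m)
  expect_equal(ca$area_mm2, ca$count * 1.27^2)
  # fine-raster oracle: brute-force pixel count within a perimeter ring
  fine <- sum(outer(seq(-8, 8, by = 0.05), seq(-8, 8, by = 0.05),
                    function(x, y) x^2 + y^2 <= 25)) * 0.05^2
  ring <- perimeter_error_bound(m)$area_bound_mm2
  expect_lt(abs(ca$area_mm2 - fine), ring)
})

test_that("perimeter bound uses 4-adjacency to inactive sensels", {
  single <- pressure_map(matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3), 1.27)
  pb <- perimeter_error_bound(single)
  expect_equal(pb$perimeter_count, 1L)
  expect_equal(pb$area_bound_mm2, 1.27^2)
  m <- disc_map(6)
  # brute-force adjacency scan oracle
  act <- m$values > 0
  cnt <- 0
  for (i in seq_len(nrow(act))) for (j in seq_len(ncol(act))) {
    if (!act[i, j]) next
    nb <- c(if (i > 1) act[i - 1, j] else FALSE,
            if (i < nrow(act)) act[i + 1, j] else FALSE,
            if (j > 1) act[i, j - 1] else FALSE,
            if (j < ncol(act)) act[i, j + 1] else FALSE)
    if (any(!nb)) cnt <- cnt + 1
  }
  expect_equal(perimeter_error_bound(m)$perimeter_count, cnt)
  expect_lt(perimeter_error_bound(m)$area_bound_mm2,
            contact_area(m)$area_mm2)
  expect_error(perimeter_error_bound(pressure_map(matrix(0, 2, 2), 1)),
               "no active")
})

test_that("defect footprints are measured in sensels against a reference", {
  # a 6.35 mm hole centred on a sensel across a 1.27 mm lattice reads as
  # 5 sensels in diameter
  n <- 25; cx <- 13
  ref <- pressure_map(outer(1:n, 1:n, function(i, j)
    ((i - cx)^2 + (j - cx)^2 <= 9^2) * 2), 1.27)
  dm <- ref
  hole <- outer(1:n, 1:n, function(i, j)
    (i - cx)^2 + (j - cx)^2 <= (6.35 / 2 / 1.27)^2)
  dm$values[hole] <- 0
  dd <- defect_diameter_sensels(dm, ref)
  expect_equal(dd$diameter_sensels, 5L)
  expect_equal(dd$diameter_mm, 6.35)
  # identical maps: no defect
  none <- defect_diameter_sensels(ref, ref)
  expect_false(none$found)
  expect_equal(none$diameter_sensels, 0L)
  # arbitrary ellipse: extents match a brute bounding-box scan
  el <- ref
  emask <- outer(1:n, 1:n, function(i, j)
    ((i - cx) / 3.2)^2 + ((j - cx) / 1.9)^2 <= 1)
  el$values[emask] <- 0
  de <- defect_diameter_sensels(el, ref)
  idx <- which(emask & ref$values > 0, arr.ind = TRUE)
  expect_equal(de$extent_x, diff(range(idx[, 1])) + 1L)
  expect_equal(de$extent_y, diff(range(idx[, 2])) + 1L)
})

test_that("map comparison reports Dice, centroid offset and area ratio", {
  m <- disc_map(5)
  id <- compare_maps(m, m)
  expect_equal(id$dice, 1.0)
  expect_equal(id$centroid_offset_mm, 0)
  shifted <- m
  shifted$values <- rbind(0, m$values[-nrow(m$values), ])
  cm <- compare_maps(m, shifted)
  expect_equal(cm$centroid_offset_mm, 1.27, tolerance = 0.15)
  # random masks vs brute-force Dice
  set.seed(8)
  a <- pressure_map(matrix(rbinom(100, 1, 0.4), 10, 10), 1)
  b <- pressure_map(matrix(rbinom(100, 1, 0.4), 10, 10), 1)
  aa <- a$values > 0; bb <- b$values > 0
  expect_equal(compare_maps(a, b)$dice,
               2 * sum(aa & bb) / (sum(aa) + sum(bb)))
  expect_error(compare_maps(pressure_map(matrix(0, 2, 2), 1),
                            pressure_map(matrix(0, 2, 2), 1)),
               "empty")
})

test_that("pressure maps round-trip through CSV + YAML", {
  m <- disc_map(4)
  path <- file.path(tempdir(), "map.csv")
  write_pressure_map(m, path)
  m2 <- read_pressure_map(path)
  expect_equal(m2$values, m$values)
  expect_equal(m2$pitch, m$pitch)
})
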