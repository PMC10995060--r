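#' Sensel-grid pressure map
#'
#' Regular 2D lattice of contact pressures (MPa) at fixed sensel pitch,
#' emulating a thin-film pressure sensor laid on the tibial plateau.
#' `values[i, j]` is the pressure of the sensel centred at
#' `origin + (c(i, j) - 1) * pitch`.
#'
#' @param values numeric matrix (pressures, MPa, >= 0).
#' @param pitch sensel pitch, mm (default 1.27).
#' @param origin length-2 centre of sensel (1,1), mm.
#' @param compartment tag: "medial", "lateral" or "full".
#' @return object of class `pressure_map`.
#' @export
pressure_map <- function(values, pitch = 1.27, origin = c(0, 0),
                         compartment = "full") {
  if (pitch <= 0) stop("`pitch` must be positive")
  if (any(values < 0)) stop("pressures must be >= 0")
  structure(list(values = values, pitch = pitch, origin = as.numeric(origin),
                 compartment = compartment),
            class = "pressure_map")
}

#' @export
print.pressure_map <- function(x, ...) {
  cat(sprintf("<pressure_map> %d x %d sensels, pitch %.3g mm, peak %.3g MPa\n",
              nrow(x$values), ncol(x$values), x$pitch, max(x$values)))
  invisible(x)
}

#' Rasterise a contact pressure field onto a sensel grid
#'
#' The field is a triangulated surface patch (projected to the plane of
#' the sensor) with per-vertex pressures. Each triangle is supersampled
#' and its load deposited into the sensel cells it overlaps; a sensel's
#' value is its deposited load divided by the sensel area, so total load
#' is conserved exactly.
#'
#' @param field list with `xy` (n x 2 vertex positions, mm), `tri`
#'   (m x 3 vertex indices) and `pressure` (per-vertex, MPa).
#' @param pitch sensel pitch, mm.
#' @param origin length-2 centre of sensel (1,1); `NULL` = snapped to the
#'   field's bounding box.
#' @param dims c(nx, ny) sensel counts; `NULL` = cover the field.
#' @param subdiv supersampling level per triangle edge.
#' @return a [pressure_map()].
#' @export
rasterise_to_sensels <- function(field, pitch = 1.27, origin = NULL,
                                 dims = NULL, subdiv = 4L) {
  if (!length(field$tri) || all(field$pressure == 0)) {
    warning("empty contact field; returning an all-zero map")
    if (is.null(origin)) origin <- c(0, 0)
    if (is.null(dims)) dims <- c(1L, 1L)
    return(pressure_map(matrix(0, dims[1], dims[2]), pitch, origin))
  }
  xy <- field$xy
  tri <- field$tri
  if (is.null(origin)) origin <- floor(apply(xy, 2, min) / pitch) * pitch
  if (is.null(dims)) {
    dims <- c(ceiling((max(xy[, 1]) - origin[1]) / pitch) + 1L,
              ceiling((max(xy[, 2]) - origin[2]) / pitch) + 1L)
  }
  bary_points <- function(sd) {
    bc <- NULL
    for (i in 0:(sd - 1)) for (j in 0:(sd - 1 - i)) {
      # two sub-triangles per (i,j) lattice cell, sampled at centroids
      bc <- rbind(bc, c(i + 1 / 3, j + 1 / 3))
      if (i + j < sd - 1) bc <- rbind(bc, c(i + 2 / 3, j + 2 / 3))
    }
    bc <- bc / sd
    cbind(1 - bc[, 1] - bc[, 2], bc[, 1], bc[, 2])
  }
  a <- xy[tri[, 1], , drop = FALSE]
  b <- xy[tri[, 2], , drop = FALSE]
  cc <- xy[tri[, 3], , drop = FALSE]
  area <- abs((b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
                (cc[, 1] - a[, 1]) * (b[, 2] - a[, 2])) / 2
  p1 <- field$pressure[tri[, 1]]
  p2 <- field$pressure[tri[, 2]]
  p3 <- field$pressure[tri[, 3]]
  # adaptive supersampling: keep the sample spacing below half a sensel
  # even for large triangles
  emax <- pmax(sqrt(rowSums((b - a)^2)), sqrt(rowSums((cc - a)^2)),
               sqrt(rowSums((cc - b)^2)))
  lev <- pmin(32L, pmax(as.integer(subdiv),
                        as.integer(ceiling(emax / (pitch / 2)))))
  load <- matrix(0, dims[1], dims[2])
  for (sd in sort(unique(lev))) {
    sel <- which(lev == sd)
    w3 <- bary_points(sd)
    ns <- nrow(w3)
    dA <- area[sel] / ns
    for (s in seq_len(ns)) {
      px <- w3[s, 1] * a[sel, 1] + w3[s, 2] * b[sel, 1] + w3[s, 3] * cc[sel, 1]
      py <- w3[s, 1] * a[sel, 2] + w3[s, 2] * b[sel, 2] + w3[s, 3] * cc[sel, 2]
      pp <- w3[s, 1] * p1[sel] + w3[s, 2] * p2[sel] + w3[s, 3] * p3[sel]
      # cloud-in-cell deposition: bilinear weights over the 4 nearest
      # sensels (conservative, and exact for linear pressure fields)
      fi <- (px - origin[1]) / pitch
      fj <- (py - origin[2]) / pitch
      i0 <- floor(fi); j0 <- floor(fj)
      wx <- fi - i0; wy <- fj - j0
      for (corner in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
        ii <- as.integer(i0) + corner[1] + 1L
        jj <- as.integer(j0) + corner[2] + 1L
        w <- (if (corner[1] == 1) wx else 1 - wx) *
             (if (corner[2] == 1) wy else 1 - wy)
        ok <- ii >= 1 & ii <= dims[1] & jj >= 1 & jj <= dims[2] & w > 0
        if (any(ok)) {
          lin <- (jj[ok] - 1L) * dims[1] + ii[ok]
          agg <- rowsum((pp * dA * w)[ok], lin)
          load[as.integer(rownames(agg))] <-
            load[as.integer(rownames(agg))] + agg
        }
      }
    }
  }
  pressure_map(load / pitch^2, pitch, origin)
}

#' Contact area by sensel counting
#'
#' Area = number of active sensels times the sensel area, the convention
#' of thin-film sensor analyses (partial contact across a sensel counts
#' the full sensel).
#'
#' @param map a [pressure_map()].
#' @param threshold activation threshold, MPa (default a tiny epsilon).
#' @return list with `area_mm2` and `count`.
#' @export
contact_area <- function(map, threshold = 1e-9) {
  if (threshold < 0) stop("`threshold` must be >= 0")
  cnt <- sum(map$values > threshold)
  list(area_mm2 = cnt * map$pitch^2, count = cnt)
}

#' Perimeter-sensel error bound on contact area
#'
#' Sensels on the patch edge may register full area under partial
#' contact; the bound is the count of active sensels 4-adjacent to an
#' inactive sensel, times the sensel area.
#'
#' @param map a [pressure_map()].
#' @param threshold activation threshold, MPa.
#' @return list with `perimeter_count`, `area_bound_mm2`, `fraction` (of
#'   the reported contact area).
#' @export
perimeter_error_bound <- function(map, threshold = 1e-9) {
  act <- map$values > threshold
  if (!any(act)) stop("no active sensels")
  padded <- matrix(FALSE, nrow(act) + 2L, ncol(act) + 2L)
  padded[2:(nrow(act) + 1), 2:(ncol(act) + 1)] <- act
  core <- padded[2:(nrow(act) + 1), 2:(ncol(act) + 1)]
  nb_inactive <-
    !padded[1:nrow(act), 2:(ncol(act) + 1)] |
    !padded[3:(nrow(act) + 2), 2:(ncol(act) + 1)] |
    !padded[2:(nrow(act) + 1), 1:ncol(act)] |
    !padded[2:(nrow(act) + 1), 3:(ncol(act) + 2)]
  per <- core & nb_inactive
  cnt <- sum(per)
  ca <- contact_area(map, threshold)
  list(perimeter_count = cnt,
       area_bound_mm2 = cnt * map$pitch^2,
       fraction = cnt * map$pitch^2 / ca$area_mm2)
}

#' Defect diameter in sensels
#'
#' Finds the connected region inside the reference contact patch where
#' the pressure has dropped to zero or below a fraction of the intact
#' reference, and reports its maximum axis-aligned extent in sensels and
#' mm. This mirrors reading a drilled-hole footprint off an experimental
#' pressure map.
#'
#' @param map defect-case [pressure_map()].
#' @param reference intact-case map on the same lattice.
#' @param fraction "reduced pressure" cutoff as a fraction of the
#'   reference (default 0.5).
#' @param threshold activation threshold for the reference patch, MPa.
#' @return list with `diameter_sensels`, `diameter_mm`, `extent_x`,
#'   `extent_y` (sensels), `found` flag.
#' @export
defect_diameter_sensels <- function(map, reference, fraction = 0.5,
                                    threshold = 1e-9) {
  if (!all(dim(map$values) == dim(reference$values)) ||
      map$pitch != reference$pitch)
    stop("maps must share one lattice")
  inref <- reference$values > threshold
  dropped <- inref & (map$values <= fraction * reference$values)
  if (!any(dropped))
    return(list(diameter_sensels = 0L, diameter_mm = 0, extent_x = 0L,
                extent_y = 0L, found = FALSE))
  # largest 4-connected dropped component
  lab <- matrix(0L, nrow(dropped), ncol(dropped))
  cur <- 0L
  for (start in which(dropped)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      s <- queue[1]; queue <- queue[-1]
      i <- (s - 1L) %% nrow(dropped) + 1L
      j <- (s - 1L) %/% nrow(dropped) + 1L
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nrow(dropped) && jj >= 1 && jj <= ncol(dropped)) {
          s2 <- (jj - 1L) * nrow(dropped) + ii
          if (dropped[s2] && lab[s2] == 0L) {
            lab[s2] <- cur
            queue <- c(queue, s2)
          }
        }
      }
    }
  }
  sizes <- tabulate(lab[lab > 0L])
  big <- which.max(sizes)
  idx <- which(lab == big, arr.ind = TRUE)
  ex <- diff(range(idx[, 1])) + 1L
  ey <- diff(range(idx[, 2])) + 1L
  dia <- max(ex, ey)
  list(diameter_sensels = as.integer(dia),
       diameter_mm = dia * map$pitch,
       extent_x = as.integer(ex), extent_y = as.integer(ey), found = TRUE)
}

#' Compare two pressure maps
#'
#' @param map_a,map_b [pressure_map()]s on the same lattice.
#' @param threshold activation threshold, MPa.
#' @return list with `dice` (active-mask overlap), `centroid_offset_mm`,
#'   `area_ratio` (b over a).
#' @export
compare_maps <- function(map_a, map_b, threshold = 1e-9) {
  if (!all(dim(map_a$values) == dim(map_b$values)))
    stop("maps must share one lattice")
  a <- map_a$values > threshold
  b <- map_b$values > threshold
  if (!any(a) && !any(b)) stop("both maps are empty")
  dice <- 2 * sum(a & b) / (sum(a) + sum(b))
  cen <- function(m, act) {
    idx <- which(act, arr.ind = TRUE)
    w <- m$values[act]
    c(sum(idx[, 1] * w), sum(idx[, 2] * w)) / sum(w) * m$pitch
  }
  offset <- if (any(a) && any(b)) {
    sqrt(sum((cen(map_a, a) - cen(map_b, b))^2))
  } else NA_real_
  list(dice = dice, centroid_offset_mm = offset,
       area_ratio = sum(b) / max(sum(a), 1))
}

#' Write a pressure map as CSV with a YAML header sidecar
#' @param map a [pressure_map()].
#' @param path output `.csv` path (a `.yaml` sidecar is written next to
#'   it).
#' @return `path`, invisibly.
#' @export
write_pressure_map <- function(map, path) {
  utils::write.table(map$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  yaml::write_yaml(list(pitch = map$pitch, origin = as.numeric(map$origin),
                        compartment = map$compartment,
                        dims = dim(map$values)),
                   sub("\\.csv$", ".yaml", path))
  invisible(path)
}

#' Read a pressure map written by [write_pressure_map()]
#' @param path `.csv` path.
#' @return a [pressure_map()].
#' @export
read_pressure_map <- function(path) {
  v <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(v) <- NULL
  meta <- yaml::read_yaml(sub("\\.csv$", ".yaml", path))
  pressure_map(v, pitch = meta$pitch, origin = meta$origin,
               compartment = meta$compartment)
}
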