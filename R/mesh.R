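#' Mesh settings
#'
#' @param target_edge_length target element edge length, mm (default 1.0,
#'   matching the element size at which the density mapping is calibrated;
#'   the mapping is element-size dependent, so keep it consistent).
#' @param smoothing_iterations Laplacian boundary smoothing passes
#'   (default 0; smoothing never inverts elements — offending passes are
#'   rolled back with a warning).
#' @return An object of class `mesh_settings`.
#' @export
mesh_settings <- function(target_edge_length = 1.0, smoothing_iterations = 0L) {
  if (target_edge_length <= 0) stop("`target_edge_length` must be positive")
  structure(list(target_edge_length = target_edge_length,
                 smoothing_iterations = as.integer(smoothing_iterations)),
            class = "mesh_settings")
}

# the six Kuhn tetrahedra of a unit cube; vertex codes are bitmasks
# (1 = +x, 2 = +y, 4 = +z); every tet shares the 0-7 diagonal, so the
# triangulation is conforming across neighbouring cells
kuhn_tets <- function() {
  paths <- list(c(1L, 3L), c(1L, 5L), c(2L, 3L), c(2L, 6L), c(4L, 5L), c(4L, 6L))
  t(vapply(paths, function(p) c(0L, p[1], p[2], 7L), integer(4)))
}

corner_offset <- function(code) {
  c(bitwAnd(code, 1L) != 0L, bitwAnd(code, 2L) != 0L, bitwAnd(code, 4L) != 0L) * 1
}

# majority label per coarse block (ties broken toward the lower code,
# i.e. void wins ties against tissue)
majority_downsample <- function(values, factor) {
  d <- dim(values)
  codes <- sort(unique(as.vector(values)))
  block_sum_axis <- function(a, axis) {
    da <- dim(a)
    grp <- (seq_len(da[axis]) - 1L) %/% factor
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = da[axis])
    s <- rowsum(m, grp, reorder = TRUE)
    out <- array(s, dim = c(nrow(s), da[perm[2]], da[perm[3]]))
    aperm(out, order(perm))
  }
  counts <- lapply(codes, function(cd) {
    a <- (values == cd) * 1
    for (ax in 1:3) a <- block_sum_axis(a, ax)
    a
  })
  best <- counts[[1]]
  lab <- array(codes[1], dim = dim(best))
  if (length(codes) > 1) {
    for (i in 2:length(codes)) {
      upd <- counts[[i]] > best
      lab[upd] <- codes[i]
      best[upd] <- counts[[i]][upd]
    }
  }
  lab
}

tet_signed_volumes <- function(nodes, elements) {
  a <- nodes[elements[, 1], , drop = FALSE]
  b <- nodes[elements[, 2], , drop = FALSE] - a
  c_ <- nodes[elements[, 3], , drop = FALSE] - a
  d <- nodes[elements[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

#' Mesh a labelled volume with linear tetrahedra
#'
#' Resamples the label volume by majority vote onto cubes of edge close to
#' the target element size, then splits every non-void cube into six
#' conforming tetrahedra (Kuhn subdivision). Region labels are carried
#' per element; all elements have positive signed volume.
#'
#' @param labels a [label_volume()].
#' @param settings a [mesh_settings()].
#' @return A `tet_mesh`: list with `nodes` (n x 3, mm), `elements`
#'   (m x 4, 1-based), `region` (character per element), `E`, `patches`
#'   (named list), `cell_edge` (mm).
#' @export
mesh_labelled_volume <- function(labels, settings = mesh_settings()) {
  vals <- labels$values
  if (all(vals == 0L)) stop("label volume has no non-void voxels")
  f <- max(1L, as.integer(round(settings$target_edge_length / labels$spacing)))
  lab_c <- if (f > 1L) majority_downsample(vals, f) else vals
  h <- labels$spacing * f
  dc <- dim(lab_c)
  if (all(lab_c == 0L))
    stop("resampled label volume is empty at this element size")

  cells <- which(lab_c != 0L, arr.ind = TRUE)     # n_cells x 3
  ncel <- nrow(cells)
  # grid node ids (corners), built lazily over used corners
  nxg <- dc[1] + 1L; nyg <- dc[2] + 1L
  corner_id <- function(ijk) {
    (ijk[, 3] - 1L) * nxg * nyg + (ijk[, 2] - 1L) * nxg + ijk[, 1]
  }
  tets <- kuhn_tets()
  offs <- t(vapply(0:7, corner_offset, numeric(3)))   # 8 x 3
  # all 8 corner grid ids per cell
  cid <- matrix(0L, ncel, 8)
  for (cc in 1:8) {
    cid[, cc] <- corner_id(sweep(cells, 2, as.integer(offs[cc, ]), "+"))
  }
  used <- sort(unique(as.vector(cid)))
  remap <- integer(max(used)); remap[used] <- seq_along(used)
  # node positions: cell (1,1,1) spans [origin - spacing/2, +h] per axis
  base <- labels$origin - labels$spacing / 2
  gi <- (used - 1L) %% nxg
  gj <- ((used - 1L) %/% nxg) %% nyg
  gk <- (used - 1L) %/% (nxg * nyg)
  nodes <- cbind(base[1] + gi * h, base[2] + gj * h, base[3] + gk * h)

  elements <- matrix(0L, ncel * 6L, 4L)
  region_code <- integer(ncel * 6L)
  for (tt in 1:6) {
    rows <- seq.int(tt, by = 6L, length.out = ncel)
    elements[rows, ] <- cbind(remap[cid[, tets[tt, 1] + 1L]],
                              remap[cid[, tets[tt, 2] + 1L]],
                              remap[cid[, tets[tt, 3] + 1L]],
                              remap[cid[, tets[tt, 4] + 1L]])
    region_code[rows] <- lab_c[cells]
  }
  # enforce positive orientation
  sv <- tet_signed_volumes(nodes, elements)
  flip <- sv < 0
  if (any(flip)) elements[flip, 3:4] <- elements[flip, 4:3]

  name_of <- function(code) names(labels$labels)[match(code, labels$labels)]
  mesh <- structure(list(
    nodes = nodes,
    elements = elements,
    region = vapply(region_code, name_of, character(1)),
    E = rep(NA_real_, nrow(elements)),
    patches = list(),
    cell_edge = h,
    body = rep(1L, nrow(nodes))
  ), class = "tet_mesh")

  if (settings$smoothing_iterations > 0L)
    mesh <- smooth_boundary(mesh, settings$smoothing_iterations)
  mesh
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d elements, regions: %s; patches: %s\n",
              nrow(x$nodes), nrow(x$elements),
              paste(unique(x$region), collapse = ", "),
              if (length(x$patches)) paste(names(x$patches), collapse = ", ")
              else "(none)"))
  invisible(x)
}

# face table: each tet contributes 4 faces; returns data on sorted keys
tet_face_table <- function(mesh) {
  ele <- mesh$elements
  m <- nrow(ele)
  # local faces with the opposite (4th) node recorded
  loc <- rbind(c(2, 3, 4, 1), c(1, 4, 3, 2), c(1, 2, 4, 3), c(1, 3, 2, 4))
  faces <- matrix(0L, 4L * m, 3L)
  opp <- integer(4L * m)
  elem_of <- integer(4L * m)
  for (ff in 1:4) {
    rows <- seq.int(ff, by = 4L, length.out = m)
    faces[rows, ] <- ele[, loc[ff, 1:3]]
    opp[rows] <- ele[, loc[ff, 4]]
    elem_of[rows] <- seq_len(m)
  }
  key <- apply(faces, 1, function(r) paste(sort(r), collapse = "_"))
  list(faces = faces, opp = opp, elem = elem_of, key = key)
}

# outward-oriented triangle (normal away from the opposite node)
orient_faces_outward <- function(nodes, faces, opp) {
  a <- nodes[faces[, 1], , drop = FALSE]
  ab <- nodes[faces[, 2], , drop = FALSE] - a
  ac <- nodes[faces[, 3], , drop = FALSE] - a
  n <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
             ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
             ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  to_opp <- nodes[opp, , drop = FALSE] - a
  inward <- rowSums(n * to_opp) > 0
  faces[inward, 2:3] <- faces[inward, 3:2]
  faces
}

face_normals_areas <- function(nodes, tri) {
  a <- nodes[tri[, 1], , drop = FALSE]
  ab <- nodes[tri[, 2], , drop = FALSE] - a
  ac <- nodes[tri[, 3], , drop = FALSE] - a
  n <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
             ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
             ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  len <- sqrt(rowSums(n^2))
  list(normal = n / len, area = len / 2,
       centroid = (a + nodes[tri[, 2], , drop = FALSE] +
                     nodes[tri[, 3], , drop = FALSE]) / 3)
}

#' Extract a named boundary surface patch
#'
#' Returns the outward-oriented boundary triangles of a region, optionally
#' restricted to the interface with another region and/or filtered by a
#' geometric predicate on face centroids and outward normals.
#'
#' @param mesh a `tet_mesh`.
#' @param region region whose boundary is wanted.
#' @param other `NULL` for any boundary (void or different region),
#'   `"void"` for the free surface only, or another region name for that
#'   interface only.
#' @param predicate optional `function(centroid, normal)` over n x 3
#'   matrices returning a logical vector.
#' @param name patch name; the patch is stored in `mesh$patches[[name]]`
#'   and also returned.
#' @return The mesh with the patch added. The patch is a list with `tri`
#'   (outward-oriented node triples), `elem` (owner elements), `name`.
#' @export
extract_patch <- function(mesh, region, other = "void", predicate = NULL,
                          name = region) {
  ft <- tet_face_table(mesh)
  first <- !duplicated(ft$key)
  idx1 <- which(first)
  match2 <- match(ft$key, ft$key[idx1])
  partner <- rep(NA_integer_, length(ft$key))
  dup_rows <- which(!first)
  partner[idx1[match2[dup_rows]]] <- dup_rows
  partner[dup_rows] <- idx1[match2[dup_rows]]

  own_reg <- mesh$region[ft$elem]
  nb_reg <- ifelse(is.na(partner), "void", mesh$region[ft$elem[partner]])
  # each interface face is selected once, from its `region`-side row
  sel <- own_reg == region & nb_reg != region
  if (identical(other, "void")) sel <- sel & nb_reg == "void"
  else if (!is.null(other)) sel <- sel & nb_reg %in% other
  rows <- which(sel)
  if (!length(rows))
    stop("extract_patch: selector matched no boundary faces (region=",
         region, ", other=", paste(other, collapse = "/"), ")")
  tri <- orient_faces_outward(mesh$nodes, ft$faces[rows, , drop = FALSE],
                              ft$opp[rows])
  if (!is.null(predicate)) {
    fg <- face_normals_areas(mesh$nodes, tri)
    keep <- predicate(fg$centroid, fg$normal)
    if (!any(keep))
      stop("extract_patch: predicate removed every face for patch ", name)
    tri <- tri[keep, , drop = FALSE]
    rows <- rows[keep]
  }
  mesh$patches[[name]] <- list(tri = tri, elem = ft$elem[rows], name = name)
  mesh
}

#' Total patch area (mm^2)
#' @param mesh a `tet_mesh`.
#' @param name patch name.
#' @return scalar area.
#' @export
patch_area <- function(mesh, name) {
  p <- mesh$patches[[name]]
  if (is.null(p)) stop("no patch named ", name)
  sum(face_normals_areas(mesh$nodes, p$tri)$area)
}

unique_edges <- function(elements) {
  pairs <- rbind(elements[, c(1, 2)], elements[, c(1, 3)], elements[, c(1, 4)],
                 elements[, c(2, 3)], elements[, c(2, 4)], elements[, c(3, 4)])
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  pairs[!duplicated(pairs), , drop = FALSE]
}

#' Mesh quality summary
#'
#' Edge-length statistics, per-element aspect ratio (longest edge over
#' smallest altitude), and the minimum dihedral angle across the mesh.
#'
#' @param mesh a non-empty `tet_mesh`.
#' @return list with `edge` (min/median/max, mm), `aspect`
#'   (median/max), `min_dihedral_deg`, `n_elements`, `n_nodes`,
#'   `min_volume`.
#' @export
mesh_quality_report <- function(mesh) {
  if (is.null(mesh$elements) || nrow(mesh$elements) == 0L)
    stop("mesh_quality_report: empty mesh")
  ed <- unique_edges(mesh$elements)
  el <- sqrt(rowSums((mesh$nodes[ed[, 1], , drop = FALSE] -
                        mesh$nodes[ed[, 2], , drop = FALSE])^2))
  vols <- tet_signed_volumes(mesh$nodes, mesh$elements)
  # per-element longest edge and smallest altitude (3V / largest face area)
  ele <- mesh$elements
  combs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  emax <- rep(0, nrow(ele))
  for (cb in combs) {
    l <- sqrt(rowSums((mesh$nodes[ele[, cb[1]], , drop = FALSE] -
                         mesh$nodes[ele[, cb[2]], , drop = FALSE])^2))
    emax <- pmax(emax, l)
  }
  fmax <- rep(0, nrow(ele))
  loc <- list(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  fnormals <- vector("list", 4)
  for (ff in 1:4) {
    tri <- cbind(ele[, loc[[ff]][1]], ele[, loc[[ff]][2]], ele[, loc[[ff]][3]])
    g <- face_normals_areas(mesh$nodes, tri)
    fmax <- pmax(fmax, g$area)
    fnormals[[ff]] <- g$normal
  }
  aspect <- emax * fmax / (3 * vols)
  # dihedral angles between the 4 face planes of each element
  min_dih <- rep(180, nrow(ele))
  for (i in 1:3) for (j in (i + 1):4) {
    cosang <- rowSums(fnormals[[i]] * fnormals[[j]])
    ang <- 180 - acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    min_dih <- pmin(min_dih, ang)
  }
  list(edge = c(min = min(el), median = stats::median(el), max = max(el)),
       aspect = c(median = stats::median(aspect), max = max(aspect)),
       min_dihedral_deg = min(min_dih),
       n_elements = nrow(ele), n_nodes = nrow(mesh$nodes),
       min_volume = min(vols))
}

# Laplacian smoothing of free-surface nodes with per-pass inversion rollback
smooth_boundary <- function(mesh, iterations, relax = 0.3) {
  ft <- tet_face_table(mesh)
  bd <- !(ft$key %in% ft$key[duplicated(ft$key)])
  btri <- ft$faces[bd, , drop = FALSE]
  bnodes <- unique(as.vector(btri))
  # boundary-node adjacency over boundary edges
  ed <- rbind(btri[, 1:2], btri[, 2:3], btri[, c(3, 1)])
  for (it in seq_len(iterations)) {
    old <- mesh$nodes
    mean_nb <- rowsum(old[ed[, 2], , drop = FALSE], ed[, 1])
    cnt <- as.vector(rowsum(rep(1, nrow(ed)), ed[, 1]))
    ids <- as.integer(rownames(mean_nb))
    targ <- mean_nb / cnt
    mesh$nodes[ids, ] <- (1 - relax) * old[ids, ] + relax * targ
    if (min(tet_signed_volumes(mesh$nodes, mesh$elements)) <= 0) {
      mesh$nodes <- old
      warning("smoothing pass ", it, " would invert elements; rolled back")
      break
    }
  }
  mesh
}

#' Rigidly transform a mesh
#' @param mesh a `tet_mesh`.
#' @param translate length-3 translation, mm.
#' @param rotation 3 x 3 rotation matrix (applied about `centre`).
#' @param centre rotation centre, mm.
#' @return the transformed mesh.
#' @export
transform_mesh <- function(mesh, translate = c(0, 0, 0), rotation = NULL,
                           centre = c(0, 0, 0)) {
  nd <- mesh$nodes
  if (!is.null(rotation)) {
    nd <- sweep(nd, 2, centre)
    nd <- nd %*% t(rotation)
    nd <- sweep(nd, 2, centre, "+")
  }
  mesh$nodes <- sweep(nd, 2, translate, "+")
  mesh
}

#' Merge two meshes into one model
#'
#' Node and element ids of `b` are offset; patches keep their names
#' (prefix with `prefix_b` to disambiguate duplicates).
#'
#' @param a,b `tet_mesh` objects.
#' @param prefix_b optional string prepended to `b`'s patch names.
#' @return combined `tet_mesh`.
#' @export
combine_meshes <- function(a, b, prefix_b = NULL) {
  off <- nrow(a$nodes)
  out <- a
  out$nodes <- rbind(a$nodes, b$nodes)
  out$elements <- rbind(a$elements, b$elements + off)
  out$region <- c(a$region, b$region)
  out$E <- c(a$E, b$E)
  ab <- if (is.null(a$body)) rep(1L, off) else a$body
  bb <- if (is.null(b$body)) rep(1L, nrow(b$nodes)) else b$body
  out$body <- c(ab, bb + max(ab))
  if (!is.null(a$bvtv) || !is.null(b$bvtv)) {
    av <- if (is.null(a$bvtv)) rep(NA_real_, nrow(a$elements)) else a$bvtv
    bv <- if (is.null(b$bvtv)) rep(NA_real_, nrow(b$elements)) else b$bvtv
    out$bvtv <- c(av, bv)
  }
  bp <- lapply(b$patches, function(p) {
    p$tri <- p$tri + off
    p$elem <- p$elem + nrow(a$elements)
    p
  })
  if (!is.null(prefix_b) && length(bp))
    names(bp) <- paste0(prefix_b, names(bp))
  out$patches <- c(a$patches, bp)
  out
}

#' Export a mesh as legacy ASCII VTK
#' @param mesh a `tet_mesh`.
#' @param path output `.vtk` path.
#' @param point_data optional named list of per-node scalar vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0", "tet_mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$nodes, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  utils::write.table(cbind(4L, mesh$elements - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(factor(mesh$region))), con)
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], digits = 9, trim = TRUE), con)
    }
  }
  invisible(path)
}

#' Export a mesh as an Abaqus INP deck
#'
#' Nodes, C3D4 elements, one element set per region, and one surface-style
#' node set per patch, for cross-checking in external solvers.
#'
#' @param mesh a `tet_mesh`.
#' @param path output `.inp` path.
#' @return `path`, invisibly.
#' @export
write_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.9g, %.9g, %.9g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  for (reg in unique(mesh$region)) {
    rows <- which(mesh$region == reg)
    writeLines(sprintf("*ELEMENT, TYPE=C3D4, ELSET=%s", toupper(reg)), con)
    e <- mesh$elements[rows, , drop = FALSE]
    writeLines(sprintf("%d, %d, %d, %d, %d", rows, e[, 1], e[, 2], e[, 3],
                       e[, 4]), con)
  }
  for (nm in names(mesh$patches)) {
    writeLines(sprintf("*NSET, NSET=%s", toupper(nm)), con)
    ids <- sort(unique(as.vector(mesh$patches[[nm]]$tri)))
    writeLines(paste(ids, collapse = ", "), con)
  }
  invisible(path)
}
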