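#' Linear BV/TV to Young's modulus material map
#'
#' Per-element bone modulus is `E = max(modulus_floor, c * BV/TV)` (MPa),
#' the linear greyscale-to-modulus conversion used for specimen-specific
#' bone property mapping. The floor keeps near-empty elements from making
#' the stiffness matrix singular while staying orders of magnitude below
#' bone.
#'
#' @param conversion_factor `c`, MPa per unit BV/TV (> 0).
#' @param modulus_floor minimum element modulus, MPa (> 0).
#' @param poisson_ratio bone Poisson's ratio (0, 0.5).
#' @return An object of class `material_map`.
#' @export
material_map <- function(conversion_factor = 100.5, modulus_floor = 0.1,
                         poisson_ratio = 0.3) {
  if (conversion_factor <= 0) stop("`conversion_factor` must be positive")
  if (modulus_floor <= 0) stop("`modulus_floor` must be positive")
  if (!(poisson_ratio > 0 && poisson_ratio < 0.5))
    stop("`poisson_ratio` must lie in (0, 0.5)")
  structure(list(conversion_factor = conversion_factor,
                 modulus_floor = modulus_floor,
                 poisson_ratio = poisson_ratio),
            class = "material_map")
}

#' Fixed-threshold binarisation
#'
#' @param volume greyscale [voxel_volume()].
#' @param threshold scalar; output is 1 where `value >= threshold`, else 0.
#'   Idempotent on binary input with threshold 0.5.
#' @return Binary [voxel_volume()] on the same lattice.
#' @export
binarise <- function(volume, threshold) {
  v <- volume$values
  nbad <- sum(!is.finite(v))
  if (nbad > 0)
    stop(sprintf("volume contains %d non-finite voxels", nbad))
  voxel_volume((v >= threshold) * 1, spacing = volume$spacing,
               origin = volume$origin, binary = TRUE)
}

#' Downsample a binary volume to a BV/TV density field
#'
#' Each coarse voxel is the arithmetic mean of its `factor`^3 fine voxels
#' (edge blocks average over the voxels available), so total bone volume is
#' conserved exactly whenever `factor` divides the shape. Output spacing is
#' `input spacing * factor` (e.g. 82 um binned 2x to 0.164 mm).
#'
#' @param binary binary [voxel_volume()].
#' @param factor integer downsampling factor >= 1.
#' @return A `density_field`: list with `values` (BV/TV in \[0, 1\]),
#'   `spacing`, `origin`.
#' @export
downsample_to_bvtv <- function(binary, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1")
  v <- binary$values
  if (!is_binary_values(v)) stop("input volume must be binary")
  d <- dim(v)
  nd <- as.integer(ceiling(d / factor))
  # block sums via cumulative group means along each axis in turn
  block_mean_axis <- function(a, axis) {
    da <- dim(a)
    grp <- (seq_len(da[axis]) - 1L) %/% factor
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = da[axis])
    s <- rowsum(m, grp, reorder = TRUE)
    cnt <- as.vector(table(grp))
    s <- s / cnt
    out <- array(s, dim = c(nrow(s), da[perm[2]], da[perm[3]]))
    aperm(out, order(perm))
  }
  out <- v
  for (ax in 1:3) out <- block_mean_axis(out, ax)
  # origin shifts to the centre of the first coarse block
  new_origin <- binary$origin + (factor - 1) / 2 * binary$spacing
  structure(list(values = out, spacing = binary$spacing * factor,
                 origin = new_origin),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_field> %d x %d x %d, spacing %.4g mm, mean BV/TV %.3f\n",
              d[1], d[2], d[3], x$spacing, mean(x$values)))
  invisible(x)
}

# nearest-voxel sample of a density field at world points (n x 3), with
# out-of-bounds points flagged NA
sample_density_field <- function(field, pts) {
  d <- dim(field$values)
  idx <- sweep(pts, 2, field$origin) / field$spacing
  ij <- round(idx) + 1
  ok <- ij[, 1] >= 1 & ij[, 1] <= d[1] &
        ij[, 2] >= 1 & ij[, 2] <= d[2] &
        ij[, 3] >= 1 & ij[, 3] <= d[3]
  out <- rep(NA_real_, nrow(pts))
  if (any(ok)) {
    lin <- (ij[ok, 3] - 1) * d[1] * d[2] + (ij[ok, 2] - 1) * d[1] + ij[ok, 1]
    out[ok] <- field$values[lin]
  }
  out
}

#' Assign per-element Young's moduli from a density field
#'
#' Bone elements sample the BV/TV field with a 5-point rule (the four
#' vertices and the centroid, nearest-voxel lookup, averaged) and receive
#' `E = max(modulus_floor, c * BV/TV)`. Elements falling outside the field's
#' bounding box take the floor modulus and are counted in the returned
#' mesh's `material_info`. Non-bone regions are untouched.
#'
#' @param mesh a `tet_mesh` (see [mesh_labelled_volume()]).
#' @param field a `density_field`.
#' @param map a [material_map()].
#' @param bone_regions region labels treated as density-mapped bone.
#' @return The mesh with `E` filled in for bone elements (MPa) and a
#'   `material_info` record (elements outside field, map used).
#' @export
assign_element_moduli <- function(mesh, field, map,
                                  bone_regions = c("bone", "graft_bone")) {
  sel <- mesh$region %in% bone_regions
  if (!any(sel)) stop("mesh has no bone-labelled elements")
  ele <- mesh$elements[sel, , drop = FALSE]
  n1 <- mesh$nodes[ele[, 1], , drop = FALSE]
  n2 <- mesh$nodes[ele[, 2], , drop = FALSE]
  n3 <- mesh$nodes[ele[, 3], , drop = FALSE]
  n4 <- mesh$nodes[ele[, 4], , drop = FALSE]
  cen <- (n1 + n2 + n3 + n4) / 4
  samp <- cbind(sample_density_field(field, n1),
                sample_density_field(field, n2),
                sample_density_field(field, n3),
                sample_density_field(field, n4),
                sample_density_field(field, cen))
  bvtv <- rowMeans(samp, na.rm = TRUE)
  outside <- !is.finite(bvtv)          # all five samples out of bounds
  bvtv[outside] <- 0
  E <- pmax(map$modulus_floor, map$conversion_factor * bvtv)
  if (is.null(mesh$E)) mesh$E <- rep(NA_real_, nrow(mesh$elements))
  mesh$E[sel] <- E
  if (is.null(mesh$bvtv)) mesh$bvtv <- rep(NA_real_, nrow(mesh$elements))
  mesh$bvtv[sel] <- bvtv
  mesh$material_info <- list(map = unclass(map),
                             n_bone_elements = sum(sel),
                             n_outside_field = sum(outside))
  mesh
}
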