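#' Trabecular phantom parameters
#'
#' Parameters of the seeded trabecular-bone phantom generator. Texture is a
#' thresholded, Gaussian-smoothed random field: `target_bvtv` sets the bone
#' volume fraction, `correlation_length` (mm) the typical strut/marrow-space
#' scale, and `depth_gradient` a linear BV/TV trend per mm of depth (z axis),
#' centred on the mid-depth so the global BV/TV stays at `target_bvtv`. This
#' emulates the depth-wise density decline seen beneath the subchondral
#' plate in human condyles.
#'
#' @param target_bvtv bone volume fraction in (0, 1).
#' @param correlation_length correlation length in mm (> 0).
#' @param depth_gradient BV/TV change per mm of depth (may be negative; 0 =
#'   homogeneous).
#' @param seed integer RNG seed; the generator is a pure function of
#'   (parameters, seed).
#' @return An object of class `trabecular_params`.
#' @export
trabecular_params <- function(target_bvtv, correlation_length = 0.6,
                              depth_gradient = 0, seed = 1L) {
  if (!(target_bvtv > 0 && target_bvtv < 1))
    stop("`target_bvtv` must lie in (0, 1)")
  if (correlation_length <= 0) stop("`correlation_length` must be positive")
  structure(list(target_bvtv = target_bvtv,
                 correlation_length = correlation_length,
                 depth_gradient = depth_gradient,
                 seed = as.integer(seed)),
            class = "trabecular_params")
}

#' Graft / hole geometry
#'
#' Records the interference-fit geometry: a graft deliberately oversized
#' relative to its drilled hole. Hole depth and graft length are both
#' measured from the articular (cartilage) surface, so a seated graft's
#' flush offset is `graft_length - hole_depth` (negative = below flush).
#'
#' @param graft_diameter graft diameter, mm.
#' @param hole_diameter drilled hole diameter, mm (must not exceed
#'   `graft_diameter`).
#' @param graft_length total graft length (bone plus cartilage cap), mm.
#' @param hole_depth drill depth below the articular surface, mm.
#' @param cartilage_thickness cartilage cap / host layer thickness, mm.
#' @return An object of class `graft_geometry`, with
#'   `diametral_interference = graft_diameter - hole_diameter` recorded.
#' @export
graft_geometry <- function(graft_diameter = 6.5, hole_diameter = 6.35,
                           graft_length = 10, hole_depth = 10,
                           cartilage_thickness = 1.5) {
  dims <- c(graft_diameter, hole_diameter, graft_length, hole_depth,
            cartilage_thickness)
  if (any(dims <= 0)) stop("all geometry dimensions must be positive")
  if (graft_diameter < hole_diameter)
    stop("interference fit requires graft_diameter >= hole_diameter")
  structure(list(graft_diameter = graft_diameter,
                 hole_diameter = hole_diameter,
                 graft_length = graft_length,
                 hole_depth = hole_depth,
                 cartilage_thickness = cartilage_thickness,
                 diametral_interference = graft_diameter - hole_diameter),
            class = "graft_geometry")
}

# run expr with a local, restored RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# periodic Gaussian smoothing of a 3D array via FFT, sigma in voxels
smooth_gaussian_fft <- function(arr, sigma) {
  d <- dim(arr)
  g1 <- function(n) {
    f <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) / n
    exp(-2 * pi^2 * sigma^2 * f^2)
  }
  gx <- g1(d[1]); gy <- g1(d[2]); gz <- g1(d[3])
  ker <- outer(outer(gx, gy), gz)
  Re(fft(fft(arr) * ker, inverse = TRUE)) / prod(d)
}

# threshold a continuous field to hit exact per-slice foreground counts
threshold_to_targets <- function(field, slice_targets) {
  d <- dim(field)
  out <- array(0, dim = d)
  for (k in seq_len(d[3])) {
    sl <- field[, , k]
    n <- length(sl)
    m <- round(slice_targets[k] * n)
    if (m > 0) {
      cut <- sort(as.vector(sl), decreasing = TRUE)[m]
      bin <- (sl >= cut) * 1
      # continuous field: ties essentially impossible, but guard anyway
      extra <- sum(bin) - m
      if (extra > 0) {
        idx <- which(sl == cut)
        bin[idx[seq_len(extra)]] <- 0
      }
      out[, , k] <- bin
    }
  }
  out
}

per_slice_targets <- function(params, nz, spacing) {
  depth <- (seq_len(nz) - 1) * spacing
  t <- params$target_bvtv + params$depth_gradient * (depth - mean(depth))
  if (any(t <= 0) || any(t >= 1))
    stop("invalid parameters: target + depth gradient pushes a slice ",
         "BV/TV outside (0, 1)")
  t
}

#' Generate a binary trabecular-bone phantom
#'
#' Seeded Gaussian random field, smoothed to the requested correlation
#' length and thresholded by per-slice quantiles so the achieved BV/TV
#' matches `target_bvtv` (globally, and per slice after the depth
#' gradient) to within rounding of the voxel count.
#'
#' @param shape integer length-3 voxel counts (each >= 8).
#' @param spacing voxel edge, mm. The 0.082 mm default mirrors a typical
#'   HR-pQCT acquisition.
#' @param params a [trabecular_params()].
#' @return A binary [voxel_volume()].
#' @export
generate_trabecular_volume <- function(shape, spacing = 0.082, params) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("`shape` must give 3 voxel counts, each >= 8")
  targets <- per_slice_targets(params, shape[3], spacing)
  sigma <- params$correlation_length / spacing
  field <- with_seed(params$seed, {
    smooth_gaussian_fft(array(stats::rnorm(prod(shape)), dim = shape), sigma)
  })
  bin <- threshold_to_targets(field, targets)
  voxel_volume(bin, spacing = spacing, binary = TRUE)
}

# elliptical-cylinder mask (axis z) inscribed with a margin, per-voxel
ellipse_mask <- function(nx, ny, spacing, semi_x, semi_y,
                         cx = NULL, cy = NULL) {
  xs <- (seq_len(nx) - 1) * spacing
  ys <- (seq_len(ny) - 1) * spacing
  if (is.null(cx)) cx <- mean(xs)
  if (is.null(cy)) cy <- mean(ys)
  outer(((xs - cx) / semi_x)^2, ((ys - cy) / semi_y)^2, "+") <= 1
}

#' Generate a potted condyle compression specimen
#'
#' Builds an elliptical-cylinder bone block with a dense peripheral shell
#' and trabecular interior, potted between two PMMA endcaps, mirroring the
#' potted single-condyle specimens used for stiffness calibration. The bone
#' microstructure is a trabecular phantom whose bone-region BV/TV equals
#' `params$target_bvtv`; a radial bias concentrates bone near the shell
#' without changing the global fraction.
#'
#' @param params a [trabecular_params()].
#' @param endcap_thickness PMMA cap thickness, mm; the cap slice count is
#'   `round(endcap_thickness / spacing)`.
#' @param shape voxel counts (x, y, z) of the full specimen lattice.
#' @param spacing voxel edge, mm.
#' @param shell_bias strength of the dense-shell bias (field units).
#' @return An `oc_specimen`: list with `labels` (a [label_volume()] with
#'   regions bone / pmma), `micro` (binary [voxel_volume()], bone
#'   microstructure), and `params`.
#' @export
generate_condyle_specimen <- function(params, endcap_thickness = 2,
                                      shape = c(40, 40, 64),
                                      spacing = 0.082, shell_bias = 1.5) {
  if (endcap_thickness <= 0) stop("`endcap_thickness` must be positive")
  shape <- as.integer(shape)
  ncap <- max(1L, round(endcap_thickness / spacing))
  nzb <- shape[3] - 2L * ncap
  if (nzb < 8L) stop("specimen too short for the requested endcaps")

  semi_x <- (shape[1] - 1) * spacing * 0.45
  semi_y <- (shape[2] - 1) * spacing * 0.45
  ell <- ellipse_mask(shape[1], shape[2], spacing, semi_x, semi_y)

  labs <- array(0L, dim = shape)
  zb <- (ncap + 1L):(ncap + nzb)
  labs[, , seq_len(ncap)] <- 2L
  labs[, , (ncap + nzb + 1L):shape[3]] <- 2L
  for (k in zb) labs[, , k][ell] <- 1L

  # trabecular microstructure in the bone region: smoothed field plus a
  # radial bias toward the periphery, thresholded over bone voxels only so
  # the bone-region BV/TV hits the target exactly (up to count rounding)
  targets <- per_slice_targets(params, nzb, spacing)
  sigma <- params$correlation_length / spacing
  field <- with_seed(params$seed, {
    smooth_gaussian_fft(array(stats::rnorm(prod(c(shape[1:2], nzb))),
                              dim = c(shape[1:2], nzb)), sigma)
  })
  xs <- (seq_len(shape[1]) - 1) * spacing
  ys <- (seq_len(shape[2]) - 1) * spacing
  r2 <- outer(((xs - mean(xs)) / semi_x)^2, ((ys - mean(ys)) / semi_y)^2, "+")
  bias <- shell_bias * pmax(0, r2 - 0.55)   # ramps up toward the shell
  sdf <- stats::sd(as.vector(field))
  micro <- array(0, dim = shape)
  for (i in seq_along(targets)) {
    sl <- field[, , i] + bias * sdf
    v <- sl[ell]
    m <- round(targets[i] * length(v))
    if (m > 0) {
      cut <- sort(v, decreasing = TRUE)[m]
      msl <- array(0, dim = shape[1:2])
      msl[ell] <- (v >= cut) * 1
      micro[, , zb[i]] <- msl
    }
  }

  structure(list(
    labels = label_volume(labs, spacing = spacing,
                          labels = c(bone = 1L, pmma = 2L),
                          meta = list(endcap_slices = ncap)),
    micro = voxel_volume(micro, spacing = spacing, binary = TRUE),
    params = params
  ), class = "oc_specimen")
}

#' Generate a graft / host pair with an interference fit
#'
#' Builds two labelled volumes: a host block (trabecular bone under a
#' uniform cartilage layer) with a cylindrical hole drilled normal to the
#' articular surface, and a cylindrical graft (trabecular bone with a
#' cartilage cap) with independent microstructure. The diametral
#' interference `graft_diameter - hole_diameter` is recorded in the pair
#' metadata.
#'
#' @param host_params,graft_params [trabecular_params()] for the two bodies.
#' @param geom a [graft_geometry()].
#' @param spacing voxel edge, mm.
#' @param margin lateral bone margin around the hole, mm (>= 2).
#' @param base_depth bone thickness below the hole base, mm.
#' @return List with `host` and `graft` (`oc_specimen`s with regions bone /
#'   cartilage and graft_bone / graft_cartilage), `geom`, and `meta`
#'   containing `diametral_interference`.
#' @export
generate_graft_host_pair <- function(host_params, graft_params, geom,
                                     spacing = 0.164, margin = 2,
                                     base_depth = 3) {
  if (margin < 2) stop("hole must fit inside the host with >= 2 mm margin")
  lat <- geom$hole_diameter + 2 * margin
  depth <- geom$hole_depth + base_depth
  nx <- ny <- as.integer(ceiling(lat / spacing)) + 1L
  nz <- as.integer(ceiling(depth / spacing)) + 1L
  nz_cart <- max(1L, round(geom$cartilage_thickness / spacing))
  if (nz <= nz_cart + 8L) stop("geometry not contained in the host block")

  host_micro_vol <- generate_trabecular_volume(c(nx, ny, nz), spacing,
                                               host_params)
  labs <- array(0L, dim = c(nx, ny, nz))
  # z index 1 is the articular surface; depth increases with z
  labs[, , seq_len(nz_cart)] <- 2L
  labs[, , (nz_cart + 1L):nz] <- 1L
  hole <- ellipse_mask(nx, ny, spacing, geom$hole_diameter / 2,
                       geom$hole_diameter / 2)
  nz_hole <- round(geom$hole_depth / spacing)
  for (k in seq_len(min(nz_hole, nz))) labs[, , k][hole] <- 0L
  micro <- host_micro_vol$values
  micro[labs != 1L] <- 0
  host <- structure(list(
    labels = label_volume(labs, spacing,
                          labels = c(bone = 1L, cartilage = 2L),
                          meta = list(geom = unclass(geom))),
    micro = voxel_volume(micro, spacing, binary = TRUE),
    params = host_params
  ), class = "oc_specimen")

  # graft lattice: tight box around the cylinder
  gnx <- as.integer(ceiling((geom$graft_diameter + 2 * spacing) / spacing)) + 1L
  gnz <- as.integer(ceiling(geom$graft_length / spacing)) + 1L
  g_micro_vol <- generate_trabecular_volume(c(gnx, gnx, gnz), spacing,
                                            graft_params)
  glabs <- array(0L, dim = c(gnx, gnx, gnz))
  gcyl <- ellipse_mask(gnx, gnx, spacing, geom$graft_diameter / 2,
                       geom$graft_diameter / 2)
  for (k in seq_len(gnz)) {
    glabs[, , k][gcyl] <- if (k <= nz_cart) 5L else 4L
  }
  gmicro <- g_micro_vol$values
  gmicro[glabs != 4L] <- 0
  graft <- structure(list(
    labels = label_volume(glabs, spacing,
                          labels = c(graft_bone = 4L, graft_cartilage = 5L),
                          meta = list(geom = unclass(geom))),
    micro = voxel_volume(gmicro, spacing, binary = TRUE),
    params = graft_params
  ), class = "oc_specimen")

  list(host = host, graft = graft, geom = geom,
       meta = list(diametral_interference = geom$diametral_interference,
                   flush_offset_seated = geom$graft_length - geom$hole_depth))
}

#' Generate noisy pseudo-experimental observations
#'
#' Adds seeded Gaussian noise to forward-model outputs, producing the
#' observation tables used for parameter-recovery testing. The generating
#' truth is attached so recovery can be scored.
#'
#' @param model_outputs named numeric vector of per-specimen model outputs.
#' @param noise_sd Gaussian noise standard deviation (same units; >= 0).
#' @param seed integer seed.
#' @param unit unit string recorded in the table.
#' @return A data.frame with columns `specimen_id`, `value`, `unit`, `seed`;
#'   attribute `truth` holds the noise-free outputs.
#' @export
generate_pseudo_observations <- function(model_outputs, noise_sd, seed = 1L,
                                         unit = "N") {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  n <- length(model_outputs)
  ids <- names(model_outputs)
  if (is.null(ids)) ids <- sprintf("specimen_%02d", seq_len(n))
  noise <- with_seed(seed, stats::rnorm(n, 0, noise_sd))
  out <- data.frame(specimen_id = ids,
                    value = as.numeric(model_outputs) + noise,
                    unit = unit, seed = as.integer(seed),
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- as.numeric(model_outputs)
  out
}
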