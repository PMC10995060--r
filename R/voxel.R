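#' 3D image volumes with isotropic spacing
#'
#' A `voxel_volume` is the basic image container of the pipeline: a 3D numeric
#' array with an isotropic voxel edge length (mm) and a world-space origin
#' giving the centre of voxel (1,1,1). Axes are in fixed (x, y, z) order.
#' World position of voxel index `(i, j, k)` (1-based) is
#' `origin + (index - 1) * spacing` (voxel-centre convention).
#'
#' @param values 3D numeric array.
#' @param spacing voxel edge length in mm (isotropic, > 0).
#' @param origin numeric length-3, world position (mm) of the first voxel
#'   centre.
#' @param binary logical; if `TRUE` values must be exactly 0/1.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing, origin = c(0, 0, 0), binary = FALSE) {
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("`spacing` must be a single positive number (mm)")
  if (length(origin) != 3L) stop("`origin` must have length 3")
  if (any(dim(values) < 1L)) stop("all dimensions must be >= 1")
  if (binary && !all(values %in% c(0, 1)))
    stop("binary volume must contain only 0 and 1")
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin),
         binary = isTRUE(binary)),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %d x %d x %d, spacing %.4g mm%s\n",
              d[1], d[2], d[3], x$spacing,
              if (isTRUE(x$binary)) ", binary" else ""))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$values)

is_binary_values <- function(v) all(v == 0 | v == 1)

#' Labelled segmentation volumes
#'
#' A `label_volume` stores an integer segmentation on the same lattice as a
#' [voxel_volume()]. Label 0 is always `"void"`; other integers are mapped to
#' region names (`bone`, `cartilage`, `pmma`, `graft_bone`, `graft_cartilage`,
#' `pin`, ...) through the `labels` table. Every voxel carries exactly one
#' label.
#'
#' @param values 3D integer array of label codes (0 = void).
#' @param spacing voxel edge (mm).
#' @param labels named integer vector mapping region name -> code; must not
#'   contain 0 (void is implicit).
#' @param origin world position (mm) of the first voxel centre.
#' @param meta optional list of provenance metadata (generator parameters,
#'   geometry records); carried through untouched.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(values, spacing, labels, origin = c(0, 0, 0),
                         meta = list()) {
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  if (spacing <= 0) stop("`spacing` must be positive")
  if (any(labels == 0L)) stop("label code 0 is reserved for void")
  if (anyDuplicated(labels) || anyDuplicated(names(labels)))
    stop("label codes and names must be unique")
  codes <- unique(as.vector(values))
  unknown <- setdiff(codes, c(0L, unname(labels)))
  if (length(unknown))
    stop("volume contains label codes without names: ",
         paste(unknown, collapse = ", "))
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin),
         labels = labels, meta = meta),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$values)
  present <- label_names_present(x)
  cat(sprintf("<label_volume> %d x %d x %d, spacing %.4g mm, labels: %s\n",
              d[1], d[2], d[3], x$spacing, paste(present, collapse = ", ")))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$values)

#' Region names present in a label volume
#' @param x a [label_volume()].
#' @return character vector of region names with at least one voxel
#'   (including `"void"` if present).
#' @export
label_names_present <- function(x) {
  codes <- sort(unique(as.vector(x$values)))
  vapply(codes, function(cd) {
    if (cd == 0L) "void" else names(x$labels)[match(cd, x$labels)]
  }, character(1))
}

#' Binary mask of one region
#' @param x a [label_volume()].
#' @param region region name (or `"void"`).
#' @return 3D 0/1 array.
#' @export
label_mask <- function(x, region) {
  code <- if (identical(region, "void")) 0L else {
    if (!region %in% names(x$labels)) stop("unknown region: ", region)
    x$labels[[region]]
  }
  (x$values == code) * 1
}

# world coordinates of voxel centres along each axis
voxel_axis <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$spacing
}

#' Write a volume as MetaImage (.mha)
#'
#' Single-file MetaImage with an ASCII header and raw little-endian data
#' (MET_DOUBLE for greyscale, MET_INT for label volumes), readable by
#' standard image toolkits.
#'
#' @param vol a [voxel_volume()] or [label_volume()].
#' @param path output path ending in `.mha`.
#' @return `path`, invisibly.
#' @export
write_mha <- function(vol, path) {
  d <- dim(vol$values)
  is_lab <- inherits(vol, "label_volume")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %.9g %.9g %.9g", vol$origin[1], vol$origin[2], vol$origin[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g", vol$spacing, vol$spacing, vol$spacing),
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementType = %s", if (is_lab) "MET_INT" else "MET_DOUBLE"),
    "ElementDataFile = LOCAL"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  if (is_lab) {
    writeBin(as.integer(vol$values), con, size = 4L, endian = "little")
  } else {
    writeBin(as.double(vol$values), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a MetaImage (.mha) volume written by [write_mha()]
#'
#' @param path path to a local-data `.mha` file.
#' @param labels optional named integer label table; if given, a
#'   [label_volume()] is returned.
#' @return a [voxel_volume()] or [label_volume()].
#' @export
read_mha <- function(path, labels = NULL) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("unexpected end of file in header")
      if (ch == "\n") break
      line <- paste0(line, ch)
    }
    hdr <- c(hdr, line)
    if (grepl("^ElementDataFile", line)) break
  }
  get <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub("^[^=]*=", "", ln[1]))
  }
  d <- as.integer(strsplit(get("DimSize"), " +")[[1]])
  sp <- as.numeric(strsplit(get("ElementSpacing"), " +")[[1]])
  off <- as.numeric(strsplit(get("Offset"), " +")[[1]])
  etype <- get("ElementType")
  n <- prod(d)
  vals <- if (identical(etype, "MET_INT")) {
    readBin(con, "integer", n = n, size = 4L, endian = "little")
  } else {
    readBin(con, "double", n = n, size = 8L, endian = "little")
  }
  arr <- array(vals, dim = d)
  if (!is.null(labels)) {
    label_volume(arr, spacing = sp[1], labels = labels, origin = off)
  } else {
    voxel_volume(arr, spacing = sp[1], origin = off,
                 binary = is_binary_values(arr))
  }
}

#' Write a volume as NIfTI
#' @param vol a [voxel_volume()] or [label_volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- rep(vol$spacing, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#' @param path `.nii` / `.nii.gz` path.
#' @return a [voxel_volume()]. Spacing is taken from the NIfTI pixdim (must
#'   be isotropic); origin defaults to c(0,0,0).
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)[1:3]
  if (diff(range(pd)) > 1e-6 * pd[1])
    stop("anisotropic NIfTI spacing not supported")
  v <- array(as.numeric(img), dim = dim(img)[1:3])
  voxel_volume(v, spacing = pd[1], binary = is_binary_values(v))
}

#' Write generation parameters as a YAML provenance sidecar
#' @param params named list of parameters.
#' @param path output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(params, path) {
  yaml::write_yaml(params, path)
  invisible(path)
}
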