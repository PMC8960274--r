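#' 3D scalar volumes with voxel geometry
#'
#' A `volume_grid` is a plain 3D numeric array carrying voxel spacing (mm per
#' voxel) and a world origin as attributes. It is the common carrier for
#' intensity sub-regions, binary bone masks, lesion masks and attribution heat
#' maps. Voxel order is (x, y, z) with x fastest, matching both R array layout
#' and the NIfTI on-disk layout.
#'
#' @param values numeric 3D array (or object coercible to one).
#' @param spacing positive numeric length-3, mm per voxel.
#' @param origin numeric length-3, world coordinate of the first voxel centre.
#' @return object of class `volume_grid` (a 3D array with geometry attributes).
#' @examples
#' v <- volume_grid(array(0, c(8, 8, 4)), spacing = c(0.082, 0.082, 0.082))
#' dim(v)
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("'values' must be a 3D array")
  if (any(dim(values) < 1L)) stop("all extent components must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("'spacing' must be 3 positive values")
  structure(values, spacing = spacing, origin = as.numeric(origin),
            class = c("volume_grid", "array"))
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(vg_spacing(x), 4), collapse = " x ")))
  cat(sprintf("  values in [%.4g, %.4g]%s\n", min(x), max(x),
              if (is_binary_grid(x)) " (binary)" else ""))
  invisible(x)
}

#' @rdname volume_grid
#' @param x a `volume_grid`.
#' @export
vg_spacing <- function(x) attr(x, "spacing") %||% c(1, 1, 1)

#' @rdname volume_grid
#' @export
vg_origin <- function(x) attr(x, "origin") %||% c(0, 0, 0)

#' @rdname volume_grid
#' @export
is_binary_grid <- function(x) all(x == 0 | x == 1)

as_volume_values <- function(x) {
  # strip geometry attributes, return bare array
  array(as.numeric(x), dim = dim(x))
}

#' Read and write volumes as NIfTI-1
#'
#' Volumes are stored as `.nii.gz` with a diagonal affine carrying the voxel
#' spacing. Binary masks are written as unsigned 8-bit, continuous volumes as
#' 32-bit float.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a [volume_grid]; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)
  volume_grid(vals, spacing = sp[seq_len(3)])
}

#' @rdname read_volume
#' @param vol a [volume_grid] (or 3D array).
#' @param binary write as unsigned 8-bit (for masks). Defaults to automatic
#'   detection.
#' @export
write_volume <- function(vol, path, binary = is_binary_grid(vol)) {
  vals <- as_volume_values(vol)
  if (binary && !all(vals %in% c(0, 1)))
    stop("binary = TRUE but volume has values outside {0, 1}")
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- if (inherits(vol, "volume_grid")) vg_spacing(vol) else c(1, 1, 1)
  ok <- try(RNifti::writeNifti(img, path,
                               datatype = if (binary) "uint8" else "float"),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write volume to '", path, "': ", attr(ok, "condition")$message)
  invisible(path)
}
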