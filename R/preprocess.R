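#' Crop a head-centred sub-region around a bone mask
#'
#' Extracts the tight axis-aligned bounding box of the mask, expanded by
#' `margin_fraction` of the box size per side and clipped to the volume, from
#' both the intensity volume and the mask. Before clipping, the mask centroid
#' lies at the sub-region centre by construction of the bounding box.
#'
#' @param intensity,mask congruent [volume_grid]s (same extent and spacing);
#'   `mask` binary and non-empty.
#' @param margin_fraction non-negative margin added per side, as a fraction of
#'   the bounding-box size (default 0.1).
#' @return list with cropped `intensity` and `mask`.
#' @export
crop_to_head <- function(intensity, mask, margin_fraction = 0.1) {
  if (!identical(dim(intensity), dim(mask)))
    stop("intensity and mask extents differ")
  if (margin_fraction < 0) stop("margin_fraction must be >= 0")
  if (!any(mask > 0)) stop("cannot crop: bone mask is empty")
  idx <- which(mask > 0, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  size <- hi - lo + 1
  lo <- pmax(1, floor(lo - margin_fraction * size))
  hi <- pmin(dim(mask), ceiling(hi + margin_fraction * size))
  sub <- function(v) volume_grid(v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
                                 spacing = vg_spacing(v))
  list(intensity = sub(intensity), mask = sub(mask))
}

#' Resize a volume to a uniform extent
#'
#' Continuous volumes are resampled with trilinear interpolation, binary
#' volumes with nearest-neighbour (so they stay in \{0, 1\}), using the
#' half-voxel-centre convention. This implements the "resized to a uniform
#' extent" step that brings every cropped scan to the network input extent.
#'
#' @param vol a [volume_grid] or 3D array.
#' @param target_extent integer length-3, components >= 4.
#' @param is_binary resample nearest-neighbour and validate binarity.
#' @return [volume_grid] with extent exactly `target_extent`; spacing is
#'   rescaled so the physical field of view is preserved.
#' @export
resize_uniform <- function(vol, target_extent, is_binary = FALSE) {
  v <- as_volume_values(vol)
  d <- dim(v)
  t <- as.integer(round(target_extent))
  if (length(t) != 3L || any(t < 4L)) stop("target extent components must be >= 4")
  if (is_binary && !all(v %in% c(0, 1)))
    stop("is_binary = TRUE but volume has values outside {0, 1}")
  scale <- d / t
  # source coordinate (0-based, voxel centres) of each target voxel per axis
  src <- lapply(1:3, function(a) {
    pmin(pmax((seq_len(t[a]) - 0.5) * scale[a] - 0.5, 0), d[a] - 1)
  })
  if (is_binary) {
    ix <- lapply(1:3, function(a) pmin(round(src[[a]]) + 1, d[a]))
    out <- v[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  } else {
    lo <- lapply(src, floor)
    fr <- mapply(function(s, l) s - l, src, lo, SIMPLIFY = FALSE)
    i0 <- lapply(1:3, function(a) pmin(lo[[a]] + 1, d[a]))
    i1 <- lapply(1:3, function(a) pmin(lo[[a]] + 2, d[a]))
    out <- array(0, t)
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      wx <- if (cx == 0) 1 - fr[[1]] else fr[[1]]
      wy <- if (cy == 0) 1 - fr[[2]] else fr[[2]]
      wz <- if (cz == 0) 1 - fr[[3]] else fr[[3]]
      w <- outer(outer(wx, wy), wz)
      gx <- if (cx == 0) i0[[1]] else i1[[1]]
      gy <- if (cy == 0) i0[[2]] else i1[[2]]
      gz <- if (cz == 0) i0[[3]] else i1[[3]]
      out <- out + w * v[gx, gy, gz, drop = FALSE]
    }
  }
  sp <- if (inherits(vol, "volume_grid")) vg_spacing(vol) else c(1, 1, 1)
  volume_grid(out, spacing = sp * scale)
}

#' Training-set normalization statistics
#'
#' Pools all voxels of all training volumes and returns their mean and
#' standard deviation. Statistics must be refit on the training rows of every
#' cross-validation fold; applying them to held-out scans only is what keeps
#' the folds leakage-free.
#'
#' @param training_volumes list of volumes (arrays or [volume_grid]s), all
#'   from the training split, or a single matrix with one column per volume.
#' @return object of class `normalization_stats`: list with `mean` and `sd`
#'   (sample SD over the pooled voxels) and the voxel count `n`.
#' @export
fit_normalization <- function(training_volumes) {
  if (is.matrix(training_volumes)) {
    vals <- as.numeric(training_volumes)
    nvol <- ncol(training_volumes)
  } else {
    if (!is.list(training_volumes)) training_volumes <- list(training_volumes)
    nvol <- length(training_volumes)
    vals <- unlist(lapply(training_volumes, as.numeric), use.names = FALSE)
  }
  if (nvol < 2L) stop("need at least 2 training volumes")
  m <- mean(vals)
  s <- stats::sd(vals)
  if (!is.finite(s) || s <= 0) stop("training volumes have zero variance")
  structure(list(mean = m, sd = s, n = length(vals)), class = "normalization_stats")
}

#' @export
print.normalization_stats <- function(x, ...) {
  cat(sprintf("<normalization_stats> mean %.6g, sd %.6g (pooled over %d voxels)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

apply_normalization <- function(v, stats) (v - stats$mean) / stats$sd

#' Build a network input representation
#'
#' The model accepts one of three representations of a preprocessed scan:
#' `"subregion"` (normalized intensities), `"mask"` (the raw binary bone mask,
#' fed unnormalized so the prediction rests purely on volumetric shape), or
#' `"product"` (voxel-wise intensity times mask, then normalized with
#' statistics fit on product images).
#'
#' @param subregion,mask congruent volumes already resized to the network
#'   extent.
#' @param kind one of `"subregion"`, `"mask"`, `"product"`.
#' @param stats [fit_normalization] result (required for `"subregion"` and
#'   `"product"`).
#' @return [volume_grid] ready to feed to the network.
#' @export
make_representation <- function(subregion, mask,
                                kind = c("mask", "subregion", "product"),
                                stats = NULL) {
  kind <- match.arg(kind)
  if (!identical(dim(subregion), dim(mask)))
    stop("subregion and mask extents differ")
  if (!is_binary_grid(mask)) stop("mask must be binary")
  sp <- if (inherits(mask, "volume_grid")) vg_spacing(mask) else c(1, 1, 1)
  if (kind == "mask") return(volume_grid(as_volume_values(mask), spacing = sp))
  if (is.null(stats)) stop("normalization stats are required for kind = '", kind, "'")
  v <- as_volume_values(subregion)
  if (kind == "product") v <- v * as_volume_values(mask)
  volume_grid(apply_normalization(v, stats), spacing = sp)
}

#' Load, crop and resize a whole cohort
#'
#' Applies [crop_to_head] and [resize_uniform] to every scan of a manifest and
#' stacks the results as voxel-by-scan matrices. Normalization is *not*
#' applied here: it is fold-dependent and happens inside [cross_validate] /
#' [train_fold].
#'
#' @param manifest a cohort manifest (see [generate_cohort]) whose
#'   `intensity_path`/`mask_path` columns point to NIfTI files, or which
#'   carries in-memory volumes as an attribute (as returned by
#'   [write_cohort]).
#' @param target_extent network input extent, each component >= 4.
#' @param dir directory that relative manifest paths are resolved against.
#' @param margin_fraction crop margin, see [crop_to_head].
#' @return object of class `prepared_cohort`: list with `sub` and `mask`
#'   (V x n matrices), `lesion` (V x n matrix of resized lesion masks, for
#'   attribution scoring), `extent`, and the manifest.
#' @export
prepare_cohort <- function(manifest, target_extent, dir = NULL,
                           margin_fraction = 0.1) {
  t <- as.integer(round(target_extent))
  n <- nrow(manifest)
  V <- prod(t)
  sub <- matrix(0, V, n); msk <- matrix(0, V, n); les <- matrix(0, V, n)
  resolve <- function(p) if (!is.null(dir)) file.path(dir, p) else p
  for (i in seq_len(n)) {
    intensity <- read_volume(resolve(manifest$intensity_path[i]))
    mask <- read_volume(resolve(manifest$mask_path[i]))
    lesion <- if (!is.null(manifest$lesion_path) && !is.na(manifest$lesion_path[i]))
      read_volume(resolve(manifest$lesion_path[i])) else NULL
    cr <- crop_to_head(intensity, mask, margin_fraction)
    rs <- resize_uniform(cr$intensity, t)
    rm_ <- resize_uniform(cr$mask, t, is_binary = TRUE)
    sub[, i] <- as.numeric(rs)
    msk[, i] <- as.numeric(rm_)
    if (!is.null(lesion)) {
      # lesion must be cropped with the same box as the mask
      lesc <- crop_with_box(lesion, mask, margin_fraction)
      les[, i] <- as.numeric(resize_uniform(lesc, t, is_binary = TRUE))
    }
  }
  structure(list(sub = sub, mask = msk, lesion = les, extent = t,
                 manifest = manifest),
            class = "prepared_cohort")
}

# crop an auxiliary volume with the bounding box defined by `mask`
crop_with_box <- function(vol, mask, margin_fraction) {
  idx <- which(mask > 0, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  size <- hi - lo + 1
  lo <- pmax(1, floor(lo - margin_fraction * size))
  hi <- pmin(dim(mask), ceiling(hi + margin_fraction * size))
  volume_grid(as_volume_values(vol)[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
              spacing = vg_spacing(vol))
}

#' @export
print.prepared_cohort <- function(x, ...) {
  cat(sprintf("<prepared_cohort> %d scans at extent %s (%d voxels)\n",
              ncol(x$sub), paste(x$extent, collapse = "x"), nrow(x$sub)))
  invisible(x)
}

# Build the representation matrix for given rows with fold-specific stats.
# Returns list(x = V x n matrix, stats).
representation_matrix <- function(prep, rows, kind, stats = NULL) {
  if (kind == "mask") return(list(x = prep$mask[, rows, drop = FALSE], stats = NULL))
  base <- if (kind == "subregion") prep$sub[, rows, drop = FALSE]
          else prep$sub[, rows, drop = FALSE] * prep$mask[, rows, drop = FALSE]
  if (is.null(stats)) stats <- fit_normalization(base)
  list(x = apply_normalization(base, stats), stats = stats)
}
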