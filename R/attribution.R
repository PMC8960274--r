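#' Guided-backpropagation heat map
#'
#' The gradient of the target-class score with respect to the input volume,
#' with the guided rule applied at every LeakyReLU: the backward signal is
#' zeroed wherever the forward activation was non-positive *or* the incoming
#' gradient is negative. The result highlights the voxels that contributed
#' most to the class decision ("topographical heat map"). Evaluation mode
#' (dropout off) is always used, so repeated calls agree bitwise.
#'
#' @param model a fitted [csae_fit] model.
#' @param input a preprocessed input volume (array, [volume_grid], or V-long
#'   vector) congruent with the model's `target_extent`.
#' @param target_class class label (or 1-based index) whose score is
#'   attributed.
#' @return a `heat_map`: [volume_grid] of signed gradients with attributes
#'   `target_class`.
#' @export
guided_backprop <- function(model, input, target_class) {
  stopifnot(inherits(model, "csae"))
  x <- as_input_matrix(input, model$config)
  if (ncol(x) != 1) stop("guided_backprop attributes one scan at a time")
  if (is.character(target_class) || is.factor(target_class)) {
    idx <- match(as.character(target_class), model$classes)
    if (is.na(idx)) stop("invalid class label: ", target_class)
  } else {
    idx <- as.integer(target_class)
    if (idx < 1 || idx > length(model$classes)) stop("invalid class index")
  }
  g <- cpp_guided_backprop(as.numeric(x), idx, model$weights,
                           unclass(model$config))
  hm <- volume_grid(array(g, model$config$target_extent))
  attr(hm, "target_class") <- model$classes[idx]
  class(hm) <- c("heat_map", class(hm))
  hm
}

#' Hotspot mask from a heat map
#'
#' Marks the voxels whose absolute attribution magnitude lies in the top
#' `top_fraction` quantile; ties at the cut are all included.
#'
#' @param heatmap a heat map ([volume_grid] or array).
#' @param top_fraction fraction of voxels to mark, in (0, 1).
#' @return binary [volume_grid].
#' @export
hotspot_mask <- function(heatmap, top_fraction = 0.01) {
  if (top_fraction <= 0 || top_fraction >= 1)
    stop("top_fraction must lie in (0, 1)")
  a <- abs(as_volume_values(heatmap))
  if (diff(range(a)) == 0)
    stop("constant heat map: hotspot quantile undefined")
  m <- ceiling(top_fraction * length(a))
  cutoff <- sort(as.numeric(a), decreasing = TRUE)[m]
  volume_grid((a >= cutoff) + 0)
}

# binary dilation by a Euclidean ball of the given radius (voxels)
dilate_mask <- function(mask, radius) {
  v <- as_volume_values(mask) > 0
  if (radius <= 0) return(volume_grid(v + 0))
  d <- dim(v)
  r <- ceiling(radius)
  offs <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 + offs$dz^2 <= radius^2, ]
  out <- array(FALSE, d)
  for (i in seq_len(nrow(offs))) {
    o <- as.integer(offs[i, ])
    xs <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
    ys <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
    zs <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
    out[xs + o[1], ys + o[2], zs + o[3]] <-
      out[xs + o[1], ys + o[2], zs + o[3]] | v[xs, ys, zs]
  }
  volume_grid(out + 0)
}

#' Hotspot-lesion localization score
#'
#' Fraction of hotspot voxels that fall inside the ground-truth lesion mask
#' dilated by `dilation_radius` voxels. Under uniformly random hotspots the
#' expected score equals the dilated lesion's volume fraction, which makes
#' the enrichment over that baseline a quantitative check that attribution
#' points at the lesions.
#'
#' @param hotspots binary hotspot mask (from [hotspot_mask]).
#' @param lesion_mask binary ground-truth lesion mask, congruent.
#' @param dilation_radius tolerance radius in voxels (default 3).
#' @return fraction in \[0, 1\].
#' @export
lesion_localization_score <- function(hotspots, lesion_mask, dilation_radius = 3) {
  h <- as_volume_values(hotspots) > 0
  l <- as_volume_values(lesion_mask) > 0
  if (!identical(dim(h), dim(l))) stop("hotspots and lesion mask are not congruent")
  if (!any(h)) stop("empty hotspot set")
  dil <- as_volume_values(dilate_mask(l, dilation_radius)) > 0
  mean(dil[h])
}
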