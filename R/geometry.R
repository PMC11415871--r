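#' Label connected components of a 3D binary mask
#'
#' Components are found under face (6) or face/edge/vertex (26) connectivity.
#' Labels are assigned in scan order starting at 1; background voxels get 0.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 or 26 (default 26, the convention used by all
#'   lesion-component operators in this package).
#' @return integer array of the same shape holding component labels.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  lab <- .cc_label_cpp(as.logical(mask), as.integer(dim(mask)), as.integer(connectivity))
  array(lab, dim = dim(mask))
}

#' Euclidean distance transform of a 3D binary mask
#'
#' For voxels inside the mask, the exact Euclidean distance (in physical
#' units) from the voxel centre to the nearest voxel centre outside the
#' mask; 0 outside the mask. A mask covering the whole grid yields `Inf`.
#'
#' @param mask logical 3D array.
#' @param spacing numeric length-3 voxel size per axis (default 1,1,1 for a
#'   purely voxel-unit transform).
#' @return numeric array of distances.
#' @export
distance_transform <- function(mask, spacing = c(1, 1, 1)) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, length(spacing) == 3L,
            all(spacing > 0))
  d2 <- .edt_sq_cpp(as.logical(mask), as.integer(dim(mask)), as.numeric(spacing))
  array(sqrt(d2), dim = dim(mask))
}

#' Fill enclosed cavities of a 3D binary mask
#'
#' Background components (6-connected, the complement convention for a
#' 26-connected foreground) that do not touch the grid border are treated
#' as cavities and filled.
#'
#' @param mask logical 3D array.
#' @return logical array with cavities filled.
#' @export
fill_holes <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  bg <- label_components(!mask, connectivity = 6L)
  dm <- dim(mask)
  border <- array(FALSE, dm)
  border[c(1, dm[1]), , ] <- TRUE
  border[, c(1, dm[2]), ] <- TRUE
  border[, , c(1, dm[3])] <- TRUE
  outside <- unique(bg[border & bg > 0L])
  mask | (bg > 0L & !(bg %in% outside))
}

#' Dilate a 3D binary mask by a Euclidean radius
#'
#' A voxel belongs to the dilation iff its centre lies within `radius`
#' (voxel units by default) of some mask voxel centre.
#'
#' @param mask logical 3D array.
#' @param radius non-negative dilation radius.
#' @param spacing voxel size per axis used for the distance (default voxel
#'   units).
#' @return logical array.
#' @export
dilate_mask <- function(mask, radius, spacing = c(1, 1, 1)) {
  stopifnot(radius >= 0)
  if (!any(mask)) return(mask & FALSE)
  d <- distance_transform(!mask, spacing = spacing)
  out <- mask | (d <= radius + 1e-9)
  array(out, dim = dim(mask))
}
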