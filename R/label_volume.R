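# Internal label coding is fixed: 0 = background, 1 = nonenhancing tumour
# (NET), 2 = perilesional signal change (PS), 3 = enhancing tumour (ET).
# External files in other dialects are remapped on load.
.compartments <- c(background = 0L, net = 1L, ps = 2L, et = 3L)

# registered label dialects: external code -> internal code
.dialects <- list(
  internal = c(`0` = 0L, `1` = 1L, `2` = 2L, `3` = 3L),
  brats    = c(`0` = 0L, `1` = 1L, `2` = 2L, `4` = 3L)
)

#' Construct a label volume
#'
#' A `label_volume` couples a 3D array of compartment codes with its voxel
#' spacing, a voxel-to-world affine, and a template-space tag. It is the
#' sole patient-level input of the featurisation engine.
#'
#' @param voxels 3D integer array with codes in \{0, 1, 2, 3\}
#'   (background / NET / PS / ET).
#' @param spacing numeric length-3, strictly positive voxel size in mm.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices). Default:
#'   axis-aligned RAS with the world origin at the grid centre, so the
#'   template midsagittal plane x = 0 bisects the grid.
#' @param space_tag template-space identifier (informative only).
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(voxels, spacing = c(1, 1, 1), affine = NULL,
                         space_tag = "MNI152") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop_data("voxels must be a 3D array (got %s dimensions)",
              length(dim(voxels)))
  storage.mode(voxels) <- "integer"
  bad <- setdiff(unique(as.vector(voxels)), 0:3)
  if (length(bad))
    stop_data("voxel codes outside {0,1,2,3}: %s",
              paste(sort(bad), collapse = ", "))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_data("spacing must be three strictly positive values")
  if (is.null(affine)) affine <- centred_affine(dim(voxels), spacing)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)))
    stop_data("affine must be a 4x4 matrix")
  structure(
    list(voxels = voxels, spacing = spacing, affine = affine,
         space_tag = space_tag),
    class = "label_volume"
  )
}

# axis-aligned affine placing the world origin at the grid centre
centred_affine <- function(dim, spacing) {
  a <- diag(c(spacing, 1))
  a[1:3, 4] <- -(dim - 1) / 2 * spacing
  a
}

#' @export
print.label_volume <- function(x, ...) {
  cts <- compartment_counts(x)
  cat(sprintf(
    "<label_volume> %s grid, spacing %s mm, space %s\n  ET %d | NET %d | PS %d voxels\n",
    paste(dim(x$voxels), collapse = "x"),
    paste(signif(x$spacing, 4), collapse = "x"),
    x$space_tag, cts[["et"]], cts[["net"]], cts[["ps"]]
  ))
  invisible(x)
}

#' Per-compartment voxel counts of a label volume
#'
#' @param vol a `label_volume`.
#' @return named integer vector with elements `net`, `ps`, `et`.
#' @export
compartment_counts <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  v <- vol$voxels
  c(net = sum(v == 1L), ps = sum(v == 2L), et = sum(v == 3L))
}

#' Extract a compartment (or derived union) as a binary mask
#'
#' @param vol a `label_volume`.
#' @param which one of `"et"`, `"net"`, `"ps"`, `"core"` (ET plus NET) or
#'   `"lesion"` (all foreground).
#' @return logical 3D array.
#' @export
compartment_mask <- function(vol, which = c("et", "net", "ps", "core", "lesion")) {
  stopifnot(inherits(vol, "label_volume"))
  which <- match.arg(which)
  v <- vol$voxels
  switch(which,
    et     = v == 3L,
    net    = v == 1L,
    ps     = v == 2L,
    core   = v == 3L | v == 1L,
    lesion = v != 0L
  )
}

# world x coordinate of every voxel centre (for midline tests); returns a
# 3D array aligned with vol$voxels
voxel_world_x <- function(vol) {
  dm <- dim(vol$voxels)
  a <- vol$affine
  ix <- (seq_len(dm[1]) - 1)
  iy <- (seq_len(dm[2]) - 1)
  iz <- (seq_len(dm[3]) - 1)
  outer(outer(a[1, 1] * ix, a[1, 2] * iy, `+`), a[1, 3] * iz, `+`) + a[1, 4]
}

#' Read a segmentation NIfTI into a label volume
#'
#' The file's codes are remapped to the internal compartment coding through
#' a registered label dialect. Unknown codes are rejected rather than
#' silently dropped.
#'
#' @param path NIfTI file (.nii or .nii.gz), 3D or 4D with a trailing
#'   singleton dimension.
#' @param label_dialect `"internal"` (codes 0/1/2/3 = background/NET/PS/ET)
#'   or `"brats"` (0/1/2/4 with 4 = enhancing tumour).
#' @param space_tag template-space tag recorded on the volume.
#' @return a `label_volume`.
#' @export
load_segmentation <- function(path, label_dialect = "internal",
                              space_tag = "MNI152") {
  if (!file.exists(path)) stop_data("segmentation file not found: %s", path)
  if (!label_dialect %in% names(.dialects))
    stop_config("unknown label dialect '%s' (registered: %s)", label_dialect,
                paste(names(.dialects), collapse = ", "))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  dm <- dim(arr)
  if (length(dm) == 4L && dm[4] == 1L) {
    arr <- array(arr, dm[1:3])
    dm <- dm[1:3]
  }
  if (length(dm) != 3L)
    stop_data("expected a 3D volume, got %s dimensions", length(dm))
  codes <- as.integer(round(arr))
  table <- .dialects[[label_dialect]]
  known <- as.integer(names(table))
  bad <- setdiff(unique(codes), known)
  if (length(bad))
    stop_data("label(s) outside the '%s' dialect table: %s", label_dialect,
              paste(sort(bad), collapse = ", "))
  remapped <- table[as.character(codes)]
  vox <- array(as.integer(remapped), dm)
  spacing <- as.numeric(RNifti::pixdim(img))[1:3]
  affine <- unclass(RNifti::xform(img))
  label_volume(vox, spacing = spacing, affine = affine, space_tag = space_tag)
}

#' Write a label volume to NIfTI
#'
#' Codes are written as stored (internal dialect); spacing and affine go to
#' the header, so a write/read round trip reproduces the volume exactly.
#'
#' @param vol a `label_volume`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  img <- RNifti::asNifti(vol$voxels, datatype = "int16")
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# exact-shape + affine agreement check between a volume and an atlas grid
check_grid <- function(vol, atlas, tol = 1e-4) {
  if (!all(dim(vol$voxels) == atlas$dim))
    stop_data("grid mismatch: segmentation %s vs atlas %s",
              paste(dim(vol$voxels), collapse = "x"),
              paste(atlas$dim, collapse = "x"))
  if (!is.null(atlas$affine) &&
      max(abs(vol$affine - atlas$affine)) > tol)
    stop_data("affine mismatch between segmentation and atlas (max |diff| = %g)",
              max(abs(vol$affine - atlas$affine)))
  invisible(TRUE)
}
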