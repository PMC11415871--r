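#' Construct an atlas set
#'
#' A named collection of binary anatomical region masks on one grid, each
#' tagged with laterality and (optionally) the VASARI location category it
#' contributes to, plus the special roles the contact features need:
#' `ventricles` (ependymal invasion), `cortex` (cortical involvement), and
#' the `deep_wm` set (corpus callosum, internal capsule, brainstem — deep
#' white matter invasion).
#'
#' @param regions named list of logical/0-1 3D arrays on a common grid.
#' @param laterality named character, one of `"left"`, `"right"`,
#'   `"midline"` per region.
#' @param location_map named character mapping region name to a VASARI
#'   location category; `NA` excludes the region from location scoring
#'   (used for purely role-bearing masks such as ventricles and cortex).
#' @param roles named character per region: `"ventricles"`, `"cortex"`,
#'   `"deep_wm"` or `"none"`.
#' @param spacing voxel size in mm (default 1 mm isotropic).
#' @param affine optional 4x4 voxel-to-world matrix shared with the
#'   segmentations it will be combined with.
#' @return an object of class `atlas_set`.
#' @export
atlas_set <- function(regions, laterality, location_map, roles,
                      spacing = c(1, 1, 1), affine = NULL) {
  nms <- names(regions)
  if (is.null(nms) || anyDuplicated(nms))
    stop_config("regions must be a uniquely named list")
  dims <- unique(lapply(regions, dim))
  if (length(dims) != 1L || length(dims[[1]]) != 3L)
    stop_data("all atlas masks must share one 3D grid shape")
  regions <- lapply(regions, function(m) array(m != 0, dim = dim(m)))
  for (set in list(laterality, location_map, roles))
    if (!all(nms %in% names(set)))
      stop_config("laterality, location_map and roles must cover every region")
  bad_lat <- setdiff(unique(laterality[nms]), c("left", "right", "midline"))
  if (length(bad_lat))
    stop_config("invalid laterality tag(s): %s", paste(bad_lat, collapse = ", "))
  roles <- roles[nms]
  for (need in c("ventricles", "cortex", "deep_wm")) {
    if (!any(roles == need, na.rm = TRUE))
      stop_config("atlas is missing a region with required role '%s'", need)
  }
  if (is.null(affine)) affine <- centred_affine(dims[[1]], spacing)
  structure(
    list(regions = regions, laterality = laterality[nms],
         location_map = location_map[nms], roles = roles,
         dim = dims[[1]], spacing = as.numeric(spacing),
         affine = as.matrix(affine)),
    class = "atlas_set"
  )
}

#' @export
print.atlas_set <- function(x, ...) {
  cat(sprintf("<atlas_set> %d regions on a %s grid\n", length(x$regions),
              paste(x$dim, collapse = "x")))
  invisible(x)
}

# union mask of all regions carrying a role
role_mask <- function(atlas, role) {
  nms <- names(atlas$roles)[atlas$roles == role]
  if (!length(nms)) stop_config("atlas has no region with role '%s'", role)
  out <- array(FALSE, atlas$dim)
  for (nm in nms) out <- out | atlas$regions[[nm]]
  out
}

#' Load an atlas set from a directory of NIfTI masks and a manifest
#'
#' The manifest (CSV or YAML) lists one row/entry per region with columns
#' `name`, `file`, `laterality`, `f1_location` (empty = excluded from
#' location scoring) and `role` (`ventricles`, `cortex`, `deep_wm` or
#' `none`). Masks are binarised at 0.5, so probabilistic maps are accepted.
#'
#' @param dir directory containing the mask files.
#' @param manifest path to the manifest (.csv, .yaml or .yml).
#' @return an `atlas_set`.
#' @export
load_atlas <- function(dir, manifest) {
  if (!dir.exists(dir)) stop_data("atlas directory not found: %s", dir)
  if (!file.exists(manifest)) stop_data("manifest not found: %s", manifest)
  ext <- tolower(tools::file_ext(manifest))
  if (ext %in% c("yaml", "yml")) {
    rows <- yaml::read_yaml(manifest)
    tab <- dplyr::bind_rows(lapply(rows, function(r) {
      tibble(name = r$name, file = r$file,
             laterality = r$laterality,
             f1_location = r$f1_location %||% NA_character_,
             role = r$role %||% "none")
    }))
  } else {
    tab <- readr::read_csv(manifest, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  }
  need <- c("name", "file", "laterality")
  if (!all(need %in% names(tab)))
    stop_config("manifest must provide columns: %s", paste(need, collapse = ", "))
  if (!"f1_location" %in% names(tab)) tab$f1_location <- NA_character_
  if (!"role" %in% names(tab)) tab$role <- "none"
  tab$role[is.na(tab$role) | tab$role == ""] <- "none"
  tab$f1_location[!is.na(tab$f1_location) & tab$f1_location == ""] <- NA_character_

  regions <- list()
  spacing <- NULL
  affine <- NULL
  for (i in seq_len(nrow(tab))) {
    fp <- file.path(dir, tab$file[i])
    if (!file.exists(fp)) stop_data("atlas mask not found: %s", fp)
    img <- RNifti::readNifti(fp)
    arr <- as.array(img)
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
      arr <- array(arr, dim(arr)[1:3])
    regions[[tab$name[i]]] <- arr >= 0.5
    if (is.null(spacing)) {
      spacing <- as.numeric(RNifti::pixdim(img))[1:3]
      affine <- unclass(RNifti::xform(img))
    }
  }
  dims <- unique(lapply(regions, dim))
  if (length(dims) != 1L)
    stop_data("atlas masks do not share one grid shape")
  atlas_set(
    regions,
    laterality = setNames(tab$laterality, tab$name),
    location_map = setNames(tab$f1_location, tab$name),
    roles = setNames(tab$role, tab$name),
    spacing = spacing, affine = affine
  )
}

#' Write an atlas set to a directory of NIfTI masks plus a CSV manifest
#'
#' @param atlas an `atlas_set`.
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "atlas_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- tibble(
    name = names(atlas$regions),
    file = paste0(names(atlas$regions), ".nii.gz"),
    laterality = unname(atlas$laterality),
    f1_location = unname(atlas$location_map),
    role = unname(atlas$roles)
  )
  for (i in seq_len(nrow(tab))) {
    img <- RNifti::asNifti(array(as.integer(atlas$regions[[tab$name[i]]]),
                                 atlas$dim), datatype = "uint8")
    RNifti::qform(img) <- structure(atlas$affine, code = 2L)
    RNifti::sform(img) <- structure(atlas$affine, code = 2L)
    RNifti::writeNifti(img, file.path(dir, tab$file[i]))
  }
  manifest <- file.path(dir, "manifest.csv")
  readr::write_csv(tab, manifest)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
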