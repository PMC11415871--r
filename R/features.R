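#' Tumour core mask (ET plus NET)
#'
#' Locational features (F1/F2, F9, F19-F23) are defined on the tumour core,
#' the union of enhancing and nonenhancing tumour; perilesional signal
#' change is excluded.
#'
#' @param vol a `label_volume`.
#' @return logical 3D array.
#' @export
tumour_core <- function(vol) compartment_mask(vol, "core")

# world x of the voxels selected by a mask, given a 4x4 affine
mask_world_x <- function(mask, affine) {
  idx <- which(mask, arr.ind = TRUE) - 1L
  affine[1, 1] * idx[, 1] + affine[1, 2] * idx[, 2] +
    affine[1, 3] * idx[, 3] + affine[1, 4]
}

#' Tumour location and side of epicentre (F1/F2)
#'
#' F1 is the VASARI location category of the atlas region holding the
#' largest share of core voxels (regions without a location mapping, such
#' as ventricles and cortex, do not compete). F2 is decided by the signed
#' hemispheric core-volume imbalance about the template midsagittal plane
#' (world x = 0): `"center/bilateral"` when the minority hemisphere holds
#' at least `center_fraction` of off-plane core voxels or the winning
#' region is midline-tagged, otherwise the majority side.
#'
#' @param core logical core mask (see [tumour_core()]).
#' @param atlas an `atlas_set` on the same grid.
#' @param params a [vasari_params()] list.
#' @return list with elements `f1`, `f2`, `region` (winning region name or
#'   `NA`), and `side_counts` (left/right off-plane core voxels).
#' @export
derive_f1_f2_location <- function(core, atlas, params = vasari_params()) {
  if (!any(core)) {
    return(list(f1 = "n/a", f2 = "n/a", region = NA_character_,
                side_counts = c(left = 0L, right = 0L)))
  }
  eligible <- names(atlas$regions)[!is.na(atlas$location_map)]
  overlaps <- vapply(eligible, function(nm) sum(core & atlas$regions[[nm]]),
                     integer(1))
  region <- if (length(overlaps) && max(overlaps) > 0L) {
    eligible[[which.max(overlaps)]]     # ties: first region in atlas order
  } else NA_character_
  f1 <- if (is.na(region)) "n/a" else unname(atlas$location_map[[region]])

  xw <- mask_world_x(core, atlas$affine)
  eps <- 1e-9
  left <- sum(xw < -eps)
  right <- sum(xw > eps)
  total <- left + right
  f2 <- if (total == 0L) {
    "center/bilateral"                  # all core voxels on the plane
  } else if (min(left, right) / total >= params$center_fraction) {
    "center/bilateral"
  } else if (!is.na(region) && atlas$laterality[[region]] == "midline") {
    "center/bilateral"
  } else if (left > right) "left" else "right"

  list(f1 = f1, f2 = f2, region = region,
       side_counts = c(left = left, right = right))
}

#' Compartment proportions and enhancement quality (F4-F7, F14)
#'
#' The whole lesion is ET + NET + PS. Necrosis (F7) is the NET that lies in
#' cavities fully enclosed by the enhancing tumour (3D hole fill of the ET
#' mask, minus ET, intersected with NET); F6 uses the residual
#' (non-enclosed) NET. Fractions are binned with [vasari_bin()].
#' Enhancement quality F4 is `"none"` when ET is absent, `"mild"` when the
#' ET fraction is below `f4_mild_threshold`, else `"marked"`.
#'
#' @param vol a `label_volume`.
#' @param params a [vasari_params()] list.
#' @return list with bin labels `f4`, `f5`, `f6`, `f7`, `f14` and a
#'   `fractions`/`counts` raw block.
#' @export
derive_proportions <- function(vol, params = vasari_params()) {
  et <- compartment_mask(vol, "et")
  net <- compartment_mask(vol, "net")
  ps <- compartment_mask(vol, "ps")
  n_et <- sum(et); n_net <- sum(net); n_ps <- sum(ps)
  total <- n_et + n_net + n_ps

  if (total == 0L) {
    fr <- c(et = NA_real_, necrosis = NA_real_, net_residual = NA_real_,
            ps = NA_real_)
    return(list(f4 = "n/a", f5 = "n/a", f6 = "n/a", f7 = "n/a", f14 = "n/a",
                fractions = fr,
                counts = c(et = 0L, necrosis = 0L, net_residual = 0L,
                           ps = 0L, lesion = 0L)))
  }

  enclosed <- fill_holes(et) & !et
  necrosis <- net & enclosed
  net_resid <- net & !enclosed
  n_necr <- sum(necrosis); n_resid <- sum(net_resid)

  counts <- c(et = n_et, necrosis = n_necr, net_residual = n_resid,
              ps = n_ps, lesion = total)
  fr <- counts[1:4] / total
  f4 <- if (n_et == 0L) "none"
        else if (fr[["et"]] < params$f4_mild_threshold) "mild" else "marked"

  list(
    f4 = f4,
    f5 = bin_from_counts(n_et, total),
    f6 = bin_from_counts(n_resid, total),
    f7 = bin_from_counts(n_necr, total),
    f14 = bin_from_counts(n_ps, total),
    fractions = fr, counts = counts
  )
}

#' Lesion focality (F9)
#'
#' Core components (26-connected by default) smaller than
#' `min_component_voxels` are discarded as noise. One surviving component
#' is `"focal"`; several that share one connected component of the whole
#' lesion (core bridged by perilesional signal) are `"multifocal"`;
#' otherwise `"multicentric"`.
#'
#' @inheritParams derive_proportions
#' @return list with `f9`, `n_core_components`, `n_lesion_components`.
#' @export
derive_f9_focality <- function(vol, params = vasari_params()) {
  core <- tumour_core(vol)
  lab <- label_components(core, params$connectivity)
  sizes <- tabulate(lab)
  keep <- which(sizes >= params$min_component_voxels)
  if (!length(keep))
    return(list(f9 = "n/a", n_core_components = 0L, n_lesion_components = 0L))

  lesion_lab <- label_components(compartment_mask(vol, "lesion"),
                                 params$connectivity)
  hosts <- vapply(keep, function(k) {
    unique(lesion_lab[lab == k])[1]     # a core component lies in one host
  }, integer(1))
  f9 <- if (length(keep) == 1L) "focal"
        else if (length(unique(hosts)) == 1L) "multifocal"
        else "multicentric"
  list(f9 = f9, n_core_components = length(keep),
       n_lesion_components = length(unique(lesion_lab[lesion_lab > 0L])))
}

# 26-neighbourhood local maxima of a numeric field restricted to a mask
local_maxima <- function(field, mask) {
  dm <- dim(field)
  is_max <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    shifted <- array(-Inf, dm)
    xs <- max(1, 1 + dx):min(dm[1], dm[1] + dx)
    ys <- max(1, 1 + dy):min(dm[2], dm[2] + dy)
    zs <- max(1, 1 + dz):min(dm[3], dm[3] + dz)
    shifted[xs, ys, zs] <- field[xs - dx, ys - dy, zs - dz]
    is_max <- is_max & (field >= shifted)
  }
  is_max
}

#' Thickness of the enhancing margin (F11)
#'
#' With no ET the feature is `"n/a"`. An ET mask without any enclosed
#' cavity is `"solid"` (there is no rim to measure). Otherwise the rim
#' thickness is estimated from the Euclidean distance transform of the ET
#' mask: twice the summary (mean by default) of the transform over the
#' medial rim voxels (local maxima of the transform within ET), minus half
#' a voxel spacing as a boundary correction (the transform reaches the
#' centre of the first voxel beyond the rim, overshooting the geometric
#' boundary, while the medial plateau slightly undershoots the true medial
#' radius; on rasterised spherical shells the net bias is half a voxel).
#' Thin below `thickness_threshold_mm` (3 mm), thick at or above.
#' Requires near-isotropic voxels.
#'
#' @inheritParams derive_proportions
#' @return list with `f11` and `thickness_mm`.
#' @export
derive_f11_thickness <- function(vol, params = vasari_params()) {
  sp <- vol$spacing
  if ((max(sp) - min(sp)) / min(sp) > params$isotropy_tol)
    stop_data("thickness derivation requires isotropic spacing within %g%% (got %s)",
              100 * params$isotropy_tol, paste(signif(sp, 4), collapse = "x"))
  et <- compartment_mask(vol, "et")
  if (!any(et)) return(list(f11 = "n/a", thickness_mm = 0))
  if (all(fill_holes(et) == et))
    return(list(f11 = "solid", thickness_mm = NA_real_))

  edt <- distance_transform(et, spacing = sp)
  medial <- local_maxima(edt, et)
  vals <- edt[medial]
  stat <- switch(params$thickness_stat,
                 mean = mean(vals),
                 median = stats::median(vals),
                 p95 = stats::quantile(vals, 0.95, names = FALSE))
  thickness <- max(2 * stat - 0.5 * mean(sp), 0)
  f11 <- if (thickness < params$thickness_threshold_mm) "thin" else "thick"
  list(f11 = f11, thickness_mm = thickness)
}

#' Ependymal, cortical and deep white matter involvement (F19-F21)
#'
#' F19 is true iff the core dilated by `contact_radius` voxels meets the
#' ventricular mask; F20/F21 are true iff the core overlaps the cortex /
#' the deep white matter set (corpus callosum, internal capsule, brainstem)
#' by at least `min_overlap_voxels`.
#'
#' @inheritParams derive_f1_f2_location
#' @return list of logicals `f19`, `f20`, `f21`.
#' @export
derive_f19_f20_f21_contact <- function(core, atlas, params = vasari_params()) {
  vent <- role_mask(atlas, "ventricles")
  cortex <- role_mask(atlas, "cortex")
  deepwm <- role_mask(atlas, "deep_wm")
  if (!any(core)) return(list(f19 = FALSE, f20 = FALSE, f21 = FALSE))
  dil <- dilate_mask(core, params$contact_radius)
  list(
    f19 = any(dil & vent),
    f20 = sum(core & cortex) >= params$min_overlap_voxels,
    f21 = sum(core & deepwm) >= params$min_overlap_voxels
  )
}

# does any connected component of mask hold >= min_cross voxels strictly on
# each side of the world x = 0 plane?
crosses_midline <- function(mask, affine, connectivity, min_cross) {
  if (!any(mask)) return(FALSE)
  lab <- label_components(mask, connectivity)
  idx <- which(mask, arr.ind = TRUE)
  xw <- affine[1, 1] * (idx[, 1] - 1) + affine[1, 2] * (idx[, 2] - 1) +
    affine[1, 3] * (idx[, 3] - 1) + affine[1, 4]
  comp <- lab[mask]
  eps <- 1e-9
  for (k in unique(comp)) {
    xs <- xw[comp == k]
    if (sum(xs < -eps) >= min_cross && sum(xs > eps) >= min_cross)
      return(TRUE)
  }
  FALSE
}

#' Midline crossing of the nonenhancing and enhancing compartments (F22/F23)
#'
#' For each compartment (all NET including enclosed necrosis for F22; ET
#' for F23): true iff a single connected component holds at least
#' `min_cross_voxels` voxels strictly on each side of the template
#' midsagittal plane (world x = 0).
#'
#' @inheritParams derive_proportions
#' @return list of logicals `f22`, `f23`.
#' @export
derive_midline_crossing <- function(vol, params = vasari_params()) {
  list(
    f22 = crosses_midline(compartment_mask(vol, "net"), vol$affine,
                          params$connectivity, params$min_cross_voxels),
    f23 = crosses_midline(compartment_mask(vol, "et"), vol$affine,
                          params$connectivity, params$min_cross_voxels)
  )
}

#' Satellite lesions (F24)
#'
#' ET components are ranked by size; after removing the largest, a
#' remaining component is a satellite iff it has at least
#' `min_satellite_voxels` voxels and lies outside the dominant lesion's
#' core-plus-perilesional envelope (i.e. in a different connected component
#' of the whole lesion).
#'
#' @inheritParams derive_proportions
#' @return list with logical `f24` and `n_et_components`.
#' @export
derive_f24_satellites <- function(vol, params = vasari_params()) {
  et <- compartment_mask(vol, "et")
  if (!any(et)) return(list(f24 = FALSE, n_et_components = 0L))
  lab <- label_components(et, params$connectivity)
  sizes <- tabulate(lab)
  dominant <- which.max(sizes)          # ties: first label in scan order
  if (length(sizes) == 1L)
    return(list(f24 = FALSE, n_et_components = 1L))

  lesion_lab <- label_components(compartment_mask(vol, "lesion"),
                                 params$connectivity)
  host_of <- function(k) unique(lesion_lab[lab == k])[1]
  dominant_host <- host_of(dominant)
  others <- setdiff(seq_along(sizes), dominant)
  sat <- vapply(others, function(k) {
    sizes[k] >= params$min_satellite_voxels && host_of(k) != dominant_host
  }, logical(1))
  list(f24 = any(sat), n_et_components = length(sizes))
}

#' Derive the full VASARI report from a segmentation and an atlas
#'
#' Orchestrates every feature operator and returns a `vasari_report`
#' holding the 15 derived feature codes plus the raw measurements they were
#' binned from. The computation is purely geometric and deterministic:
#' identical inputs and parameters give an identical report.
#'
#' @param vol a `label_volume`.
#' @param atlas an `atlas_set` on the same grid.
#' @param params a [vasari_params()] list.
#' @return a `vasari_report`; see [as_tibble.vasari_report()].
#' @export
derive_vasari <- function(vol, atlas, params = vasari_params()) {
  stopifnot(inherits(vol, "label_volume"), inherits(atlas, "atlas_set"))
  check_grid(vol, atlas)
  core <- tumour_core(vol)

  loc <- derive_f1_f2_location(core, atlas, params)
  prop <- derive_proportions(vol, params)
  foc <- derive_f9_focality(vol, params)
  thick <- derive_f11_thickness(vol, params)
  contact <- derive_f19_f20_f21_contact(core, atlas, params)
  cross <- derive_midline_crossing(vol, params)
  sat <- derive_f24_satellites(vol, params)

  voxel_mm3 <- prod(vol$spacing)
  counts <- prop$counts
  raw <- list(
    voxel_mm3 = voxel_mm3,
    volume_mm3 = as.list(counts * voxel_mm3),
    voxel_counts = as.list(counts),
    fractions = as.list(prop$fractions),
    thickness_mm = thick$thickness_mm,
    n_core_components = foc$n_core_components,
    n_lesion_components = foc$n_lesion_components,
    n_et_components = sat$n_et_components,
    epicentre_region = loc$region,
    side_counts = as.list(loc$side_counts)
  )

  report <- structure(
    list(
      features = list(
        f1 = loc$f1, f2 = loc$f2, f4 = prop$f4, f5 = prop$f5, f6 = prop$f6,
        f7 = prop$f7, f9 = foc$f9, f11 = thick$f11, f14 = prop$f14,
        f19 = contact$f19, f20 = contact$f20, f21 = contact$f21,
        f22 = cross$f22, f23 = cross$f23, f24 = sat$f24
      ),
      raw = raw,
      params = unclass(params)
    ),
    class = "vasari_report"
  )
  validate_vasari_report(report)
  report
}

# internal consistency checks promised by the report contract
validate_vasari_report <- function(r) {
  f <- r$features
  fr <- unlist(r$raw$fractions)
  if (!anyNA(fr)) {
    if (abs(sum(fr) - 1) > 1e-9)
      stop_data("internal error: compartment fractions sum to %.12f", sum(fr))
    cts <- unlist(r$raw$voxel_counts)
    stopifnot(identical(f$f5, bin_from_counts(cts[["et"]], cts[["lesion"]])),
              identical(f$f6, bin_from_counts(cts[["net_residual"]], cts[["lesion"]])),
              identical(f$f7, bin_from_counts(cts[["necrosis"]], cts[["lesion"]])),
              identical(f$f14, bin_from_counts(cts[["ps"]], cts[["lesion"]])))
  }
  et_absent <- r$raw$voxel_counts$et == 0L
  if (et_absent && !f$f4 %in% c("none", "n/a"))
    stop_data("internal error: ET absent but F4 = %s", f$f4)
  if (et_absent && !f$f11 %in% c("n/a", "none"))
    stop_data("internal error: ET absent but F11 = %s", f$f11)
  if (!et_absent && f$f4 %in% c("none", "n/a"))
    stop_data("internal error: ET present but F4 = %s", f$f4)
  invisible(r)
}
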