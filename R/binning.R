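.bin_levels <- c("n/a", "0%", "<5%", "6-33%", "34-67%", "68-95%", ">95%", "100%")

#' Bin a lesion-compartment fraction into the VASARI ordinal categories
#'
#' Boundary convention (documented, left-open/right-closed): a fraction f
#' maps to `"<5%"` when 0 < f <= 0.05, `"6-33%"` when 0.05 < f <= 1/3,
#' `"34-67%"` when 1/3 < f <= 2/3, `"68-95%"` when 2/3 < f <= 0.95,
#' `">95%"` when f > 0.95, and `"100%"` only when the compartment equals
#' the whole lesion exactly (f == 1 in exact voxel counts).
#'
#' @param f numeric vector of fractions in \[0, 1\]; `NA` maps to `"n/a"`.
#' @return character vector of bin labels (see `vasari_feature_levels()`).
#' @export
vasari_bin <- function(f) {
  vapply(f, function(x) {
    if (is.na(x)) return("n/a")
    if (x < 0 || x > 1) stop_data("fraction outside [0,1]: %g", x)
    if (x == 0) "0%"
    else if (x == 1) "100%"
    else if (x <= 0.05) "<5%"
    else if (x <= 1 / 3) "6-33%"
    else if (x <= 2 / 3) "34-67%"
    else if (x <= 0.95) "68-95%"
    else ">95%"
  }, character(1))
}

# exact-count version: "0%" and "100%" decided on integer counts, interior
# bins on the floating fraction
bin_from_counts <- function(count, total) {
  if (total == 0L) return("n/a")
  if (count == 0L) return("0%")
  if (count == total) return("100%")
  vasari_bin(count / total)
}

#' Declared ordered category sets of the derived VASARI features
#'
#' Used by the agreement metrics to build linear weight matrices over the
#' full declared scale (so unobserved categories still shape the weights)
#' and by [as_rater_table()] to encode reports as ordinal integers. Codes
#' are 0-based positions in these vectors.
#'
#' @return named list of character vectors, one per feature id.
#' @export
vasari_feature_levels <- function() {
  list(
    f1  = c("n/a", "frontal", "temporal", "insular", "parietal", "occipital",
            "brainstem", "cerebellum", "thalamus", "corpus callosum"),
    f2  = c("n/a", "right", "center/bilateral", "left"),
    f4  = c("n/a", "none", "mild", "marked"),
    f5  = .bin_levels,
    f6  = .bin_levels,
    f7  = .bin_levels,
    f9  = c("n/a", "focal", "multifocal", "multicentric"),
    f11 = c("n/a", "none", "thin", "thick", "solid"),
    f14 = .bin_levels,
    f19 = c("FALSE", "TRUE"),
    f20 = c("FALSE", "TRUE"),
    f21 = c("FALSE", "TRUE"),
    f22 = c("FALSE", "TRUE"),
    f23 = c("FALSE", "TRUE"),
    f24 = c("FALSE", "TRUE")
  )
}

#' Tunable parameters of the featurisation engine
#'
#' All geometric thresholds are exposed here; the defaults are chosen for
#' robustness to single-voxel segmentation noise on 1 mm isotropic grids.
#'
#' @param center_fraction minority-hemisphere core fraction at or above
#'   which the epicentre side (F2) is called `"center/bilateral"`.
#' @param f4_mild_threshold ET fraction below which enhancement quality
#'   (F4) is `"mild"` rather than `"marked"`.
#' @param min_component_voxels smallest core component (in voxels) counted
#'   by the focality analysis (F9).
#' @param contact_radius dilation radius in voxels for ependymal contact
#'   (F19).
#' @param min_overlap_voxels minimum core overlap (voxels) for cortical
#'   (F20) and deep white matter (F21) involvement.
#' @param min_cross_voxels minimum voxels required strictly on each side of
#'   the midsagittal plane for a midline crossing (F22/F23).
#' @param min_satellite_voxels smallest ET component that can count as a
#'   satellite lesion (F24).
#' @param connectivity neighbourhood for all component analyses (26 or 6).
#' @param thickness_stat summary over medial rim distances for F11:
#'   `"mean"`, `"median"` or `"p95"`.
#' @param thickness_threshold_mm thin/thick boundary for the enhancing
#'   margin (F11), in mm.
#' @param isotropy_tol maximal relative spread of voxel spacing tolerated
#'   by the thickness operator.
#' @return named list of parameters (class `vasari_params`).
#' @export
vasari_params <- function(center_fraction = 0.4,
                          f4_mild_threshold = 0.05,
                          min_component_voxels = 10L,
                          contact_radius = 1,
                          min_overlap_voxels = 10L,
                          min_cross_voxels = 5L,
                          min_satellite_voxels = 10L,
                          connectivity = 26L,
                          thickness_stat = c("mean", "median", "p95"),
                          thickness_threshold_mm = 3,
                          isotropy_tol = 0.05) {
  p <- list(
    center_fraction = center_fraction,
    f4_mild_threshold = f4_mild_threshold,
    min_component_voxels = as.integer(min_component_voxels),
    contact_radius = contact_radius,
    min_overlap_voxels = as.integer(min_overlap_voxels),
    min_cross_voxels = as.integer(min_cross_voxels),
    min_satellite_voxels = as.integer(min_satellite_voxels),
    connectivity = as.integer(connectivity),
    thickness_stat = match.arg(thickness_stat),
    thickness_threshold_mm = thickness_threshold_mm,
    isotropy_tol = isotropy_tol
  )
  if (!p$connectivity %in% c(6L, 26L))
    stop_config("connectivity must be 6 or 26")
  if (p$center_fraction <= 0 || p$center_fraction > 0.5)
    stop_config("center_fraction must lie in (0, 0.5]")
  structure(p, class = "vasari_params")
}
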