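# Shared fixture builders: everything is generated in code at test time.

# solid ball mask by voxel-centre inclusion; centre in 1-based voxel indices
ball_mask <- function(shape, centre, radius, spacing = c(1, 1, 1)) {
  dx2 <- ((seq_len(shape[1]) - centre[1]) * spacing[1])^2
  dy2 <- ((seq_len(shape[2]) - centre[2]) * spacing[2])^2
  dz2 <- ((seq_len(shape[3]) - centre[3]) * spacing[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
}

# label volume assembled from compartment masks (ET wins over NET over PS)
make_vol <- function(shape = c(48L, 48L, 48L), et = NULL, net = NULL,
                     ps = NULL, spacing = c(1, 1, 1), affine = NULL) {
  vox <- array(0L, shape)
  if (!is.null(ps)) vox[ps] <- 2L
  if (!is.null(net)) vox[net] <- 1L
  if (!is.null(et)) vox[et] <- 3L
  label_volume(vox, spacing = spacing, affine = affine)
}

# cached small toy atlas for feature tests
toy48 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_atlas(c(48L, 48L, 48L))
    cache
  }
})

# reflect a label volume about the midsagittal plane (first axis); with the
# centred affine this maps world x to -x exactly
reflect_volume <- function(vol) {
  n <- dim(vol$voxels)[1]
  label_volume(vol$voxels[n:1, , , drop = FALSE], spacing = vol$spacing,
               affine = vol$affine, space_tag = vol$space_tag)
}

# reflect an atlas: flip every region and swap left/right laterality tags
reflect_atlas <- function(atlas) {
  n <- atlas$dim[1]
  regions <- lapply(atlas$regions, function(m) m[n:1, , , drop = FALSE])
  lat <- atlas$laterality
  lat[] <- c(left = "right", right = "left", midline = "midline")[lat]
  atlas_set(regions, lat, atlas$location_map, atlas$roles,
            spacing = atlas$spacing, affine = atlas$affine)
}

# translate a label volume by whole voxels (zero padding at the edges)
translate_volume <- function(vol, shift) {
  v <- vol$voxels
  dm <- dim(v)
  out <- array(0L, dm)
  src <- lapply(1:3, function(a) {
    r <- seq_len(dm[a]) - shift[a]
    r[r >= 1 & r <= dm[a]]
  })
  dst <- lapply(1:3, function(a) {
    r <- seq_len(dm[a])
    r[r - shift[a] >= 1 & r - shift[a] <= dm[a]]
  })
  out[dst[[1]], dst[[2]], dst[[3]]] <- v[src[[1]], src[[2]], src[[3]]]
  label_volume(out, spacing = vol$spacing, affine = vol$affine)
}

feature_names <- function() names(vasari_feature_levels())
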