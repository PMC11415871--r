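test_that("a write/read round trip reproduces codes, spacing and affine", {
  set.seed(11)
  vox <- array(sample(0:3, 20^3, replace = TRUE), c(20, 20, 20))
  vol <- label_volume(vox, spacing = c(1, 1, 1))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_segmentation(vol, path)
  back <- load_segmentation(path)
  expect_identical(back$voxels, vol$voxels)
  expect_equal(back$spacing, vol$spacing)
  expect_lt(max(abs(back$affine - vol$affine)), 1e-4)
})

test_that("BraTS dialect remapping is volume preserving", {
  set.seed(7)
  ext <- array(sample(c(0L, 1L, 2L, 4L), 16^3, replace = TRUE,
                      prob = c(0.7, 0.1, 0.1, 0.1)), c(16, 16, 16))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(ext, datatype = "int16"), path)
  vol <- load_segmentation(path, label_dialect = "brats")
  # bijective relabel: per-compartment counts equal the source counts
  expect_identical(sum(vol$voxels == 1L), sum(ext == 1L))  # NET
  expect_identical(sum(vol$voxels == 2L), sum(ext == 2L))  # PS
  expect_identical(sum(vol$voxels == 3L), sum(ext == 4L))  # ET
  expect_identical(sum(vol$voxels != 0L), sum(ext != 0L))
})

test_that("unknown labels and dialects are rejected with useful errors", {
  ext <- array(0L, c(8, 8, 8)); ext[3, 3, 3] <- 5L
  path <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(ext, datatype = "int16"), path)
  expect_error(load_segmentation(path, label_dialect = "brats"),
               "5", class = "vasarify_data_error")
  expect_error(load_segmentation(path, label_dialect = "nonesuch"),
               class = "vasarify_config_error")
})

test_that("an all-zero segmentation loads as a valid lesion-free volume", {
  path <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0L, c(8, 8, 8)),
                                     datatype = "int16"), path)
  vol <- load_segmentation(path)
  expect_identical(unname(sum(compartment_counts(vol))), 0L)
})

test_that("trailing-singleton 4D volumes are accepted, other 4D rejected", {
  path <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1L, c(6, 6, 6, 1)),
                                     datatype = "int16"), path)
  expect_identical(dim(load_segmentation(path)$voxels), c(6L, 6L, 6L))
  RNifti::writeNifti(RNifti::asNifti(array(1L, c(6, 6, 6, 2)),
                                     datatype = "int16"), path)
  expect_error(load_segmentation(path), class = "vasarify_data_error")
})

test_that("label_volume validates codes and spacing", {
  expect_error(label_volume(array(4L, c(4, 4, 4))),
               class = "vasarify_data_error")
  expect_error(label_volume(array(0L, c(4, 4, 4)), spacing = c(1, -1, 1)),
               class = "vasarify_data_error")
  expect_error(label_volume(matrix(0L, 4, 4)), class = "vasarify_data_error")
})

test_that("atlas write/load round trip preserves regions and metadata", {
  atlas <- toy48()
  dir <- withr::local_tempdir()
  manifest <- write_atlas(atlas, dir)
  back <- load_atlas(dir, manifest)
  expect_identical(names(back$regions), names(atlas$regions))
  expect_identical(back$laterality, atlas$laterality)
  expect_identical(back$roles, atlas$roles)
  for (nm in names(atlas$regions))
    expect_identical(back$regions[[nm]], atlas$regions[[nm]])
})

test_that("a manifest missing a required role is a configuration error", {
  atlas <- toy48()
  dir <- withr::local_tempdir()
  manifest <- write_atlas(atlas, dir)
  tab <- readr::read_csv(manifest, show_col_types = FALSE)
  readr::write_csv(tab[tab$name != "ventricles", ], manifest)
  expect_error(load_atlas(dir, manifest), "ventricles",
               class = "vasarify_config_error")
})

test_that("probabilistic atlas masks are binarised at 0.5", {
  prob <- array(0, c(10, 10, 10))
  prob[2:4, 2:4, 2:4] <- 0.3   # 27 voxels below threshold
  prob[6:8, 6:8, 6:8] <- 0.7   # 27 voxels above
  dir <- withr::local_tempdir()
  for (nm in c("ventricles", "cortex", "corpus_callosum"))
    RNifti::writeNifti(RNifti::asNifti(prob), file.path(dir, paste0(nm, ".nii.gz")))
  manifest <- file.path(dir, "manifest.csv")
  readr::write_csv(tibble::tibble(
    name = c("ventricles", "cortex", "corpus_callosum"),
    file = paste0(name, ".nii.gz"),
    laterality = "midline", f1_location = NA_character_,
    role = c("ventricles", "cortex", "deep_wm")), manifest)
  atlas <- load_atlas(dir, manifest)
  # voxel-count oracle: only the 27 above-threshold voxels survive
  expect_identical(sum(atlas$regions$ventricles), 27L)
})

test_that("grid and affine mismatches between volume and atlas are caught", {
  atlas <- toy48()
  vol_bad <- make_vol(shape = c(32L, 32L, 32L))
  expect_error(derive_vasari(vol_bad, atlas), "mismatch",
               class = "vasarify_data_error")
  vol_shift <- make_vol(shape = c(48L, 48L, 48L),
                        affine = centre_shifted <- {
                          a <- atlas$affine; a[1, 4] <- a[1, 4] + 1; a
                        })
  expect_error(derive_vasari(vol_shift, atlas), "affine",
               class = "vasarify_data_error")
})
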