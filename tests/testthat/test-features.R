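# Feature operators on constructed lesions over the 48^3 toy atlas
# (midplane between voxels 24 and 25; world x = i - 24.5).

test_that("the tumour core is the ET/NET union, excluding PS", {
  shape <- c(48L, 48L, 48L)
  et <- array(FALSE, shape); et[10:14, 34:37, 31:35] <- TRUE   # 100 voxels
  net <- array(FALSE, shape); net[10:14, 30:31, 21:25] <- TRUE # 50
  ps <- array(FALSE, shape); ps[20:29, 10:29, 10] <- TRUE      # 200
  vol <- make_vol(shape, et = et, net = net, ps = ps)
  expect_identical(sum(tumour_core(vol)), 150L)
  ps_only <- make_vol(shape, ps = ps)
  expect_false(any(tumour_core(ps_only)))
})

test_that("location and side follow maximal overlap and hemispheric balance", {
  atlas <- toy48()
  shape <- c(48L, 48L, 48L)

  core <- array(FALSE, shape)
  core[10:14, 34:38, 34:38] <- TRUE          # wholly in left frontal
  loc <- derive_f1_f2_location(core, atlas)
  expect_identical(loc[c("f1", "f2")], list(f1 = "frontal", f2 = "left"))

  # 90 voxels right temporal vs 10 right insular -> temporal, right
  core <- array(FALSE, shape)
  core[26:30, 34:36, 10:15] <- TRUE
  core[36:37, 21:25, 21] <- TRUE
  expect_identical(sum(core & atlas$regions$temporal_right), 90L)
  expect_identical(sum(core & atlas$regions$insula_right), 10L)
  loc <- derive_f1_f2_location(core, atlas)
  expect_identical(loc[c("f1", "f2")], list(f1 = "temporal", f2 = "right"))

  # 35/25 hemispheric split: minority 41.7% >= 40% -> center/bilateral
  core <- array(FALSE, shape)
  core[20:24, 34:40, 36] <- TRUE
  core[25:29, 34:38, 36] <- TRUE
  loc <- derive_f1_f2_location(core, atlas)
  expect_identical(loc$f2, "center/bilateral")

  empty <- array(FALSE, shape)
  loc <- derive_f1_f2_location(empty, atlas)
  expect_identical(loc[c("f1", "f2")], list(f1 = "n/a", f2 = "n/a"))
})

test_that("compartment proportions, necrosis and enhancement quality", {
  shape <- c(48L, 48L, 48L)
  # disjoint blocks ET 50 / NET 30 / PS 20 (no enclosure)
  et <- array(FALSE, shape); et[10:14, 10:19, 10] <- TRUE
  net <- array(FALSE, shape); net[20:22, 10:19, 10] <- TRUE
  ps <- array(FALSE, shape); ps[26:27, 10:19, 10] <- TRUE
  pr <- derive_proportions(make_vol(shape, et = et, net = net, ps = ps))
  expect_equal(unname(unlist(pr$fractions)), c(0.5, 0, 0.3, 0.2))
  expect_identical(pr[c("f4", "f5", "f6", "f7", "f14")],
                   list(f4 = "marked", f5 = "34-67%", f6 = "6-33%",
                        f7 = "0%", f14 = "6-33%"))

  # ET-only lesion
  pr <- derive_proportions(make_vol(shape, et = et))
  expect_identical(pr[c("f5", "f6", "f7", "f14")],
                   list(f5 = "100%", f6 = "0%", f7 = "0%", f14 = "0%"))

  # ET shell fully filled by NET: all NET is necrosis, F6 is 0%
  shell <- ball_mask(shape, c(24, 24, 24), 7) & !ball_mask(shape, c(24, 24, 24), 4)
  inner <- ball_mask(shape, c(24, 24, 24), 4)
  pr <- derive_proportions(make_vol(shape, et = shell, net = inner))
  expect_equal(pr$fractions[["necrosis"]], sum(inner) / (sum(shell) + sum(inner)))
  expect_identical(pr$f6, "0%")
  expect_identical(pr$f7, "6-33%")

  pr <- derive_proportions(make_vol(shape))
  expect_identical(pr$f5, "n/a")
})

test_that("fraction binning agrees with the published table and convention", {
  f <- seq(0, 1, by = 0.001)
  oracle <- function(x) {
    if (x == 0) "0%" else if (x <= 0.05) "<5%" else if (x <= 1 / 3) "6-33%"
    else if (x <= 2 / 3) "34-67%" else if (x <= 0.95) "68-95%"
    else if (x < 1) ">95%" else "100%"
  }
  expect_identical(vasari_bin(f), vapply(f, oracle, character(1)))
  # boundaries are right-closed
  expect_identical(vasari_bin(c(0.05, 1 / 3, 2 / 3, 0.95)),
                   c("<5%", "6-33%", "34-67%", "68-95%"))
  expect_identical(vasari_bin(NA), "n/a")
})

test_that("focality distinguishes focal, multifocal and multicentric", {
  shape <- c(48L, 48L, 48L)
  b1 <- ball_mask(shape, c(14, 34, 34), 3)
  b2 <- ball_mask(shape, c(14, 34, 14), 3)

  expect_identical(derive_f9_focality(make_vol(shape, et = b1))$f9, "focal")

  corridor <- array(FALSE, shape); corridor[13:15, 33:35, 14:34] <- TRUE
  bridged <- make_vol(shape, et = b1 | b2, ps = corridor & !(b1 | b2))
  expect_identical(derive_f9_focality(bridged)$f9, "multifocal")

  shells <- (ball_mask(shape, c(14, 34, 34), 5) & !b1) |
    (ball_mask(shape, c(14, 34, 14), 5) & !b2)
  separate <- make_vol(shape, et = b1 | b2, ps = shells)
  expect_identical(derive_f9_focality(separate)$f9, "multicentric")

  # sub-threshold second component is ignored
  speck <- array(FALSE, shape); speck[40, 40, 40] <- TRUE
  expect_identical(derive_f9_focality(make_vol(shape, et = b1 | speck))$f9,
                   "focal")
  expect_identical(derive_f9_focality(make_vol(shape))$f9, "n/a")
})

test_that("enhancing margin thickness: n/a, solid, and measured rims", {
  shape <- c(48L, 48L, 48L)
  expect_identical(derive_f11_thickness(make_vol(shape))$f11, "n/a")

  solid <- ball_mask(shape, c(24, 24, 24), 8)
  expect_identical(derive_f11_thickness(make_vol(shape, et = solid))$f11,
                   "solid")

  # spherical shell outer r = 10, inner r = 7: analytic width 3 mm
  shell <- ball_mask(shape, c(24, 24, 24), 10) & !ball_mask(shape, c(24, 24, 24), 7)
  res <- derive_f11_thickness(make_vol(shape, et = shell))
  expect_gt(res$thickness_mm, 2.5)
  expect_lt(res$thickness_mm, 3.5)
  expect_identical(res$f11, "thick")

  # 2 mm rim is thin
  shell2 <- ball_mask(shape, c(24, 24, 24), 8) & !ball_mask(shape, c(24, 24, 24), 6)
  expect_identical(derive_f11_thickness(make_vol(shape, et = shell2))$f11,
                   "thin")

  aniso <- make_vol(shape, et = solid, spacing = c(1, 1, 1.2))
  expect_error(derive_f11_thickness(aniso), "isotropic",
               class = "vasarify_data_error")
})

test_that("ependymal, cortical and deep white matter contact", {
  atlas <- toy48()
  shape <- c(48L, 48L, 48L)

  touching <- array(FALSE, shape); touching[19:20, 22:27, 23:28] <- TRUE
  res <- derive_f19_f20_f21_contact(touching, atlas)
  expect_true(res$f19)

  distant <- array(FALSE, shape); distant[13:15, 22:27, 23:28] <- TRUE
  expect_false(derive_f19_f20_f21_contact(distant, atlas)$f19)

  in_cc <- array(FALSE, shape); in_cc[21:26, 21:26, 31:32] <- TRUE
  expect_true(derive_f19_f20_f21_contact(in_cc, atlas)$f21)

  on_cortex <- array(FALSE, shape); on_cortex[7:8, 20:30, 20:30] <- TRUE
  expect_true(derive_f19_f20_f21_contact(on_cortex, atlas)$f20)
  expect_false(derive_f19_f20_f21_contact(in_cc, atlas)$f20)
})

test_that("midline crossing needs one component with voxels on both sides", {
  shape <- c(48L, 48L, 48L)
  right_only <- array(FALSE, shape); right_only[30:34, 30:34, 30:34] <- TRUE
  expect_false(derive_midline_crossing(make_vol(shape, et = right_only))$f23)

  spanning <- array(FALSE, shape); spanning[20:29, 30:32, 36:38] <- TRUE
  res <- derive_midline_crossing(make_vol(shape, et = spanning))
  expect_true(res$f23)
  expect_false(res$f22)

  # two disjoint NET components, one per hemisphere, neither spanning
  two <- array(FALSE, shape)
  two[18:22, 30:34, 30:34] <- TRUE
  two[27:31, 30:34, 30:34] <- TRUE
  two[23:26, , ] <- FALSE
  expect_false(derive_midline_crossing(make_vol(shape, net = two))$f22)
})

test_that("satellites require size and separation from the dominant envelope", {
  shape <- c(48L, 48L, 48L)
  dom <- ball_mask(shape, c(14, 34, 34), 5)
  env <- ball_mask(shape, c(14, 34, 34), 8) & !dom

  expect_false(derive_f24_satellites(make_vol(shape, et = dom, ps = env))$f24)

  far <- ball_mask(shape, c(34, 14, 14), 2)          # 33 voxels, outside envelope
  expect_true(derive_f24_satellites(make_vol(shape, et = dom | far, ps = env))$f24)

  speck <- array(FALSE, shape); speck[34, 14, 14] <- TRUE
  speck[35, 14, 14] <- TRUE; speck[34, 15, 14] <- TRUE
  expect_false(derive_f24_satellites(make_vol(shape, et = dom | speck,
                                              ps = env))$f24)

  # a second focus attached to the dominant envelope is not a satellite
  joined <- ball_mask(shape, c(14, 34, 25), 2)       # touches the PS shell
  expect_false(derive_f24_satellites(make_vol(shape, et = dom | joined,
                                              ps = env))$f24)
})

test_that("derive_vasari is deterministic and handles empty input", {
  atlas <- toy48()
  ph <- make_phantom(phantom_spec(
    "unit", foci = list(list(centre = c(14, 34, 34), r_necrotic = 2,
                             r_enhancing = 5, r_oedema = 7)),
    shape = c(48L, 48L, 48L)), atlas = atlas, validate = FALSE)
  r1 <- derive_vasari(ph$volume, atlas)
  r2 <- derive_vasari(ph$volume, atlas)
  expect_identical(write_report_json(r1), write_report_json(r2))

  empty <- make_vol(c(48L, 48L, 48L))
  r <- derive_vasari(empty, atlas)
  expect_identical(r$features$f1, "n/a")
  expect_identical(r$features$f5, "n/a")
  expect_false(any(unlist(r$features[c("f19", "f20", "f21", "f22", "f23", "f24")])))
  expect_identical(r$raw$voxel_counts$lesion, 0L)
})

test_that("report invariants hold on a necrotic phantom", {
  atlas <- toy48()
  ph <- make_phantom(phantom_spec(
    "inv", foci = list(list(centre = c(14, 34, 34), r_necrotic = 3,
                            r_enhancing = 6, r_oedema = 8)),
    shape = c(48L, 48L, 48L)), atlas = atlas, validate = FALSE)
  r <- derive_vasari(ph$volume, atlas)
  fr <- unlist(r$raw$fractions)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  cts <- unlist(r$raw$voxel_counts)
  expect_identical(unname(cts[["et"]] + cts[["necrosis"]] +
                            cts[["net_residual"]] + cts[["ps"]]),
                   unname(cts[["lesion"]]))
})
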