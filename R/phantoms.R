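# set TRUE inside an axis-aligned box given inclusive 1-based index ranges
box_mask <- function(shape, x, y, z) {
  m <- array(FALSE, shape)
  m[x[1]:x[2], y[1]:y[2], z[1]:z[2]] <- TRUE
  m
}

#' Build the synthetic box-brain atlas
#'
#' A mirror-symmetric toy atlas hosting every region the featurisation
#' engine needs: eight lobar octants (left/right frontal, temporal,
#' parietal, occipital), insulae, thalami, internal capsules, a corpus
#' callosum slab, a brainstem block, midline ventricles, and a cortical
#' shell (the outer two voxel layers of the brain box — the only region
#' allowed to share voxels with none here, all regions are pairwise
#' disjoint by construction). The grid centre sits on the template
#' midsagittal plane, so reflecting the first axis maps each left region
#' exactly onto its right counterpart.
#'
#' @param shape 3D grid shape; every axis must be even and at least 48.
#' @param spacing voxel size in mm (default 1 mm isotropic).
#' @return an `atlas_set` with 17 regions.
#' @export
make_toy_atlas <- function(shape = c(64L, 64L, 64L), spacing = c(1, 1, 1)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 48L) || any(shape %% 2L != 0L))
    stop_config("toy atlas needs an even grid of at least 48 voxels per axis")
  n <- shape; cx <- n[1] %/% 2L; cy <- n[2] %/% 2L; cz <- n[3] %/% 2L

  brain_lo <- 7L; brain_hi <- n - 6L
  int_lo <- 9L; int_hi <- n - 8L
  deep <- function(c) c(c - 8L, c + 9L)

  brain <- box_mask(n, c(brain_lo, brain_hi[1]), c(brain_lo, brain_hi[2]),
                    c(brain_lo, brain_hi[3]))
  interior <- box_mask(n, c(int_lo, int_hi[1]), c(int_lo, int_hi[2]),
                       c(int_lo, int_hi[3]))
  cortex <- brain & !interior
  deep_box <- box_mask(n, deep(cx), deep(cy), deep(cz))

  ventricles <- box_mask(n, c(cx - 3L, cx + 4L), c(cy - 4L, cy + 5L),
                         c(cz - 2L, cz + 5L))
  corpus_callosum <- box_mask(n, c(cx - 4L, cx + 5L), c(cy - 4L, cy + 5L),
                              c(cz + 6L, cz + 9L))
  brainstem <- box_mask(n, c(cx - 3L, cx + 4L), c(cy - 3L, cy + 4L),
                        c(cz - 8L, cz - 3L))
  thalamus_l <- box_mask(n, c(cx - 8L, cx - 4L), c(cy - 4L, cy + 5L),
                         c(cz - 2L, cz + 5L))
  thalamus_r <- box_mask(n, c(cx + 5L, cx + 9L), c(cy - 4L, cy + 5L),
                         c(cz - 2L, cz + 5L))
  ic_l <- box_mask(n, c(cx - 8L, cx - 4L), c(cy + 6L, cy + 9L),
                   c(cz - 6L, cz + 5L))
  ic_r <- box_mask(n, c(cx + 5L, cx + 9L), c(cy + 6L, cy + 9L),
                   c(cz - 6L, cz + 5L))
  insula_l <- box_mask(n, c(10L, 13L), c(cy - 4L, cy + 5L),
                       c(cz - 4L, cz + 5L))
  insula_r <- box_mask(n, c(n[1] - 12L, n[1] - 9L), c(cy - 4L, cy + 5L),
                       c(cz - 4L, cz + 5L))
  carveout <- deep_box | insula_l | insula_r

  octant <- function(xs, ys, zs) {
    m <- interior & box_mask(n, xs, ys, zs) & !carveout
    m
  }
  xl <- c(int_lo, cx); xr <- c(cx + 1L, int_hi[1])
  y_ant <- c(cy + 1L, int_hi[2]); y_post <- c(int_lo, cy)
  z_sup <- c(cz + 1L, int_hi[3]); z_inf <- c(int_lo, cz)

  regions <- list(
    frontal_left = octant(xl, y_ant, z_sup),
    frontal_right = octant(xr, y_ant, z_sup),
    temporal_left = octant(xl, y_ant, z_inf),
    temporal_right = octant(xr, y_ant, z_inf),
    parietal_left = octant(xl, y_post, z_sup),
    parietal_right = octant(xr, y_post, z_sup),
    occipital_left = octant(xl, y_post, z_inf),
    occipital_right = octant(xr, y_post, z_inf),
    insula_left = insula_l, insula_right = insula_r,
    thalamus_left = thalamus_l, thalamus_right = thalamus_r,
    internal_capsule_left = ic_l, internal_capsule_right = ic_r,
    corpus_callosum = corpus_callosum,
    brainstem = brainstem,
    ventricles = ventricles,
    cortex = cortex
  )
  laterality <- c(
    frontal_left = "left", frontal_right = "right",
    temporal_left = "left", temporal_right = "right",
    parietal_left = "left", parietal_right = "right",
    occipital_left = "left", occipital_right = "right",
    insula_left = "left", insula_right = "right",
    thalamus_left = "left", thalamus_right = "right",
    internal_capsule_left = "left", internal_capsule_right = "right",
    corpus_callosum = "midline", brainstem = "midline",
    ventricles = "midline", cortex = "midline"
  )
  location_map <- c(
    frontal_left = "frontal", frontal_right = "frontal",
    temporal_left = "temporal", temporal_right = "temporal",
    parietal_left = "parietal", parietal_right = "parietal",
    occipital_left = "occipital", occipital_right = "occipital",
    insula_left = "insular", insula_right = "insular",
    thalamus_left = "thalamus", thalamus_right = "thalamus",
    internal_capsule_left = NA, internal_capsule_right = NA,
    corpus_callosum = "corpus callosum", brainstem = "brainstem",
    ventricles = NA, cortex = NA
  )
  roles <- c(
    frontal_left = "none", frontal_right = "none",
    temporal_left = "none", temporal_right = "none",
    parietal_left = "none", parietal_right = "none",
    occipital_left = "none", occipital_right = "none",
    insula_left = "none", insula_right = "none",
    thalamus_left = "none", thalamus_right = "none",
    internal_capsule_left = "deep_wm", internal_capsule_right = "deep_wm",
    corpus_callosum = "deep_wm", brainstem = "deep_wm",
    ventricles = "ventricles", cortex = "cortex"
  )
  atlas_set(regions, laterality, location_map, roles, spacing = spacing)
}

#' Describe a synthetic lesion with declared ground truth
#'
#' A phantom is one or more concentric-sphere foci — an optional
#' nonenhancing (necrotic) core of radius `r_necrotic`, an enhancing shell
#' out to `r_enhancing`, a perilesional shell out to `r_oedema` (all mm;
#' voxel-centre rasterisation) — plus optional ET-only satellite foci, and
#' the VASARI report the construction guarantees. [make_phantom()]
#' verifies the declaration at generation time, so a fixture whose
#' geometry cannot realise its declared truth fails loudly instead of
#' silently producing a wrong oracle.
#'
#' @param name identifier.
#' @param foci list of `list(centre = c(x, y, z), r_necrotic, r_enhancing,
#'   r_oedema)` with 1-based (possibly fractional) voxel-index centres and
#'   radii `r_necrotic <= r_enhancing <= r_oedema`.
#' @param ground_truth named list of expected feature values (any subset
#'   of f1 ... f24).
#' @param satellites list of `list(centre, radius)` ET-only foci; must be
#'   non-empty exactly when `ground_truth$f24` is `TRUE`.
#' @param shape,spacing grid the phantom is rasterised on.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(name, foci = list(), ground_truth = list(),
                         satellites = list(),
                         shape = c(64L, 64L, 64L), spacing = c(1, 1, 1)) {
  for (f in foci) {
    r <- c(f$r_necrotic, f$r_enhancing, f$r_oedema)
    if (length(r) != 3L || any(diff(r) < 0))
      stop_config("focus radii must satisfy r_necrotic <= r_enhancing <= r_oedema")
    if (length(f$centre) != 3L) stop_config("focus centre must have 3 coordinates")
  }
  if (!is.null(ground_truth$f24)) {
    if (isTRUE(as.logical(ground_truth$f24)) != (length(satellites) > 0))
      stop_config("phantom '%s': satellites list must be non-empty exactly when f24 is TRUE",
                  name)
  }
  structure(list(name = name, shape = as.integer(shape),
                 spacing = as.numeric(spacing), foci = foci,
                 satellites = satellites, ground_truth = ground_truth),
            class = "phantom_spec")
}

# physical distance of every voxel centre from a (fractional) voxel-index
# centre
centre_distance <- function(shape, spacing, centre) {
  dx2 <- ((seq_len(shape[1]) - centre[1]) * spacing[1])^2
  dy2 <- ((seq_len(shape[2]) - centre[2]) * spacing[2])^2
  dz2 <- ((seq_len(shape[3]) - centre[3]) * spacing[3])^2
  sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
}

#' Rasterise a phantom and verify its declared ground truth
#'
#' Compartment precedence where foci overlap is innermost-first: necrotic
#' core (NET), then enhancing tumour, then perilesional signal change. A
#' voxel belongs to a ball iff its centre lies within the radius. When
#' `validate` is on (the default) the phantom is featurised and every
#' declared ground-truth entry is checked; a mismatch is a generation-time
#' error.
#'
#' @param spec a [phantom_spec()].
#' @param atlas atlas to validate against (default: toy atlas on the
#'   spec's grid).
#' @param params featurisation parameters used for validation.
#' @param validate verify the declaration by featurising the phantom.
#' @return list with `volume` (a `label_volume`), `report` (the derived
#'   `vasari_report`, `NULL` if `validate = FALSE`) and `spec`.
#' @export
make_phantom <- function(spec, atlas = NULL, params = vasari_params(),
                         validate = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(atlas)) atlas <- make_toy_atlas(spec$shape, spec$spacing)
  shape <- spec$shape
  net <- array(FALSE, shape); et <- array(FALSE, shape)
  ps <- array(FALSE, shape)
  for (f in spec$foci) {
    d <- centre_distance(shape, spec$spacing, f$centre)
    if (f$r_necrotic > 0) net <- net | (d <= f$r_necrotic)
    in_core <- f$r_necrotic > 0 & d <= f$r_necrotic
    if (f$r_enhancing > 0) et <- et | (d <= f$r_enhancing & !in_core)
    if (f$r_oedema > 0) ps <- ps | (d > f$r_enhancing & d <= f$r_oedema)
  }
  for (s in spec$satellites) {
    d <- centre_distance(shape, spec$spacing, s$centre)
    et <- et | (d <= s$radius)
  }
  et <- et & !net
  ps <- ps & !net & !et
  vox <- array(0L, shape)
  vox[net] <- 1L; vox[ps] <- 2L; vox[et] <- 3L
  vol <- label_volume(vox, spacing = spec$spacing, affine = atlas$affine)

  report <- NULL
  if (validate) {
    report <- derive_vasari(vol, atlas, params)
    gt <- spec$ground_truth
    mism <- character()
    for (nm in names(gt)) {
      got <- report$features[[nm]]
      want <- gt[[nm]]
      if (is.logical(got)) want <- as.logical(want)
      if (!identical(as.character(got), as.character(want)))
        mism <- c(mism, sprintf("%s: declared %s, derived %s", nm,
                                as.character(want), as.character(got)))
    }
    if (length(mism))
      stop_data("phantom '%s' cannot realise its declared ground truth:\n  %s",
                spec$name, paste(mism, collapse = "\n  "))
  }
  list(volume = vol, report = report, spec = spec)
}

#' Read / write phantom specs as YAML
#'
#' @param path YAML file.
#' @return [read_phantom_spec()] returns a `phantom_spec`.
#' @export
read_phantom_spec <- function(path) {
  if (!file.exists(path)) stop_data("phantom spec not found: %s", path)
  y <- yaml::read_yaml(path)
  phantom_spec(
    name = y$name %||% tools::file_path_sans_ext(basename(path)),
    foci = lapply(y$foci %||% list(), function(f)
      list(centre = as.numeric(f$centre), r_necrotic = f$r_necrotic,
           r_enhancing = f$r_enhancing, r_oedema = f$r_oedema)),
    satellites = lapply(y$satellites %||% list(), function(s)
      list(centre = as.numeric(s$centre), radius = s$radius)),
    ground_truth = y$ground_truth %||% list(),
    shape = y$shape %||% c(64L, 64L, 64L),
    spacing = y$spacing %||% c(1, 1, 1)
  )
}

#' @rdname read_phantom_spec
#' @param spec a `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' The shipped phantom gallery
#'
#' Reads every phantom spec installed with the package: synthetic lesions
#' covering location/laterality, all reachable proportion bins, thin vs
#' thick vs solid enhancing margins, focality classes, ependymal /
#' cortical / deep white matter contact, midline crossing per compartment,
#' satellites, and degenerate (empty, PS-only) lesions.
#'
#' @return named list of `phantom_spec` objects.
#' @export
phantom_gallery <- function() {
  dir <- system.file("extdata", "phantoms", package = "vasarify")
  files <- sort(list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE))
  specs <- lapply(files, read_phantom_spec)
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Generate paired rater tables with controllable disagreement
#'
#' Rater A draws each feature's code uniformly from the feature's declared
#' non-"n/a" categories; rater B copies A and independently perturbs each
#' entry with the requested rate (one ordinal step up or down, clipped to
#' the category range). Expected agreement decreases monotonically in the
#' rate. Shared age/sex covariates are attached to both tables.
#'
#' @param n_cases number of cases.
#' @param rate scalar or per-feature named vector of perturbation
#'   probabilities in \[0, 1\].
#' @param seed RNG seed (caller's RNG state is preserved).
#' @param features feature ids to simulate (default: all derived features).
#' @return list of two rater tables `a` and `b` (see [as_rater_table()]
#'   for the format).
#' @export
make_rater_tables <- function(n_cases, rate = 0.2, seed = 1L,
                              features = names(vasari_feature_levels())) {
  levs <- vasari_feature_levels()[features]
  if (any(rate < 0 | rate > 1)) stop_config("rates must lie in [0, 1]")
  rates <- if (length(rate) == 1L) setNames(rep(rate, length(features)), features)
           else rate[features]
  withr::local_seed(as.integer(seed))
  case_id <- sprintf("case_%03d", seq_len(n_cases))
  cov <- tibble(case_id = case_id,
                age = sample(20:89, n_cases, replace = TRUE),
                sex = sample(c("male", "female"), n_cases, replace = TRUE))
  rows_a <- list(); rows_b <- list()
  for (ft in features) {
    lv <- levs[[ft]]
    valid <- which(lv != "n/a") - 1L          # 0-based codes
    a <- sample(valid, n_cases, replace = TRUE)
    step <- sample(c(-1L, 1L), n_cases, replace = TRUE)
    hit <- runif(n_cases) < rates[[ft]]
    b <- ifelse(hit, pmin(pmax(a + step, min(valid)), max(valid)), a)
    rows_a[[ft]] <- tibble(case_id = case_id, rater_id = "rater_a",
                           feature_id = ft, code = as.integer(a))
    rows_b[[ft]] <- tibble(case_id = case_id, rater_id = "rater_b",
                           feature_id = ft, code = as.integer(b))
  }
  list(a = left_join(dplyr::bind_rows(rows_a), cov, by = "case_id"),
       b = left_join(dplyr::bind_rows(rows_b), cov, by = "case_id"))
}

#' Simulate a survival cohort from a stated linear model
#'
#' Draws a synthetic encoded-feature design and generates overall survival
#' as `intercept + X beta + N(0, noise_sd)`, truncated at zero. Predictors
#' named like boolean features (f19 ... f24) are Bernoulli(0.5); other
#' feature-like names are uniform integer scores 0-4; anything else is
#' standard normal. The generating coefficients are returned so recovery
#' can be tested.
#'
#' @param n cohort size; must exceed the number of predictors.
#' @param coefficients named vector; the `"(Intercept)"` entry (default 0
#'   if absent) plus one entry per predictor.
#' @param noise_sd Gaussian noise SD in days.
#' @param seed RNG seed.
#' @return list with `data` (tibble: `os_days` + predictors), `beta`
#'   (generating coefficients) and `noise_sd`.
#' @export
make_survival_cohort <- function(n, coefficients, noise_sd = 0, seed = 1L) {
  beta <- coefficients
  pred <- setdiff(names(beta), "(Intercept)")
  if (!length(pred)) stop_config("coefficients must name at least one predictor")
  if (n <= length(pred))
    stop_config("cohort size (%d) must exceed the number of predictors (%d)",
                n, length(pred))
  intercept <- if ("(Intercept)" %in% names(beta)) beta[["(Intercept)"]] else 0
  withr::local_seed(as.integer(seed))
  X <- purrr::map_dfc(setNames(pred, pred), function(nm) {
    if (grepl("^f(19|2[0-4])$", nm)) rbinom(n, 1, 0.5)
    else if (grepl("^f[0-9]", nm)) sample(0:4, n, replace = TRUE)
    else rnorm(n)
  })
  os <- intercept + as.matrix(X) %*% beta[pred] + rnorm(n, 0, noise_sd)
  data <- dplyr::bind_cols(tibble(os_days = pmax(as.numeric(os), 0)), X)
  list(data = data, beta = beta, noise_sd = noise_sd)
}
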