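# Synthetic multimodal brain phantom: an ellipsoidal "brain" containing
# three concentric tumor spheres (whole > core > enhancing), imaged in four
# modalities as per-tissue mean intensities plus i.i.d. Gaussian noise.
# Voxel classes: 0 healthy/background, 1 necrotic core, 2 edema, 3 enhancing.

#' Default per-(modality, tissue) mean intensities
#'
#' Rows are modalities (t1, t1ce, t2, flair), columns tissue classes
#' (healthy, core, edema, enhancing).  Arbitrary units, chosen so that the
#' clinically expected contrasts hold: edema is brighter than healthy brain
#' on FLAIR, and enhancing tumor is brighter than necrotic core on T1ce.
#'
#' @return 4x4 numeric matrix with dimnames.
#' @export
default_tissue_means <- function() {
  m <- rbind(
    t1    = c(100,  60,  80,  90),
    t1ce  = c(100,  70,  85, 160),
    t2    = c(100, 130, 140, 120),
    flair = c(100, 110, 150, 120)
  )
  colnames(m) <- c("healthy", "core", "edema", "enhancing")
  m
}

#' Specification of a synthetic brain phantom
#'
#' @param grid_shape integer(3), voxels per axis (x, y, axial z).
#' @param brain_radius_frac fraction of each grid dimension used as the
#'   brain ellipsoid semi-axis.
#' @param tumor_center numeric(3) voxel coordinates (1-based array indices);
#'   default is the grid center.
#' @param region_radii numeric(3), strictly decreasing sphere radii in
#'   voxels for (whole, core, enhancing).
#' @param tissue_means 4x4 matrix of per-(modality, tissue) mean
#'   intensities; see [default_tissue_means()].
#' @param noise_sd standard deviation of the additive Gaussian intensity
#'   noise (same units as `tissue_means`).
#' @param seed integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 16L),
                         brain_radius_frac = 0.45,
                         tumor_center = NULL,
                         region_radii = c(6, 4, 2.5),
                         tissue_means = default_tissue_means(),
                         noise_sd = 5,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    validation_error("grid_shape must be three integers >= 4")
  if (is.null(tumor_center)) tumor_center <- (grid_shape + 1) / 2
  if (length(tumor_center) != 3L)
    validation_error("tumor_center must have three coordinates")
  if (length(region_radii) != 3L || any(region_radii <= 0) ||
      any(diff(region_radii) >= 0))
    validation_error(
      "region_radii must be three strictly decreasing positive radii (whole > core > enhancing)")
  stopifnot_scalar_number(brain_radius_frac, "brain_radius_frac", positive = TRUE)
  stopifnot_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) validation_error("noise_sd must be >= 0")
  if (!is.matrix(tissue_means) || !identical(dim(tissue_means), c(4L, 4L)))
    validation_error("tissue_means must be a 4x4 (modality x tissue) matrix")
  # largest tumor sphere must fit inside the brain ellipsoid
  semi <- brain_radius_frac * grid_shape
  ctr <- (grid_shape + 1) / 2
  d <- sqrt(sum(((tumor_center - ctr) / semi)^2))
  if (d + max(region_radii) / min(semi) > 1)
    validation_error("tumor sphere of largest radius does not fit inside the brain ellipsoid")
  structure(list(
    grid_shape = grid_shape, brain_radius_frac = brain_radius_frac,
    tumor_center = as.numeric(tumor_center),
    region_radii = as.numeric(region_radii),
    tissue_means = tissue_means, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# squared normalized radius of every voxel w.r.t. a center and (an)isotropic
# semi-axes; returns an array of the grid shape
.grid_dist2 <- function(shape, center, semi) {
  ax <- ((seq_len(shape[1]) - center[1]) / semi[1])^2
  ay <- ((seq_len(shape[2]) - center[2]) / semi[2])^2
  az <- ((seq_len(shape[3]) - center[3]) / semi[3])^2
  outer(outer(ax, ay, `+`), az, `+`)
}

#' Generate one synthetic BraTS-like case
#'
#' Builds the nested label mask (enhancing inside core inside whole tumor,
#' all inside an ellipsoidal brain) and renders the four modality volumes as
#' tissue means plus Gaussian noise.  Voxels outside the brain are exactly 0
#' in every modality.
#'
#' @param spec a [phantom_spec()].
#' @param case_id character identifier stored in the bundle.
#' @return A `case_bundle`: list with `modalities` (named list of 3D arrays
#'   t1, t1ce, t2, flair), `mask` (integer 3D array, labels 0..3), `affine`
#'   (4x4), `case_id`.
#' @export
generate_phantom <- function(spec, case_id = "phantom") {
  if (!inherits(spec, "phantom_spec"))
    validation_error("spec must be a phantom_spec")
  shape <- spec$grid_shape
  semi <- spec$brain_radius_frac * shape
  ctr <- (shape + 1) / 2
  brain <- .grid_dist2(shape, ctr, semi) <= 1

  r <- spec$region_radii
  d2 <- .grid_dist2(shape, spec$tumor_center, c(1, 1, 1))  # voxel units
  mask <- array(0L, dim = shape)
  mask[brain & (d2 <= r[1]^2)] <- 2L   # edema shell (whole tumor sphere)
  mask[brain & (d2 <= r[2]^2)] <- 1L   # necrotic core
  mask[brain & (d2 <= r[3]^2)] <- 3L   # enhancing center

  set.seed(spec$seed)
  modalities <- vector("list", 4L)
  names(modalities) <- MODALITIES
  # tissue column lookup: class 0 -> healthy, 1 -> core, 2 -> edema, 3 -> enhancing
  for (m in seq_along(MODALITIES)) {
    vol <- array(0, dim = shape)
    means <- spec$tissue_means[m, ]
    vol[brain] <- means[mask[brain] + 1L]
    if (spec$noise_sd > 0)
      vol[brain] <- vol[brain] + rnorm(sum(brain), 0, spec$noise_sd)
    modalities[[m]] <- vol
  }
  new_case_bundle(modalities, mask, diag(4), case_id)
}

new_case_bundle <- function(modalities, mask, affine, case_id) {
  shapes <- vapply(modalities, function(v) paste(dim(v), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    format_error("all modality volumes must share one shape")
  if (!is.null(mask) && !identical(dim(mask), dim(modalities[[1]])))
    format_error("mask shape must match the modality volumes")
  if (abs(det(affine)) < .Machine$double.eps)
    format_error("affine must be invertible")
  structure(list(modalities = modalities, mask = mask, affine = affine,
                 case_id = case_id),
            class = "case_bundle")
}

#' @export
print.case_bundle <- function(x, ...) {
  cat(sprintf("<case_bundle '%s'> %s voxels, mask: %s\n", x$case_id,
              paste(dim(x$modalities[[1]]), collapse = "x"),
              if (is.null(x$mask)) "absent" else "present"))
  invisible(x)
}

#' Generate a cohort of phantoms with jittered tumor geometry
#'
#' Tumor centers are jittered uniformly by up to `center_jitter` voxels per
#' axis and radii by up to `radius_jitter` voxels (nesting and fit are
#' re-validated), each case receiving its own noise seed derived from
#' `seed`.
#'
#' @param n number of cases (>= 1).
#' @param base_spec the [phantom_spec()] to jitter.
#' @param seed cohort RNG seed.
#' @param center_jitter,radius_jitter maximum absolute jitter, voxels.
#' @return list of `case_bundle`s with ids `case001`, `case002`, ...
#' @export
phantom_cohort <- function(n, base_spec = phantom_spec(), seed = 1L,
                           center_jitter = c(2, 2, 0.5), radius_jitter = 0.5) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    validation_error("n must be >= 1")
  n <- as.integer(n)
  center_jitter <- rep_len(center_jitter, 3L)
  set.seed(as.integer(seed))
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    jc <- runif(3, -center_jitter, center_jitter)
    jr <- runif(1, -radius_jitter, radius_jitter)
    seed_i <- sample.int(.Machine$integer.max - 1L, 1L)
    center <- base_spec$tumor_center + jc
    radii <- pmax(base_spec$region_radii + jr, 0.5)
    # keep the jittered center but scale the radii so the tumor still
    # fits inside the brain ellipsoid
    semi <- base_spec$brain_radius_frac * base_spec$grid_shape
    ctr <- (base_spec$grid_shape + 1) / 2
    d <- sqrt(sum(((center - ctr) / semi)^2))
    rmax <- max((1 - d) * min(semi) * 0.98, 1.5)
    if (radii[1] > rmax) radii <- radii * rmax / radii[1]
    sp <- phantom_spec(grid_shape = base_spec$grid_shape,
                       brain_radius_frac = base_spec$brain_radius_frac,
                       tumor_center = center, region_radii = radii,
                       tissue_means = base_spec$tissue_means,
                       noise_sd = base_spec$noise_sd, seed = seed_i)
    cases[[i]] <- generate_phantom(sp, case_id = sprintf("case%03d", i))
  }
  cases
}
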