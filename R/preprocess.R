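# Intensity normalization and class-balanced axial patch extraction.
# "Patch" here means a full size x size axial slice window (center-cropped
# or zero-padded in-plane); tumor_fraction constrains how many sampled
# slices must contain at least one tumor voxel, countering the heavy
# background/tumor class imbalance of BraTS-style data.

#' Z-score normalize a volume over its nonzero support
#'
#' Background voxels (exact zeros) are treated as non-brain and left at 0;
#' the remaining voxels are shifted/scaled to mean 0, sd 1 (population sd).
#'
#' @param volume numeric array.
#' @return array of the same shape.
#' @export
zscore_normalize <- function(volume) {
  nz <- volume != 0
  n <- sum(nz)
  if (n < 2L)
    validation_error("zscore_normalize needs >= 2 nonzero voxels")
  v <- volume[nz]
  mu <- mean(v)
  sdv <- sqrt(mean((v - mu)^2))   # population convention
  if (sdv == 0)
    validation_error("constant nonzero region: variance is zero")
  out <- volume
  out[nz] <- (v - mu) / sdv
  out
}

# center-crop or zero-pad a 2D slice (H x W x C array) to size x size
.fit_plane <- function(x, size) {
  d <- dim(x)
  out <- array(0, dim = c(size, size, d[3]))
  # source range
  src1 <- max(1L, floor((d[1] - size) / 2) + 1L); src1e <- min(d[1], src1 + size - 1L)
  src2 <- max(1L, floor((d[2] - size) / 2) + 1L); src2e <- min(d[2], src2 + size - 1L)
  n1 <- src1e - src1 + 1L; n2 <- src2e - src2 + 1L
  dst1 <- floor((size - n1) / 2) + 1L
  dst2 <- floor((size - n2) / 2) + 1L
  out[dst1:(dst1 + n1 - 1L), dst2:(dst2 + n2 - 1L), ] <-
    x[src1:src1e, src2:src2e, , drop = FALSE]
  out
}

#' Extract class-balanced axial training patches from a case
#'
#' Each modality volume is z-score normalized (over nonzero voxels), axial
#' slices are center-cropped/zero-padded to `size` x `size`, and `n_patches`
#' slices are sampled such that at least `ceiling(tumor_fraction *
#' n_patches)` contain at least one tumor voxel.  Sampling is without
#' replacement where possible and reproducible under `seed`.
#'
#' @param case a `case_bundle` with mask present.
#' @param size patch edge length in pixels (default 224).
#' @param tumor_fraction minimum fraction of tumor-bearing patches, in
#'   \[0, 1\] (default 0.5).
#' @param n_patches number of patches; default = number of axial slices.
#' @param seed RNG seed.
#' @param normalize z-score the modalities first (default TRUE).
#' @return a `patch_set`: list with `images` (list of size x size x 4
#'   arrays, channels t1, t1ce, t2, flair), `masks` (list of size x size
#'   integer matrices), `provenance` (data.frame case_id, axial 0-based).
#' @export
extract_patches <- function(case, size = 224L, tumor_fraction = 0.5,
                            n_patches = NULL, seed = 1L, normalize = TRUE) {
  if (!inherits(case, "case_bundle")) validation_error("case must be a case_bundle")
  if (is.null(case$mask)) validation_error("case mask is required for patch extraction")
  if (tumor_fraction < 0 || tumor_fraction > 1)
    validation_error("tumor_fraction must be in [0, 1]")
  shape <- dim(case$mask)
  nslices <- shape[3]
  if (is.null(n_patches)) n_patches <- nslices
  size <- as.integer(size)

  vols <- case$modalities
  if (normalize) vols <- lapply(vols, zscore_normalize)

  tumor_slices <- which(apply(case$mask > 0, 3, any))          # 1-based
  need_tumor <- ceiling(tumor_fraction * n_patches)
  if (need_tumor > 0 && length(tumor_slices) == 0L)
    data_error("tumor_fraction > 0 but the case has no tumor voxels")

  set.seed(as.integer(seed))
  # sample() quirk guard: sample(5, 2) would sample from 1:5
  pick_n <- function(pool, k) {
    if (k <= 0L) return(integer(0))
    if (length(pool) == 1L) return(rep(pool, k))
    if (length(pool) >= k) sample(pool, k) else sample(pool, k, replace = TRUE)
  }
  chosen <- c(pick_n(tumor_slices, need_tumor),
              pick_n(seq_len(nslices), n_patches - need_tumor))

  images <- vector("list", length(chosen))
  masks <- vector("list", length(chosen))
  for (i in seq_along(chosen)) {
    z <- chosen[i]
    sl <- array(0, dim = c(shape[1], shape[2], 4L))
    for (m in seq_along(MODALITIES)) sl[, , m] <- vols[[m]][, , z]
    images[[i]] <- .fit_plane(sl, size)
    mk <- .fit_plane(array(case$mask[, , z], dim = c(shape[1], shape[2], 1L)), size)
    masks[[i]] <- matrix(as.integer(mk[, , 1]), size, size)
  }
  structure(list(
    images = images, masks = masks,
    provenance = data.frame(case_id = case$case_id, axial = chosen - 1L)
  ), class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of %s, %d with tumor\n",
              length(x$images),
              paste(dim(x$images[[1]])[1:2], collapse = "x"),
              sum(vapply(x$masks, function(m) any(m > 0), TRUE))))
  invisible(x)
}
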