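# Inference: slice-wise forward pass, argmax labeling, optional per-class
# MRF polish, and recombination into a 0..3 label volume.

# shared crop/pad index bookkeeping with .fit_plane
.fit_indices <- function(d, size) {
  src1 <- max(1L, floor((d - size) / 2) + 1L)
  src1e <- min(d, src1 + size - 1L)
  n <- src1e - src1 + 1L
  dst1 <- floor((size - n) / 2) + 1L
  list(src = src1:src1e, dst = dst1:(dst1 + n - 1L))
}

#' Predict a label mask for one case
#'
#' Each axial slice is normalized (per-modality z-score over the volume's
#' nonzero voxels), center-cropped/zero-padded to the network input size,
#' passed through the network (inference batch statistics), and labeled by
#' per-pixel argmax.  With `polish = TRUE`, each tumor class's binary map
#' is converted to a bipolar mask, optionally noise-injected, relaxed by
#' ICM under `mrf`, and the polished maps are recombined by priority
#' enhancing > core > edema; pixels claimed by no polished map become
#' background.
#'
#' @param net a trained `attnseg_net`.
#' @param case a `case_bundle`.
#' @param polish run the MRF polish (default TRUE).
#' @param mrf an [mrf_config()] (default eta = 15, diag neighborhood).
#' @param inject_noise_first add Gaussian noise before ICM (the
#'   training-time regularizer replayed at inference; default FALSE).
#' @param batch_size slices per forward pass.
#' @return integer 3D array of labels in \{0, 1, 2, 3\}, same shape as the
#'   case volumes.
#' @export
predict_segmentation <- function(net, case, polish = TRUE,
                                 mrf = mrf_config(),
                                 inject_noise_first = FALSE,
                                 batch_size = 8L) {
  if (!inherits(net, "attnseg_net")) contract_error("net must be an attnseg_net")
  if (!inherits(case, "case_bundle")) contract_error("case must be a case_bundle")
  shape <- dim(case$modalities[[1]])
  size <- net$config$input_size
  if (length(case$modalities) != net$config$in_channels)
    contract_error("modality count does not match the network's input channels")
  vols <- lapply(case$modalities, zscore_normalize)

  ix <- .fit_indices(shape[1], size)
  iy <- .fit_indices(shape[2], size)
  slices <- vector("list", shape[3])
  for (z in seq_len(shape[3])) {
    sl <- array(0, dim = c(shape[1], shape[2], 4L))
    for (m in seq_along(vols)) sl[, , m] <- vols[[m]][, , z]
    slices[[z]] <- .fit_plane(sl, size)
  }
  out <- array(0L, dim = shape)
  for (start in seq(1L, shape[3], by = batch_size)) {
    zs <- start:min(start + batch_size - 1L, shape[3])
    probs <- segmenter_forward(net, slices[zs], training = FALSE)
    for (k in seq_along(zs)) {
      p <- probs[[k]]
      lab <- matrix(max.col(matrix(p, size * size, dim(p)[3])) - 1L, size, size)
      if (polish) lab <- .polish_labels(lab, mrf, inject_noise_first)
      out[ix$src, iy$src, zs[k]] <- lab[ix$dst, iy$dst]
    }
  }
  out
}

# per-class MRF polish of one label slice; recombine by priority
# enhancing (3) > core (1) > edema (2)
.polish_labels <- function(lab, mrf, inject_noise_first = FALSE) {
  polished <- list()
  for (cls in c(3L, 1L, 2L)) {
    bip <- matrix(ifelse(lab == cls, 1L, -1L), nrow(lab), ncol(lab))
    if (inject_noise_first)
      bip <- inject_noise(bip, mrf$sigma, seed = mrf$seed + cls)
    polished[[as.character(cls)]] <- icm_denoise(bip, mrf)
  }
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (cls in c(2L, 1L, 3L))           # lowest priority first, overwrite up
    out[polished[[as.character(cls)]] > 0] <- cls
  out
}

#' Evaluate predicted masks against ground truth
#'
#' Directories are matched by case id: every `<id>_seg.nii[.gz]` (or
#' `<id>_pred.nii[.gz]`) in `pred_dir` must have a `<id>_seg.nii[.gz]`
#' counterpart in `truth_dir`.  In-memory lists of label arrays (named by
#' case id) are also accepted.
#'
#' @param pred predictions: directory path or named list of label arrays.
#' @param truth ground truth: directory path or named list of label arrays.
#' @param csv,json optional output file paths.
#' @return data.frame: per-case, per-region metrics plus `cohort_mean`
#'   rows averaging each region over cases.
#' @export
evaluate_cases <- function(pred, truth, csv = NULL, json = NULL) {
  load_dir <- function(d) {
    files <- list.files(d, pattern = "_(seg|pred)\\.nii(\\.gz)?$",
                        full.names = TRUE)
    ids <- sub("_(seg|pred)\\.nii(\\.gz)?$", "", basename(files))
    out <- lapply(files, function(f) {
      v <- read_nifti(f)$data
      remap_labels(v)
    })
    names(out) <- ids
    out
  }
  if (is.character(pred)) pred <- load_dir(pred)
  if (is.character(truth)) truth <- load_dir(truth)
  missing_t <- setdiff(names(pred), names(truth))
  missing_p <- setdiff(names(truth), names(pred))
  if (length(missing_t) || length(missing_p))
    data_error(sprintf(
      "unmatched case ids -- missing truth: [%s]; missing prediction: [%s]",
      paste(missing_t, collapse = ", "), paste(missing_p, collapse = ", ")))
  rows <- lapply(names(pred), function(id) {
    r <- metrics_report(pred[[id]], truth[[id]])
    cbind(case_id = id, r)
  })
  tab <- do.call(rbind, rows)
  means <- do.call(rbind, lapply(split(tab, tab$region), function(g) {
    data.frame(case_id = "cohort_mean", region = g$region[1],
               dsc = mean(g$dsc), sensitivity = mean(g$sensitivity),
               specificity = mean(g$specificity),
               precision = mean(g$precision), accuracy = mean(g$accuracy))
  }))
  tab <- rbind(tab, means)
  rownames(tab) <- NULL
  if (!is.null(csv)) write.csv(tab, csv, row.names = FALSE)
  if (!is.null(json)) jsonlite::write_json(tab, json, dataframe = "rows")
  tab
}
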