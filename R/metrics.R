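# Dice similarity coefficient, confusion-matrix metrics, and the BraTS
# region composites: WT (whole tumor) = labels {1,2,3}, TC (tumor core) =
# {1,3}, ET (enhancing tumor) = {3}, nested ET <= TC <= WT.

#' Region composite masks from a label volume
#'
#' @param labels integer array with voxel labels in \{0, 1, 2, 3\}
#'   (0 background, 1 necrotic core, 2 edema, 3 enhancing).
#' @return list of logical arrays `ET`, `TC`, `WT`.
#' @export
region_masks <- function(labels) {
  u <- unique(as.vector(labels))
  if (!all(u %in% 0:3))
    validation_error(sprintf("labels outside {0..3}: %s",
                             paste(sort(setdiff(u, 0:3)), collapse = ", ")))
  list(ET = labels == 3, TC = labels == 1 | labels == 3, WT = labels > 0)
}

#' Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)`.  Two empty masks agree perfectly
#' (DSC = 1); an empty vs a nonempty mask scores 0.
#'
#' @param a,b logical/0-1 masks of the same shape.
#' @return scalar in \[0, 1\].
#' @export
dsc <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    contract_error("masks must share a shape")
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Confusion counts and derived segmentation metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP),
#' accuracy (TP+TN)/total; a zero-denominator ratio is reported as NA
#' rather than 0.  The DSC recomputed from the counts, `2TP/(2TP+FN+FP)`,
#' is included and always equals the set-overlap definition.
#'
#' @param pred,truth logical/0-1 masks of the same shape.
#' @return list with `counts` (TP, FP, TN, FN), `sensitivity`,
#'   `specificity`, `precision`, `accuracy`, `dsc`.
#' @export
confusion_metrics <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    contract_error("masks must share a shape")
  p <- as.logical(pred); t <- as.logical(truth)
  TP <- sum(p & t); FP <- sum(p & !t); FN <- sum(!p & t); TN <- sum(!p & !t)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(
    counts = c(TP = TP, FP = FP, TN = TN, FN = FN),
    sensitivity = ratio(TP, TP + FN),
    specificity = ratio(TN, TN + FP),
    precision = ratio(TP, TP + FP),
    accuracy = ratio(TP + TN, TP + FP + TN + FN),
    dsc = if (2 * TP + FN + FP == 0) 1 else 2 * TP / (2 * TP + FN + FP)
  )
}

#' Full per-region metrics report for one predicted label volume
#'
#' @param pred,truth integer label arrays over \{0..3\} of the same shape.
#' @param per_slice also compute a slice-mean DSC variant (default FALSE;
#'   the headline numbers are whole-volume).
#' @return data.frame with one row per region (ET, TC, WT).
#' @export
metrics_report <- function(pred, truth, per_slice = FALSE) {
  rp <- region_masks(pred); rt <- region_masks(truth)
  rows <- lapply(names(rp), function(rg) {
    cm <- confusion_metrics(rp[[rg]], rt[[rg]])
    out <- data.frame(region = rg, dsc = dsc(rp[[rg]], rt[[rg]]),
                      sensitivity = cm$sensitivity,
                      specificity = cm$specificity,
                      precision = cm$precision, accuracy = cm$accuracy)
    if (per_slice && length(dim(pred)) == 3L) {
      out$dsc_slice_mean <- mean(vapply(seq_len(dim(pred)[3]), function(z)
        dsc(rp[[rg]][, , z], rt[[rg]][, , z]), 0))
    }
    out
  })
  do.call(rbind, rows)
}
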