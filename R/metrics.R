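#' One-vs-rest confusion counts for a label
#'
#' Voxel counts treating the given label as positive class: TP (voxels
#' correctly segmented as the muscle), FP, FN, TN.
#'
#' @param pred,gt Geometry-matched [label_mask()] objects (predicted and
#'   ground truth).
#' @param label Label ID (1..6).
#' @return Named numeric vector `c(TP, FP, FN, TN)`.
#' @export
confusion_counts <- function(pred, gt, label) {
  if (!same_geometry(pred, gt)) stopf("prediction/ground-truth geometry mismatch")
  p <- pred$data == label
  g <- gt$data == label
  tp <- sum(p & g)
  c(TP = tp, FP = sum(p) - tp, FN = sum(g) - tp,
    TN = length(p) - sum(p) - sum(g) + tp)
}

#' Seven-metric segmentation accuracy report
#'
#' For each muscle label computes the Sorensen-Dice index
#' `2|SM n GT| / (|SM| + |GT|)`, Jaccard index, conformity coefficient
#' `1 - (FP + FN)/TP`, true positive rate, true negative rate, positive
#' predictive value, and volume ratio `SM/GT`, plus the absolute volumes of
#' both masks in ml (voxel count x voxel volume / 1000). Metrics are computed
#' on whole volumes.
#'
#' Degenerate cases are flagged in the `flag` column and reported as `NA`
#' where undefined: if both masks are empty for a label all overlap metrics
#' are 1; if only the ground truth is empty, Dice is 0 and the volume ratio
#' undefined (`gt_empty`); conformity is undefined when TP = 0 with any
#' positives (`tp_zero`).
#'
#' @param pred,gt Geometry-matched [label_mask()] objects.
#' @param spacing Voxel spacing in mm; defaults to the masks' spacing.
#' @param labels Label IDs to evaluate (default 1:6).
#' @param subject Optional subject ID recorded in the output.
#' @return Data frame with one row per label: `subject`, `label`, `muscle`,
#'   `dice`, `jaccard`, `conformity`, `tpr`, `tnr`, `ppv`, `volume_ratio`,
#'   `volume_sm_ml`, `volume_gt_ml`, `flag`.
#' @export
compute_metrics <- function(pred, gt, spacing = NULL, labels = 1:6, subject = NA) {
  if (!same_geometry(pred, gt)) stopf("prediction/ground-truth geometry mismatch")
  if (is.null(spacing)) spacing <- gt$spacing
  vox_ml <- prod(spacing) / 1000
  rows <- lapply(labels, function(lab) {
    cc <- confusion_counts(pred, gt, lab)
    tp <- cc["TP"]; fp <- cc["FP"]; fn <- cc["FN"]; tn <- cc["TN"]
    nsm <- tp + fp; ngt <- tp + fn
    flag <- ""
    if (nsm == 0 && ngt == 0) {
      dice <- jacc <- conf <- tpr <- ppv <- vr <- 1
      flag <- "both_empty"
    } else {
      dice <- 2 * tp / (nsm + ngt)
      jacc <- tp / (nsm + ngt - tp)
      conf <- if (tp > 0) 1 - (fp + fn) / tp else NA_real_
      if (tp == 0) flag <- "tp_zero"
      tpr <- if (ngt > 0) tp / ngt else 1
      ppv <- if (nsm > 0) tp / nsm else 1
      vr <- if (ngt > 0) nsm / ngt else NA_real_
      if (ngt == 0) flag <- "gt_empty"
    }
    tnr <- if (tn + fp > 0) tn / (tn + fp) else 1
    data.frame(subject = subject, label = lab,
               muscle = lab_name(lab), dice = unname(dice),
               jaccard = unname(jacc), conformity = unname(conf),
               tpr = unname(tpr), tnr = unname(tnr), ppv = unname(ppv),
               volume_ratio = unname(vr),
               volume_sm_ml = unname(nsm * vox_ml),
               volume_gt_ml = unname(ngt * vox_ml),
               flag = flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate predictions over a cohort
#'
#' Runs [predict_volume()] + [compute_metrics()] for each subject of a
#' manifest (or list of pairs) and binds the per-subject reports.
#'
#' @param checkpoint Trained checkpoint.
#' @param data Manifest data frame / CSV path or list of pairs.
#' @return Combined metric report data frame.
#' @export
evaluate_cohort <- function(checkpoint, data) {
  pairs <- if (is.list(data) && !is.data.frame(data)) data else load_cohort(data)
  ids <- names(pairs) %||% as.character(seq_along(pairs))
  do.call(rbind, lapply(seq_along(pairs), function(i) {
    pred <- predict_volume(checkpoint, pairs[[i]]$image)
    compute_metrics(pred, pairs[[i]]$mask, subject = ids[i])
  }))
}
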