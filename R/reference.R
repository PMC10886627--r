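# Reported test-set metrics of the clinical SRS/SRH oral-tissue CNN study
# that this package re-implements.  The per-class precision/recall/F1
# table and the squamous/tumor confusion counts ship as plain-text data so
# that every derived summary statistic (balanced accuracy, harmonic-mean
# F1, misclassification percentages) can be recomputed from the primary
# printed values rather than asserted.

#' Reported per-class test metrics of the reference study
#'
#' @return Data frame with columns `class`, `modality` (`"srs"` on the raw
#'   two-channel images, `"srh"` on the virtual-H&E renders), `precision`,
#'   `recall`, `f1`, `n_tiles`.
#' @export
reference_metrics <- function() {
  read.csv(system.file("extdata", "reference_test_metrics.csv",
                       package = "ramanhisto"),
           stringsAsFactors = FALSE)
}

#' Reported squamous/tumor confusion counts of the reference study
#'
#' @return Data frame with columns `modality`, `true_class`, `pred_class`,
#'   `count`, `true_total`.
#' @export
reference_confusion_counts <- function() {
  read.csv(system.file("extdata", "reference_confusion_counts.csv",
                       package = "ramanhisto"),
           stringsAsFactors = FALSE)
}

#' Recompute the reference study's summary statistics from its primary
#' printed values
#'
#' Balanced accuracy is recomputed as the mean of the six per-class
#' recalls; F1 scores are recomputed as harmonic means of the printed
#' precision/recall pairs; misclassification percentages are recomputed
#' from the printed confusion counts.  (Printed F1 cells that are not
#' recoverable from the rounded precision/recall pair -- a pre-rounding
#' artifact, e.g. stroma -- are returned too but should be compared with
#' care.)
#'
#' @return List with `balanced_accuracy` (named by modality), `f1` (data
#'   frame of recomputed and reported F1 per class and modality) and
#'   `misclassification_pct` (data frame with recomputed whole-percent
#'   rates).
#' @export
recompute_reference_summary <- function() {
  m <- reference_metrics()
  ba <- tapply(m$recall, m$modality, mean)
  f1 <- data.frame(class = m$class, modality = m$modality,
                   f1_recomputed = f1_score(m$precision, m$recall),
                   f1_reported = m$f1)
  cc <- reference_confusion_counts()
  cc$pct <- round(100 * cc$count / cc$true_total)
  list(balanced_accuracy = ba, f1 = f1, misclassification_pct = cc)
}
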