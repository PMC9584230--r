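# Published full-scale benchmark values, used as inputs for reconstruction
# checks (analogous AUC, F1 identities, mean F1-CV) — not produced by this
# package's training code.

#' Published full-scale operating points of the batch-control schemes
#'
#' Mean +/- sd over eight 60,000-step trainings of the UNet model on the
#' radiograph challenge data, evaluated on the balanced 229/229 test set, as
#' reported in the original full-scale benchmark. These serve as inputs for
#' the analogous ROC reconstruction and the metric identity checks; they are
#' not reproducible at desk scale.
#'
#' @return Data frame with one row per scheme (P100..P17, RAND) and columns
#'   `scheme, tpr_mean, tpr_sd, tnr_mean, tnr_sd, fpr_mean, fpr_sd, acc_mean,
#'   acc_sd, f1_mean, f1_sd, f1_cv`.
#' @export
referenceOperatingPoints <- function() {
  data.frame(
    scheme = c("P100", "P83", "P66", "P50", "P33", "P17", "RAND"),
    tpr_mean = c(0.93, 0.80, 0.73, 0.67, 0.60, 0.44, 0.46),
    tpr_sd = c(0.01, 0.03, 0.05, 0.03, 0.04, 0.03, 0.09),
    tnr_mean = c(0.23, 0.75, 0.83, 0.88, 0.93, 0.99, 0.98),
    tnr_sd = c(0.05, 0.03, 0.05, 0.03, 0.03, 0.00, 0.01),
    fpr_mean = c(0.77, 0.25, 0.17, 0.12, 0.07, 0.01, 0.02),
    fpr_sd = c(0.05, 0.03, 0.05, 0.03, 0.03, 0.00, 0.01),
    acc_mean = c(0.58, 0.78, 0.78, 0.78, 0.77, 0.71, 0.72),
    acc_sd = c(0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.04),
    f1_mean = c(0.69, 0.78, 0.77, 0.75, 0.72, 0.60, 0.62),
    f1_sd = c(0.01, 0.01, 0.02, 0.01, 0.02, 0.03, 0.08),
    f1_cv = c(0.019, 0.012, 0.024, 0.011, 0.033, 0.043, 0.135),
    stringsAsFactors = FALSE)
}

#' Published training-set class counts
#'
#' Three-way class counts of the 24,684-image training split of the
#' radiograph challenge data (plus the balanced 229/229 test set). The
#' lung-opacity fraction, 5430/24684, is the 22% prevalence that makes RAND
#' batches average 22% positive.
#'
#' @return Named list with `train` (named vector of the three class counts),
#'   `testPerClass`, and `totalImages`.
#' @export
referenceTrainingCounts <- function() {
  list(train = c(lung_opacity = 5430, normal = 8194,
                 no_opacity_not_normal = 11060),
       testPerClass = 229,
       totalImages = 25684)
}
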