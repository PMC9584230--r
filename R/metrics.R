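#' Count confusion outcomes in an outcome table
#'
#' @param outcomes Outcome table from [adjudicateCases()] (or a character
#'   vector of `"TP"/"FP"/"TN"/"FN"`).
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @export
countOutcomes <- function(outcomes) {
  oc <- if (is.data.frame(outcomes)) outcomes$outcome else outcomes
  c(tp = sum(oc == "TP"), fp = sum(oc == "FP"),
    tn = sum(oc == "TN"), fn = sum(oc == "FN"))
}

#' Case-level classification metrics from confusion counts
#'
#' `tpr = tp/(tp+fn)` (sensitivity/recall), `tnr = tn/(tn+fp)` (specificity),
#' `fpr = fp/(fp+tn) = 1 - tnr`, `acc = (tp+tn)/total`, and
#' `f1 = 2 * prec * tpr / (prec + tpr)` with `prec = tp/(tp+fp)`; `f1 = 0`
#' when `tp = 0`.
#'
#' @param counts Named vector with `tp`, `fp`, `tn`, `fn` (as from
#'   [countOutcomes()]), or the `tp` count if the four are given separately.
#' @param fp,tn,fn Individual counts when `counts` is scalar.
#' @return One-row data frame with `tpr`, `tnr`, `fpr`, `acc`, `f1`.
#' @examples
#' computeMetrics(c(tp = 183, fp = 57, tn = 172, fn = 46))  # f1 ~ 0.78
#' @export
computeMetrics <- function(counts, fp = NULL, tn = NULL, fn = NULL) {
  if (!is.null(fp)) counts <- c(tp = counts, fp = fp, tn = tn, fn = fn)
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be non-negative", call. = FALSE)
  if (tp + fn == 0) stop("TPR undefined: no positive cases", call. = FALSE)
  if (fp + tn == 0) stop("TNR undefined: no negative cases", call. = FALSE)
  tpr <- tp / (tp + fn)
  tnr <- tn / (tn + fp)
  f1 <- if (tp == 0) 0 else {
    prec <- tp / (tp + fp)
    2 * prec * tpr / (prec + tpr)
  }
  data.frame(tpr = tpr, tnr = tnr, fpr = fp / (fp + tn),
             acc = (tp + tn) / (tp + fp + tn + fn), f1 = f1)
}

#' Reconstruct F1 from printed mean TPR/TNR on a balanced test set
#'
#' Converts the published mean rates back into counts on an `n`-per-class
#' balanced test set (rounding to whole cases) and recomputes F1.
#'
#' @param tpr,tnr Mean rates.
#' @param nPerClass Cases per class (default 229, the published test set).
#' @return The F1 score.
#' @export
f1FromRates <- function(tpr, tnr, nPerClass = 229) {
  tp <- round(tpr * nPerClass)
  tn <- round(tnr * nPerClass)
  computeMetrics(c(tp = tp, fp = nPerClass - tn, tn = tn,
                   fn = nPerClass - tp))$f1
}

#' Aggregate per-trial metrics
#'
#' Mean and sample standard deviation (n - 1 denominator) per metric over
#' independently trained trials, plus the coefficient of variation of the
#' F1-score, `f1_cv = sd(f1) / mean(f1)` — the stability measure of the batch
#' control method.
#'
#' @param trials Data frame with one row per trial and columns `tpr`, `tnr`,
#'   `fpr`, `acc`, `f1` (as from [computeMetrics()]).
#' @return List with `mean` and `sd` (named vectors), `f1_cv`, `n_trials`.
#' @export
aggregateTrials <- function(trials) {
  stopifnot(is.data.frame(trials))
  if (nrow(trials) < 2) stop("need >= 2 trials for sd and F1-CV", call. = FALSE)
  cols <- c("tpr", "tnr", "fpr", "acc", "f1")
  mu <- vapply(cols, function(cn) mean(trials[[cn]]), 0)
  sdev <- vapply(cols, function(cn) sd(trials[[cn]]), 0)
  if (mu[["f1"]] == 0) stop("F1-CV undefined: mean F1 is zero", call. = FALSE)
  list(mean = mu, sd = sdev, f1_cv = sdev[["f1"]] / mu[["f1"]],
       n_trials = nrow(trials))
}

#' Analogous ROC curve and trapezoidal AUC over scheme operating points
#'
#' Each batch scheme's aggregate (FPR, TPR) is one operating point; the curve
#' is the points sorted by FPR (ties by ascending TPR, exact duplicates
#' collapsed) with endpoints (0,0) and (1,1) prepended/appended, and the AUC
#' is the sum of trapezoid areas between consecutive points.
#'
#' @param points Data frame with columns `fpr` and `tpr`, all in `[0, 1]`.
#' @return List with `curve` (data frame of the full point sequence) and `auc`.
#' @examples
#' rocAuc(data.frame(fpr = c(0.77, 0.25, 0.17, 0.12, 0.07, 0.01),
#'                   tpr = c(0.93, 0.80, 0.73, 0.67, 0.60, 0.44)))$auc  # ~0.83
#' @export
rocAuc <- function(points) {
  stopifnot(is.data.frame(points), all(c("fpr", "tpr") %in% names(points)))
  if (any(points$fpr < 0 | points$fpr > 1 | points$tpr < 0 | points$tpr > 1))
    stop("operating points must lie in the unit square", call. = FALSE)
  pts <- points[order(points$fpr, points$tpr), c("fpr", "tpr")]
  pts <- rbind(data.frame(fpr = 0, tpr = 0), pts, data.frame(fpr = 1, tpr = 1))
  pts <- unique(pts)
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(curve = pts, auc = auc)
}

#' Aggregate a full multi-scheme, multi-trial run into a report
#'
#' Produces the benchmark-shaped report: one row per scheme with mean +/- sd
#' of TPR, TNR, FPR, ACC and F1 plus the F1-CV, and the analogous ROC over the
#' P-scheme (BCM) operating points. All trial outcome tables must cover the
#' same test ids. With a single trial, sd and F1-CV are reported as `NA`.
#'
#' @param outcomeTables Named list (by scheme) of lists of outcome tables
#'   (one per trial), each as returned by [adjudicateCases()].
#' @return List with `table` (data frame, one row per scheme), `trialMetrics`
#'   (per-scheme data frames), and `roc` (list from [rocAuc()], or `NULL` if
#'   fewer than one BCM scheme is present).
#' @export
evaluateRun <- function(outcomeTables) {
  stopifnot(is.list(outcomeTables), length(outcomeTables) > 0,
            !is.null(names(outcomeTables)))
  refIds <- NULL
  rows <- list()
  trialMetrics <- list()
  for (scheme in names(outcomeTables)) {
    trials <- outcomeTables[[scheme]]
    tm <- do.call(rbind, lapply(trials, function(tab) {
      ids <- sort(tab$id)
      if (is.null(refIds)) refIds <<- ids
      else if (!identical(ids, refIds))
        stop("trial outcome tables cover different test ids", call. = FALSE)
      computeMetrics(countOutcomes(tab))
    }))
    trialMetrics[[scheme]] <- tm
    if (nrow(tm) >= 2) {
      ag <- tryCatch(aggregateTrials(tm), error = function(e) {
        # degrade gracefully when F1-CV is undefined (mean F1 of zero)
        warning(sprintf("scheme %s: %s", scheme, conditionMessage(e)), call. = FALSE)
        cols <- c("tpr", "tnr", "fpr", "acc", "f1")
        list(mean = vapply(cols, function(cn) mean(tm[[cn]]), 0),
             sd = vapply(cols, function(cn) sd(tm[[cn]]), 0),
             f1_cv = NA_real_, n_trials = nrow(tm))
      })
      rows[[scheme]] <- data.frame(
        scheme = scheme, n_trials = ag$n_trials,
        tpr_mean = ag$mean[["tpr"]], tpr_sd = ag$sd[["tpr"]],
        tnr_mean = ag$mean[["tnr"]], tnr_sd = ag$sd[["tnr"]],
        fpr_mean = ag$mean[["fpr"]], fpr_sd = ag$sd[["fpr"]],
        acc_mean = ag$mean[["acc"]], acc_sd = ag$sd[["acc"]],
        f1_mean = ag$mean[["f1"]], f1_sd = ag$sd[["f1"]],
        f1_cv = ag$f1_cv, stringsAsFactors = FALSE)
    } else {
      rows[[scheme]] <- data.frame(
        scheme = scheme, n_trials = 1L,
        tpr_mean = tm$tpr, tpr_sd = NA_real_, tnr_mean = tm$tnr,
        tnr_sd = NA_real_, fpr_mean = tm$fpr, fpr_sd = NA_real_,
        acc_mean = tm$acc, acc_sd = NA_real_, f1_mean = tm$f1,
        f1_sd = NA_real_, f1_cv = NA_real_, stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  bcm <- table[table$scheme != "RAND", , drop = FALSE]
  roc <- if (nrow(bcm) >= 1)
    rocAuc(data.frame(fpr = bcm$fpr_mean, tpr = bcm$tpr_mean)) else NULL
  list(table = table, trialMetrics = trialMetrics, roc = roc)
}
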