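test_that("confusion metrics reproduce the published P83 operating point", {
  # counts implied by TPR 0.80 / TNR 0.75 on the 229/229 balanced test
  mt <- computeMetrics(c(tp = 183, fp = 57, tn = 172, fn = 46))
  expect_equal(round(mt$tpr, 2), 0.80)
  expect_equal(round(mt$tnr, 2), 0.75)
  expect_equal(round(mt$f1, 2), 0.78)
  expect_equal(round(f1FromRates(0.80, 0.75), 2), 0.78)
})

test_that("degenerate confusion counts behave", {
  perfect <- computeMetrics(c(tp = 50, fp = 0, tn = 50, fn = 0))
  expect_equal(unlist(perfect[c("tpr", "tnr", "acc", "f1")]),
               c(tpr = 1, tnr = 1, acc = 1, f1 = 1))
  expect_equal(perfect$fpr, 0)
  zero <- computeMetrics(c(tp = 0, fp = 3, tn = 47, fn = 50))
  expect_equal(zero$tpr, 0)
  expect_equal(zero$f1, 0)
  expect_error(computeMetrics(c(tp = 0, fp = 1, tn = 1, fn = 0)), "TPR undefined")
  expect_error(computeMetrics(c(tp = 1, fp = 0, tn = 0, fn = 1)), "TNR undefined")
})

test_that("metrics agree with a brute-force recount of random outcome tables", {
  withr::with_seed(5, {
    for (i in 1:20) {
      oc <- sample(c("TP", "FP", "TN", "FN"), 60, replace = TRUE,
                   prob = c(0.3, 0.2, 0.3, 0.2))
      tab <- data.frame(id = paste0("c", 1:60), outcome = oc)
      mt <- computeMetrics(countOutcomes(tab))
      tp <- sum(oc == "TP"); fp <- sum(oc == "FP")
      tn <- sum(oc == "TN"); fn <- sum(oc == "FN")
      if (tp + fn == 0 || fp + tn == 0) next
      expect_equal(mt$tpr, tp / (tp + fn))
      expect_equal(mt$fpr, 1 - mt$tnr)
      expect_equal(mt$acc, (tp + tn) / 60)
      if (tp > 0) {
        prec <- tp / (tp + fp)
        expect_equal(mt$f1, 2 * prec * mt$tpr / (prec + mt$tpr))
      }
      # balanced identity: acc = (tpr + tnr) / 2 when classes are balanced
      if (tp + fn == fp + tn)
        expect_equal(mt$acc, (mt$tpr + mt$tnr) / 2)
    }
  })
})

test_that("trial aggregation uses sample sd and the F1 coefficient of variation", {
  one <- computeMetrics(c(tp = 40, fp = 10, tn = 40, fn = 10))
  same <- do.call(rbind, replicate(8, one, simplify = FALSE))
  ag <- aggregateTrials(same)
  expect_equal(unname(ag$sd), rep(0, 5))
  expect_equal(ag$f1_cv, 0)
  expect_equal(ag$n_trials, 8)
  # direct ratio on synthetic f1 values centred at the published P83 row
  f1s <- c(0.77, 0.775, 0.78, 0.785, 0.79, 0.78, 0.77, 0.79)
  trials <- data.frame(tpr = 0.8, tnr = 0.75, fpr = 0.25, acc = 0.78, f1 = f1s)
  ag2 <- aggregateTrials(trials)
  expect_equal(ag2$f1_cv, sd(f1s) / mean(f1s))
  # same order of magnitude as the published P83 stability (sd 0.01, mean 0.78)
  expect_equal(round(0.01 / 0.78, 3), 0.013)
  expect_lt(abs(ag2$f1_cv - 0.0128), 0.01)
  # scale-free: multiplying all f1 by k > 0 leaves the CV unchanged
  trials2 <- trials; trials2$f1 <- trials$f1 * 0.37
  expect_equal(aggregateTrials(trials2)$f1_cv, ag2$f1_cv)
  expect_error(aggregateTrials(trials[1, , drop = FALSE]), ">= 2 trials")
  trials0 <- trials; trials0$f1 <- 0
  expect_error(aggregateTrials(trials0), "F1-CV undefined")
})

test_that("the analogous ROC handles canonical configurations", {
  expect_equal(rocAuc(data.frame(fpr = 0, tpr = 1))$auc, 1.0)
  diag <- data.frame(fpr = c(0.25, 0.5, 0.75), tpr = c(0.25, 0.5, 0.75))
  expect_equal(rocAuc(diag)$auc, 0.5)
  expect_error(rocAuc(data.frame(fpr = 1.2, tpr = 0.5)), "unit square")
})

test_that("the trapezoidal AUC matches an independent integrator and is monotone", {
  skip_if_not_installed("pracma")
  withr::with_seed(8, {
    for (i in 1:10) {
      pts <- data.frame(fpr = runif(6), tpr = runif(6))
      r <- rocAuc(pts)
      expect_equal(r$auc, pracma::trapz(r$curve$fpr, r$curve$tpr))
      # permutation invariance
      expect_equal(rocAuc(pts[sample(6), ])$auc, r$auc)
      # raising one point's tpr at fixed fpr never lowers the auc
      pts2 <- pts
      j <- sample(6, 1)
      pts2$tpr[j] <- min(1, pts2$tpr[j] + 0.2)
      expect_gte(rocAuc(pts2)$auc, r$auc - 1e-12)
    }
  })
})

test_that("outcomes built to the published P17 rates reproduce its report row", {
  # tp = round(0.44 * 229), tn = round(0.99 * 229) on the balanced test
  oc <- c(rep("TP", 101), rep("FN", 128), rep("TN", 227), rep("FP", 2))
  tab <- data.frame(id = paste0("c", seq_along(oc)), outcome = oc,
                    n_true_boxes = 0L, n_pred_boxes = 0L)
  rep <- evaluateRun(list(P17 = list(tab, tab)))
  expect_equal(round(rep$table$tpr_mean, 2), 0.44)
  expect_equal(round(rep$table$tnr_mean, 2), 0.99)
})

test_that("evaluateRun produces a benchmark-shaped report", {
  mkTab <- function(oc) data.frame(id = paste0("c", seq_along(oc)), outcome = oc,
                                   n_true_boxes = 0L, n_pred_boxes = 0L)
  ocA <- c(rep("TP", 8), rep("FN", 2), rep("TN", 9), rep("FP", 1))
  ocB <- c(rep("TP", 6), rep("FN", 4), rep("TN", 10))
  run <- list(P83 = list(mkTab(ocA), mkTab(ocA)),
              P17 = list(mkTab(ocB), mkTab(ocB)),
              RAND = list(mkTab(ocB), mkTab(ocA)))
  rep1 <- evaluateRun(run)
  tab <- rep1$table
  expect_equal(tab$scheme, c("P83", "P17", "RAND"))
  # identical trials give zero sd columns
  expect_equal(tab$tpr_sd[1:2], c(0, 0))
  expect_equal(tab$f1_cv[1:2], c(0, 0))
  # RAND is excluded from the analogous ROC operating points
  expect_equal(nrow(rep1$roc$curve), 2 + 2)
  # permutation invariance over trial order
  run2 <- list(P83 = run$P83[2:1], P17 = run$P17, RAND = run$RAND[2:1])
  rep2 <- evaluateRun(run2)
  expect_equal(rep2$table, tab)
  # a single trial yields explicit NA markers instead of sd / F1-CV
  rep3 <- evaluateRun(list(P50 = list(mkTab(ocA))))
  expect_true(is.na(rep3$table$tpr_sd))
  expect_true(is.na(rep3$table$f1_cv))
  # inconsistent id sets are rejected
  bad <- mkTab(ocA); bad$id[1] <- "zzz"
  expect_error(evaluateRun(list(P83 = list(mkTab(ocA), bad))), "different test ids")
})
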