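test_that("mask-to-box extraction finds tight component bounds", {
  expect_equal(nrow(maskToBoxes(matrix(0, 10, 10))), 0)
  m <- matrix(0, 12, 12)
  m[6:7, 4:7] <- 1  # rectangle at x=3, y=5, w=4, h=2
  expect_equal(maskToBoxes(m, minArea = 1), boxFrame(3, 5, 4, 2))
})

test_that("diagonal-touching blobs merge under 8-connectivity only", {
  m <- matrix(0, 8, 8)
  m[2:3, 2:3] <- 1
  m[4:5, 4:5] <- 1  # touches the first blob only at a corner
  expect_equal(max(floodLabel(m, 8)), 1)
  expect_equal(max(floodLabel(m, 4)), 2)
  # implementation is pinned to 8-connectivity
  expect_equal(nrow(maskToBoxes(m, minArea = 1)), 1)
})

test_that("component labeling agrees with the flood-fill oracle on random masks", {
  withr::with_seed(14, {
    for (i in 1:20) {
      m <- matrix(rbinom(400, 1, 0.3), 20, 20)
      ours <- bcmseg:::.labelComponents8(m > 0)
      oracle <- floodLabel(m, 8)
      expect_equal(max(ours), max(oracle))
      # identical partitions up to label permutation
      expect_equal(length(unique(paste(ours, oracle))) - 1, max(oracle))
      # every surviving foreground pixel is covered by some box
      boxes <- maskToBoxes(m, minArea = 1)
      covered <- matrix(FALSE, 20, 20)
      for (j in seq_len(nrow(boxes))) {
        covered[(boxes$y[j] + 1):(boxes$y[j] + boxes$h[j]),
                (boxes$x[j] + 1):(boxes$x[j] + boxes$w[j])] <- TRUE
      }
      expect_true(all(covered[m > 0]))
    }
  })
})

test_that("minimum-area filtering drops small specks", {
  m <- matrix(0, 20, 20)
  m[2, 2] <- 1            # single pixel
  m[10:14, 10:14] <- 1    # 25 pixels
  expect_equal(nrow(maskToBoxes(m, minArea = 2)), 1)
  expect_equal(nrow(maskToBoxes(m, minArea = 1)), 2)
  expect_equal(nrow(maskToBoxes(m, minArea = 26)), 0)
})

test_that("box overlap uses half-open semantics", {
  a <- boxFrame(0, 0, 10, 10)
  expect_true(boxesOverlap(a, a))
  expect_false(boxesOverlap(a, boxFrame(10, 0, 5, 5)))   # shared edge only
  expect_false(boxesOverlap(a, boxFrame(10, 10, 5, 5)))  # shared corner only
  expect_true(boxesOverlap(a, boxFrame(9, 9, 5, 5)))     # 1-pixel overlap
})

test_that("the published edge cases adjudicate correctly", {
  truth <- boxFrame(10, 10, 20, 20)
  # extra non-overlapping predicted box does not revoke a TP
  oc <- adjudicateCase(truth, boxFrame(c(15, 60), c(15, 60), c(5, 5), c(5, 5)))
  expect_equal(caseOutcome(oc), "TP")
  # positive case whose only predicted box misses is an FP
  expect_equal(caseOutcome(adjudicateCase(truth, boxFrame(60, 60, 5, 5))), "FP")
  expect_equal(caseOutcome(adjudicateCase(boxFrame(), boxFrame())), "TN")
  expect_equal(caseOutcome(adjudicateCase(truth, boxFrame())), "FN")
  expect_equal(caseOutcome(adjudicateCase(boxFrame(), boxFrame(1, 1, 2, 2))), "FP")
})

test_that("adjudication matches the brute-force oracle over a config grid", {
  # toy universe: boxes on a 12x12 canvas at varied positions/sizes
  candidates <- list(
    boxFrame(), boxFrame(0, 0, 4, 4), boxFrame(4, 4, 4, 4),
    boxFrame(2, 2, 4, 4), boxFrame(8, 8, 3, 3),
    boxFrame(c(0, 8), c(0, 8), c(3, 3), c(3, 3)),
    boxFrame(c(1, 5), c(1, 5), c(5, 2), c(5, 2)))
  for (ti in seq_along(candidates)) {
    for (pi in seq_along(candidates)) {
      tb <- candidates[[ti]]; pb <- candidates[[pi]]
      oc <- adjudicateCase(tb, pb)
      expect_equal(caseOutcome(oc), bruteOutcome(tb, pb),
                   label = sprintf("true=%d pred=%d", ti, pi))
    }
  }
})

test_that("adjudication is invariant to box order and duplication", {
  truth <- boxFrame(c(2, 20), c(2, 20), c(5, 5), c(5, 5))
  pred <- boxFrame(c(40, 3), c(40, 3), c(4, 4), c(4, 4))
  oc1 <- caseOutcome(adjudicateCase(truth, pred))
  oc2 <- caseOutcome(adjudicateCase(truth[2:1, ], pred[2:1, ]))
  oc3 <- caseOutcome(adjudicateCase(truth, pred[c(1, 2, 2, 1), ]))
  expect_equal(oc1, "TP")
  expect_equal(oc2, oc1)
  expect_equal(oc3, oc1)
})

test_that("outcome tables preserve ids and counts", {
  recs <- list(caseRecord("a", "lung_opacity", boxFrame(1, 1, 4, 4)),
               caseRecord("b", "normal"))
  preds <- list(a = boxFrame(2, 2, 2, 2), b = boxFrame())
  tab <- adjudicateCases(recs, preds)
  expect_equal(tab$outcome, c("TP", "TN"))
  expect_equal(tab$n_true_boxes, c(1L, 0L))
  expect_equal(tab$n_pred_boxes, c(1L, 0L))
})
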