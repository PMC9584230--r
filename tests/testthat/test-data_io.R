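test_that("label table groups rows per patient and collects boxes", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patientId,x,y,width,height,Target",
    "a,10,20,30,40,1",
    "a,50,60,20,10,1",
    "b,,,,,0",
    "c,5,5,8,8,1",
    "d,,,,,0",
    "e,,,,,0"), f)
  recs <- readLabelTable(f)
  expect_length(recs, 5)
  byId <- setNames(recs, vapply(recs, caseId, ""))
  expect_equal(nrow(caseBoxes(byId[["a"]])), 2)
  expect_equal(caseTarget(byId[["b"]]), 0L)
  expect_equal(nrow(caseBoxes(byId[["b"]])), 0)
  expect_equal(sum(vapply(recs, function(r) nrow(caseBoxes(r)), 0L)), 3)
  expect_equal(caseBoxes(byId[["a"]])$x, c(10, 50))
})

test_that("label table validation catches conflicts and missing boxes", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patientId,x,y,width,height,Target",
               "a,1,1,5,5,1", "a,,,,,0"), f)
  expect_error(readLabelTable(f), "conflicting Target")
  writeLines(c("patientId,x,y,width,height,Target", "a,,,,,1"), f)
  expect_error(readLabelTable(f), "no parseable box")
  expect_error(readLabelTable(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("write-then-read of a label table is the identity on id/target/boxes", {
  recs <- list(
    caseRecord("p1", "lung_opacity", boxFrame(c(4, 40), c(8, 50), c(10, 12), c(6, 9))),
    caseRecord("p2", "normal"),
    caseRecord("p3", "lung_opacity", boxFrame(0, 0, 3, 3)),
    caseRecord("p4", "no_opacity_not_normal"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeLabelTable(recs, f)
  back <- readLabelTable(f)
  expect_equal(vapply(back, caseId, ""), vapply(recs, caseId, ""))
  expect_equal(vapply(back, caseTarget, 0L), vapply(recs, caseTarget, 0L))
  for (i in seq_along(recs))
    expect_equal(caseBoxes(back[[i]]), caseBoxes(recs[[i]]))
})

test_that("balanced test split has exact class counts and preserves the pool", {
  recs <- c(lapply(1:12, function(i) caseRecord(paste0("p", i), "lung_opacity",
                                                boxFrame(1, 1, 4, 4))),
            lapply(1:20, function(i) caseRecord(paste0("n", i), "normal")))
  sp <- splitBalancedTest(recs, 5, seed = 42)
  tt <- vapply(testCases(sp), caseTarget, 0L)
  expect_equal(sum(tt == 1L), 5)
  expect_equal(sum(tt == 0L), 5)
  expect_length(trainCases(sp), 22)
  allIds <- sort(c(vapply(trainCases(sp), caseId, ""),
                   vapply(testCases(sp), caseId, "")))
  expect_equal(allIds, sort(vapply(recs, caseId, "")))  # seed-independent multiset
  # determinism
  sp2 <- splitBalancedTest(recs, 5, seed = 42)
  expect_identical(vapply(testCases(sp2), caseId, ""),
                   vapply(testCases(sp), caseId, ""))
  # different seed still partitions the same multiset
  sp3 <- splitBalancedTest(recs, 5, seed = 7)
  allIds3 <- sort(c(vapply(trainCases(sp3), caseId, ""),
                    vapply(testCases(sp3), caseId, "")))
  expect_equal(allIds3, allIds)
})

test_that("balanced split handles exhaustion and truncation", {
  recs <- c(lapply(1:5, function(i) caseRecord(paste0("p", i), "lung_opacity",
                                               boxFrame(1, 1, 2, 2))),
            lapply(1:5, function(i) caseRecord(paste0("n", i), "normal")))
  sp <- splitBalancedTest(recs, 5, seed = 1)
  expect_length(trainCases(sp), 0)
  expect_error(splitBalancedTest(recs, 6, seed = 1), "per class")
  recs2 <- c(recs, lapply(1:6, function(i) caseRecord(paste0("x", i), "normal")))
  sp2 <- splitBalancedTest(recs2, 5, seed = 1, trainSize = 4)
  expect_length(trainCases(sp2), 4)
})

test_that("the full-scale split arithmetic is reachable", {
  # published pool: 5659 positives of 25,684; test 229+229; train 24,684
  # (leaving 542 unassigned — both readings must be reachable)
  counts <- referenceTrainingCounts()
  nPos <- 5659
  recs <- c(lapply(seq_len(nPos), function(i)
    caseRecord(paste0("p", i), "lung_opacity", boxFrame(1, 1, 2, 2))),
    lapply(seq_len(counts$totalImages - nPos), function(i)
      caseRecord(paste0("n", i), "normal")))
  spAll <- splitBalancedTest(recs, 229, seed = 1)
  expect_length(testCases(spAll), 458)
  expect_length(trainCases(spAll), 25684 - 458)
  spPublished <- splitBalancedTest(recs, 229, seed = 1, trainSize = 24684)
  expect_length(trainCases(spPublished), 24684)
  expect_equal(25684 - 24684 - 458, 542)  # the discarded remainder
})

test_that("prediction table round-trips boxes and confidences", {
  f <- withr::local_tempfile(fileext = ".csv")
  ids <- c("a", "b", "c")
  boxes <- list(boxFrame(10, 20, 30, 40),
                boxFrame(),
                boxFrame(c(1, 7), c(2, 8), c(3, 9), c(4, 10)))
  conf <- list(0.9, numeric(), c(0.5, 0.25))
  writePredictionTable(ids, boxes, conf, f)
  back <- readPredictionTable(f)
  expect_equal(names(back), ids)
  expect_equal(back[["a"]]$boxes, boxes[[1]])
  expect_equal(back[["a"]]$conf, 0.9)
  expect_equal(nrow(back[["b"]]$boxes), 0)
  expect_equal(back[["c"]]$boxes, boxes[[3]])
  expect_equal(back[["c"]]$conf, c(0.5, 0.25))
  raw <- read.csv(f, colClasses = "character")
  expect_equal(raw$PredictionString[1], "0.9 10 20 30 40")
  expect_equal(raw$PredictionString[2], "")
  expect_error(writePredictionTable(c("a", "a"), boxes[1:2], conf[1:2], f),
               "duplicate")
})

test_that("PNG rasters read back with unit-interval intensities", {
  f <- withr::local_tempfile(fileext = ".png")
  m <- matrix(seq(0, 1, length.out = 64), 8, 8)
  png::writePNG(m, f)
  r <- readPngImage(f, id = "pix")
  expect_s4_class(r, "ImageRaster")
  expect_equal(dim(r@pixels), c(8, 8))
  expect_equal(r@pixels, m, tolerance = 1 / 255)
  expect_equal(caseId(r), "pix")
})
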