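oneObjectScene <- function(counts, seed = 1L, nSlices = 9L) {
  cfg <- sceneConfig(imageSize = c(256L, 256L), nSlices = nSlices,
                     objectCounts = counts, seed = seed)
  sampleScene(cfg)
}

test_that("segmentation returns nothing on flat images and errors on empty", {
  cfg <- detectorConfig()
  expect_equal(nrow(segmentSlice(matrix(0.7, 64, 64), cfg)), 0L)
  expect_error(segmentSlice(matrix(numeric(0), 0, 0), cfg), "empty")
})

test_that("an in-focus cell is segmented as one box containing its centre", {
  sc <- oneObjectScene(c(cell = 1, cluster = 0, colony = 0), seed = 6L)
  cfg <- detectorConfigForScene(sc)
  obj <- sceneObjects(sc)
  focalSlice <- round(obj$focal_z / sceneConfigOf(sc)@sliceSpacing)
  img <- renderStack(sc)[, , focalSlice + 1L]
  boxes <- segmentSlice(img, cfg)
  expect_equal(nrow(boxes), 1L)
  cx <- obj$x_um / sceneConfigOf(sc)@pixelSize
  cy <- obj$y_um / sceneConfigOf(sc)@pixelSize
  expect_true(boxes$x <= cx && cx <= boxes$x + boxes$w)
  expect_true(boxes$y <= cy && cy <= boxes$y + boxes$h)
})

test_that("well-separated objects produce disjoint boxes", {
  sc <- oneObjectScene(c(cell = 0, cluster = 2, colony = 0), seed = 9L)
  cfg <- detectorConfigForScene(sc)
  obj <- sceneObjects(sc)
  ## pick a slice where both clusters are within candidate depth
  zs <- (seq_len(sceneConfigOf(sc)@nSlices) - 1L) * 30
  ok <- which(vapply(zs, function(z)
    all(abs(z - obj$focal_z) <= 90), logical(1)))
  if (length(ok)) {
    img <- renderStack(sc)[, , ok[1]]
    boxes <- segmentSlice(img, cfg)
    expect_equal(nrow(boxes), 2L)
    expect_equal(boxIoU(boxes[1, ], boxes[2, , drop = FALSE]), 0)
  }
  succeed()
})

test_that("focus score behaves like a sharpness measure", {
  expect_equal(focusScore(matrix(0.5, 32, 32),
                          c(x = 2, y = 2, w = 20, h = 20)), 0)
  ## sharper at the focal plane than far from it
  sc <- oneObjectScene(c(cell = 0, cluster = 0, colony = 1), seed = 12L)
  gt <- groundTruth(sc)
  obj <- sceneObjects(sc)
  stk <- renderStack(sc)
  dz <- abs(gt$slice * 30 - obj$focal_z)
  nearRow <- which.min(dz); farRow <- which.max(dz)
  sNear <- focusScore(stk[, , gt$slice[nearRow] + 1L],
                      gt[nearRow, c("x", "y", "w", "h")])
  sFar <- focusScore(stk[, , gt$slice[farRow] + 1L],
                     gt[farRow, c("x", "y", "w", "h")])
  expect_gt(sNear, sFar)
  ## invariance to a constant intensity offset
  img <- stk[, , gt$slice[nearRow] + 1L]
  box <- gt[nearRow, c("x", "y", "w", "h")]
  expect_equal(focusScore(img - 0.2, box), focusScore(img, box),
               tolerance = 1e-12)
  expect_error(focusScore(img, c(x = 1, y = 1, w = 0, h = 5)), "degenerate")
})

test_that("blob classification follows the hierarchical size/focus rules", {
  cfg <- detectorConfig()
  A <- cfg@cellArea
  hi <- cfg@focusThreshold * 3
  lo <- cfg@focusThreshold / 3
  expect_equal(classifyBlob(1.0 * A, hi, cfg)$label, "cell")
  expect_equal(classifyBlob(10 * A, hi, cfg)$label, "cluster")
  expect_equal(classifyBlob(20 * A, hi, cfg)$label, "colony")
  expect_equal(classifyBlob(20 * A, lo, cfg)$label, "candidate")
  expect_null(classifyBlob(1.0 * A, lo, cfg))
  ## confidence strictly below 1 under the bounded-product rule
  cc <- classifyBlob(10 * A, cfg@focusThreshold * 100, cfg)
  expect_lt(cc$confidence, 1)
  expect_gt(cc$confidence, 0)
  expect_error(classifyBlob(0, hi, cfg), "positive")
})

test_that("non-maximum suppression is greedy, confidence-ordered, idempotent", {
  d <- data.frame(x = c(0, 0, 50), y = c(0, 0, 50), w = 10, h = 10,
                  label = "cell", conf = c(0.9, 0.8, 0.7),
                  stringsAsFactors = FALSE)
  kept <- nmsFilter(d, 0.5)
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$conf, c(0.9, 0.7))
  disjoint <- d[c(1, 3), ]
  expect_equal(nrow(nmsFilter(disjoint, 0.5)), 2L)
  expect_identical(nmsFilter(kept, 0.5), kept)
})

test_that("slice detection recovers all objects with correct labels", {
  sc <- oneObjectScene(c(cell = 1, cluster = 1, colony = 1), seed = 4L)
  cfg <- detectorConfigForScene(sc)
  stk <- renderStack(sc)
  gt <- groundTruth(sc)
  ## blank input and extreme threshold
  expect_equal(nrow(detectSlice(matrix(1, 64, 64), cfg)), 0L)
  strict <- detectorConfigForScene(sc, confidenceThreshold = 1.0)
  anySlice <- gt$slice[1] + 1L
  expect_equal(nrow(detectSlice(stk[, , anySlice], strict)), 0L)
  ## in-focus ground truth is matched 1:1 with correct labels
  det <- detectStack(stk, cfg)
  inFocus <- gt[gt$label != "candidate", ]
  for (r in seq_len(nrow(inFocus))) {
    d <- det[det$slice == inFocus$slice[r], , drop = FALSE]
    ious <- boxIoU(inFocus[r, c("x", "y", "w", "h")], d)
    expect_gte(max(ious), 0.5)
    expect_equal(d$label[which.max(ious)], inFocus$label[r])
  }
})

test_that("per-slice precision and recall are perfect on clean scenes", {
  ## every detection overlaps some GT box, every in-focus GT box is found
  for (seed in c(5L, 17L)) {
    sc <- oneObjectScene(c(cell = 2, cluster = 1, colony = 1), seed = seed)
    cfg <- detectorConfigForScene(sc)
    stk <- renderStack(sc)
    det <- detectStack(stk, cfg)
    gt <- groundTruth(sc)
    for (s in unique(det$slice)) {
      d <- det[det$slice == s, ]
      g <- gt[gt$slice == s, ]
      expect_true(nrow(g) > 0)
      for (i in seq_len(nrow(d)))
        expect_gte(max(boxIoU(d[i, c("x", "y", "w", "h")], g)), 0.5)
    }
    inFocus <- gt[gt$label != "candidate", ]
    for (r in seq_len(nrow(inFocus))) {
      d <- det[det$slice == inFocus$slice[r], , drop = FALSE]
      expect_gte(max(boxIoU(inFocus[r, c("x", "y", "w", "h")], d)), 0.5)
    }
  }
})
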