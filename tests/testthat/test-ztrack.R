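box <- function(x, y, w = 10, h = 10) data.frame(x = x, y = y, w = w, h = h)

det <- function(slice, x, y, w = 10, h = 10, label = "cell", conf = 0.9) {
  data.frame(slice = slice, x = x, y = y, w = w, h = h, label = label,
             conf = conf, stringsAsFactors = FALSE)
}

test_that("IoU matches direct area arithmetic", {
  a <- c(x = 0, y = 0, w = 10, h = 10)
  expect_equal(boxIoU(a, box(0, 0)), 1)
  expect_equal(boxIoU(a, box(20, 20)), 0)
  expect_equal(boxIoU(a, box(5, 0)), 1 / 3)
  ## symmetry
  b <- box(3, 4, 12, 7)
  expect_equal(boxIoU(a, b), boxIoU(unlist(b), as.data.frame(t(a))))
})

test_that("assignment solver matches exhaustive permutation search", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    cost <- matrix(runif(n * m), n, m)
    got <- solveAssignment(cost)
    gotCost <- sum(cost[got])
    expect_equal(gotCost, bruteAssignmentCost(cost) -
                   0, tolerance = 1e-12)
    ## every row/col used at most once
    expect_false(anyDuplicated(got[, "row"]) > 0)
    expect_false(anyDuplicated(got[, "col"]) > 0)
  }
})

test_that("two-stage association matches and rejects as specified", {
  cfg <- trackerConfig()
  tb <- data.frame(track_id = 1L, x = 0, y = 0, w = 10, h = 10)
  hit <- det(0, 1, 0, conf = 0.9)      # IoU 9/11 with the track box
  assoc <- associateDetections(tb, hit, cfg)
  expect_equal(nrow(assoc$matches), 1L)
  expect_equal(assoc$matches$track_id, 1L)
  miss <- det(0, 200, 200, conf = 0.9)
  assoc <- associateDetections(tb, miss, cfg)
  expect_equal(nrow(assoc$matches), 0L)
  expect_equal(assoc$unmatchedTracks, 1L)
  expect_equal(assoc$unmatchedDetections, 1L)
  ## low-confidence detections only join stage 2 and never open tracks
  lowHit <- det(0, 1, 0, conf = 0.2)
  assoc <- associateDetections(tb, lowHit, cfg)
  expect_equal(assoc$matches$stage, 2L)
  expect_length(assoc$unmatchedDetections, 0L)
  expect_error(associateDetections(tb, rbind(det(0, 0, 0), det(1, 0, 0)),
                                   cfg), "one slice")
})

test_that("tracking perfect ground truth recovers one track per object", {
  cfg <- sceneConfig(seed = 31L)
  sc <- sampleScene(cfg)
  d <- gtDetections(sc)
  tracks <- trackStack(d, trackerConfig())
  gt <- groundTruth(sc)
  expect_equal(length(unique(tracks$track_id)),
               length(unique(gt$object_id)))
  ## every GT frame is covered
  expect_equal(nrow(tracks), nrow(gt))
})

test_that("gap handling splits tracks only beyond maxGap", {
  present <- function(slices) do.call(rbind, lapply(slices, function(s)
    det(s, 100, 100)))
  cfg <- trackerConfig(maxGap = 3L)
  onegap <- trackStack(present(c(0:3, 7:10)), cfg)   # gap of 3 slices
  expect_equal(length(unique(onegap$track_id)), 1L)
  split <- trackStack(present(c(0:3, 8:11)), cfg)    # gap of 4 slices
  expect_equal(length(unique(split$track_id)), 2L)
})

test_that("track classification takes the hierarchical maximum", {
  expect_equal(classifyTrack(c("candidate", "cluster", "colony",
                               "candidate")), "colony")
  expect_equal(classifyTrack(c("candidate", "candidate")), "candidate")
  expect_equal(classifyTrack("cell"), "cell")
  expect_error(classifyTrack(character(0)), "empty")
})

test_that("no detection is used twice and ids are unique and stable", {
  sc <- sampleScene(sceneConfig(seed = 55L, driftSigma = 1))
  d <- gtDetections(sc)
  tracks <- trackStack(d, trackerConfig())
  key <- paste(tracks$slice, tracks$x, tracks$y, tracks$w, tracks$h)
  expect_false(any(duplicated(key)))
  expect_true(all(key %in% paste(d$slice, d$x, d$y, d$w, d$h)))
  ## slices strictly increasing within each track
  for (id in unique(tracks$track_id))
    expect_true(all(diff(tracks$slice[tracks$track_id == id]) > 0))
})

test_that("tracking is invariant to detection order within slices", {
  sc <- sampleScene(sceneConfig(seed = 77L))
  d <- gtDetections(sc)
  set.seed(1)
  shuffled <- d[sample(nrow(d)), ]
  t1 <- trackStack(d, trackerConfig())
  t2 <- trackStack(shuffled, trackerConfig())
  rownames(t1) <- rownames(t2) <- NULL
  expect_identical(t1, t2)
})

test_that("short tracks are discarded under minLength", {
  d <- rbind(det(0, 0, 0), det(0, 100, 100), det(1, 0, 0), det(2, 0, 0))
  tr <- trackStack(d, trackerConfig(minLength = 2L))
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(nrow(tr), 3L)
})
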