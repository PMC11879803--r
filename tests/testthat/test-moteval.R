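trackRows <- function(id, slices, x, y, w = 10, h = 10) {
  data.frame(track_id = id, slice = slices, x = x, y = y, w = w, h = h)
}

test_that("identity measures are exact for perfect and empty hypotheses", {
  gt <- rbind(trackRows(1, 0:4, 10, 10), trackRows(2, 2:6, 50, 50))
  idm <- idMeasures(gt, gt)
  expect_equal(idm$idtp, nrow(gt))
  expect_equal(idm$idfp, 0)
  expect_equal(idm$idfn, 0)
  expect_equal(idm$idf1, 1)
  none <- idMeasures(gt, gt[0, ])
  expect_equal(none$idtp, 0)
  expect_equal(none$idfn, nrow(gt))
  expect_equal(none$idf1, 0)
})

test_that("a mid-stack identity swap is scored at the pairing optimum", {
  gt <- rbind(trackRows(1, 0:9, 10, 10), trackRows(2, 0:9, 100, 100))
  ## hypothesis ids swap at slice 5
  hyp <- rbind(trackRows(1, 0:4, 10, 10), trackRows(2, 5:9, 10, 10),
               trackRows(2, 0:4, 100, 100), trackRows(1, 5:9, 100, 100))
  idm <- idMeasures(gt, hyp)
  ov <- oracleOverlapMatrix(gt, hyp, 0.5)
  expect_equal(idm$idtp, bruteMaxOverlap(ov))
  expect_equal(idm$idtp, 10)           # each pairing keeps half per object
  expect_equal(idm$idf1, 0.5)
})

test_that("identity measures agree with brute force and the scipy oracle", {
  for (seed in 1:22) {
    sce <- randomScenario(seed)
    idm <- idMeasures(sce$gt, sce$hyp)
    expect_equal(idm$idtp,
                 bruteMaxOverlap(oracleOverlapMatrix(sce$gt, sce$hyp, 0.5)),
                 info = paste("seed", seed))
    py <- pythonOracle(sce$gt, sce$hyp)
    expect_equal(idm$idtp, py$idtp, info = paste("seed", seed))
    expect_equal(idm$idfp, py$idfp, info = paste("seed", seed))
    expect_equal(idm$idfn, py$idfn, info = paste("seed", seed))
  }
})

test_that("coverage categories and switch counts match the scipy oracle", {
  for (seed in 1:22) {
    sce <- randomScenario(seed)
    py <- pythonOracle(sce$gt, sce$hyp)
    fm <- clearMatching(sce$gt, sce$hyp)
    for (gid in sort(unique(sce$gt$track_id))) {
      matched <- sum(fm$gt_id == gid)
      total <- sum(sce$gt$track_id == gid)
      expect_equal(trackCoverage(matched, total),
                   py$coverage[[as.character(gid)]],
                   info = paste("seed", seed, "gt", gid))
    }
    expect_equal(idSwitches(sce$gt, sce$hyp), py$switches,
                 info = paste("seed", seed))
  }
})

test_that("coverage thresholds follow the 80/20 convention", {
  expect_equal(trackCoverage(10, 10), "mostly_tracked")
  expect_equal(trackCoverage(8, 10), "mostly_tracked")
  expect_equal(trackCoverage(5, 10), "partially_tracked")
  expect_equal(trackCoverage(2, 10), "mostly_lost")
  expect_equal(trackCoverage(0, 10), "mostly_lost")
  expect_error(trackCoverage(0, 0), "empty")
})

test_that("identity switches count re-associations, not fragmentation alone", {
  gt <- trackRows(1, 0:9, 10, 10)
  expect_equal(idSwitches(gt, gt), 0)
  ## one object covered by two hyp ids in sequence: one switch
  hyp <- rbind(trackRows(5, 0:4, 10, 10), trackRows(6, 5:9, 10, 10))
  expect_equal(idSwitches(gt, hyp), 1)
  ## two objects swapping ids mid-stack: two switches
  gt2 <- rbind(trackRows(1, 0:9, 10, 10), trackRows(2, 0:9, 100, 100))
  hyp2 <- rbind(trackRows(1, 0:4, 10, 10), trackRows(2, 5:9, 10, 10),
                trackRows(2, 0:4, 100, 100), trackRows(1, 5:9, 100, 100))
  expect_equal(idSwitches(gt2, hyp2), 2)
})

test_that("tracking evaluation composes scores with valid invariants", {
  sc <- sampleScene(sceneConfig(seed = 14L))
  gt <- gtAsTrackTable(sc)
  scores <- evaluateTracking(gt, gt)
  expect_s4_class(scores, "MOTScores")
  expect_equal(scores@idf1, 1)
  expect_equal(scores@idSwitches, 0)
  expect_equal(scores@mostlyTracked + scores@partiallyTracked +
                 scores@mostlyLost, scores@nObjects)
  df <- as.data.frame(scores)
  expect_equal(df$idf1, 1)
})

test_that("average precision reproduces hand-computed PR curves", {
  gt1 <- data.frame(slice = 0, x = 10, y = 10, w = 10, h = 10,
                    label = "colony", stringsAsFactors = FALSE)
  ## perfect detection ranked above a spurious one: AP stays 1
  dets <- data.frame(slice = 0, x = c(10, 60), y = c(10, 60), w = 10,
                     h = 10, label = "colony", conf = c(0.9, 0.8),
                     stringsAsFactors = FALSE)
  ev <- averagePrecision(dets, gt1)
  expect_equal(ev$perClass$ap50[ev$perClass$class == "colony"], 1)
  ## spurious detection ranked between two hits: AP = 0.5 + 1/3
  gt2 <- rbind(gt1, transform(gt1, x = 100, y = 100))
  dets2 <- data.frame(slice = 0, x = c(10, 60, 100), y = c(10, 60, 100),
                      w = 10, h = 10, label = "colony",
                      conf = c(0.9, 0.8, 0.7), stringsAsFactors = FALSE)
  ev2 <- averagePrecision(dets2, gt2)
  expect_equal(ev2$perClass$ap50[ev2$perClass$class == "colony"],
               0.5 + 1 / 3, tolerance = 1e-12)
  ## equality cases
  evEq <- averagePrecision(transform(gt1, conf = 0.5), gt1)
  expect_equal(evEq$perClass$ap50[evEq$perClass$class == "colony"], 1)
  evNone <- averagePrecision(dets2[0, ], gt2)
  expect_equal(evNone$perClass$ap50[evNone$perClass$class == "colony"], 0)
})

test_that("the confusion matrix routes detections to best-IoU truth", {
  gt <- data.frame(slice = 0, x = c(0, 100), y = 0, w = 10, h = 10,
                   label = c("colony", "cluster"), stringsAsFactors = FALSE)
  dets <- data.frame(slice = 0, x = c(1, 100, 200), y = 0, w = 10, h = 10,
                     label = c("colony", "colony", "cell"),
                     conf = 0.9, stringsAsFactors = FALSE)
  cm <- averagePrecision(dets, gt)$confusion
  expect_equal(cm["colony", "colony"], 1L)
  expect_equal(cm["colony", "cluster"], 1L)    # misclassified cluster
  expect_equal(cm["cell", "background"], 1L)   # spurious detection
  expect_equal(sum(cm["background", ]), 0L)    # all GT matched
})

test_that("score averaging reproduces benchmark-style summary rows", {
  scores <- read.csv(system.file("extdata", "benchmark_tracking_scores.csv",
                                 package = "ClonoTrack"))
  sm <- summarizeScores(scores)
  colony <- sm[sm$class == "colony", ]
  expect_equal(colony$idf1, mean(c(0.831, 0.887, 0.704, 0.799)))
  expect_equal(colony$idf1_rounded, 0.805)
  cluster <- sm[sm$class == "cluster", ]
  expect_equal(cluster$idf1, mean(c(0.682, 0.764, 0.749, 0.715)))
  expect_equal(cluster$idf1_rounded, 0.728)
  ## single dataset: summary equals its own scores
  one <- summarizeScores(scores[scores$dataset == 123, ])
  expect_equal(one$idf1[one$class == "colony"], 0.831)
  ## inconsistent class sets rejected
  expect_error(summarizeScores(scores[-1, ]), "inconsistent")
})

test_that("the joint objective multiplies IDF1 by the tracked share", {
  expect_equal(trackingObjective(list(idf1 = 1, mostly_tracked = 10,
                                      partially_tracked = 0,
                                      n_objects = 10)), 1)
  expect_equal(trackingObjective(list(idf1 = 0.5, mostly_tracked = 3,
                                      partially_tracked = 2,
                                      n_objects = 10)), 0.25)
  expect_equal(trackingObjective(list(idf1 = 0.752, mostly_tracked = 76,
                                      partially_tracked = 35,
                                      n_objects = 124.25)),
               0.752 * 111 / 124.25, tolerance = 1e-12)
  expect_error(trackingObjective(list(idf1 = 1, mostly_tracked = 0,
                                      partially_tracked = 0, n_objects = 0)),
               "positive")
})

test_that("random search is deterministic and finds a planted optimum", {
  space <- list(a = c(0, 1), b = c(0, 1))
  evalFn <- function(p) -((p$a - 0.3)^2 + (p$b - 0.7)^2)
  r1 <- tuneParameters(space, evalFn, nIter = 100, seed = 5)
  r2 <- tuneParameters(space, evalFn, nIter = 100, seed = 5)
  expect_identical(r1$history, r2$history)
  expect_equal(nrow(r1$history), 100L)
  expect_lt(abs(r1$bestParams$a - 0.3), 0.15)
  expect_lt(abs(r1$bestParams$b - 0.7), 0.15)
  ## constant objective: any point optimal, full history retained
  rc <- tuneParameters(space, function(p) 1, nIter = 7, seed = 1)
  expect_equal(nrow(rc$history), 7L)
  expect_equal(rc$bestValue, 1)
  expect_error(tuneParameters(list(), evalFn, 5, 1), "empty")
})
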