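smallConfig <- function(...) {
  sceneConfig(imageSize = c(256L, 256L), nSlices = 9L,
              objectCounts = c(cell = 2, cluster = 1, colony = 1), ...)
}

test_that("class derivation partitions cell counts totally and uniquely", {
  expect_equal(classFromCellCount(1), "cell")
  expect_equal(classFromCellCount(2), "cluster")
  expect_equal(classFromCellCount(14), "cluster")
  expect_equal(classFromCellCount(15), "colony")
  cls <- classFromCellCount(1:40)
  expect_true(all(cls %in% objectClasses()))
  expect_equal(sum(cls == "cell"), 1)
  expect_equal(sum(cls == "cluster"), 13)
  expect_error(classFromCellCount(0))
})

test_that("sampleScene honours the requested census and is deterministic", {
  cfg <- sceneConfig(objectCounts = c(cell = 5, cluster = 3, colony = 2),
                     seed = 11L)
  sc <- sampleScene(cfg)
  obj <- sceneObjects(sc)
  expect_equal(nrow(obj), 10L)
  tab <- table(obj$true_class)
  expect_equal(as.integer(tab[c("cell", "cluster", "colony")]),
               c(5L, 3L, 2L))
  sc2 <- sampleScene(cfg)
  expect_identical(sceneObjects(sc2), obj)
  expect_identical(groundTruth(sc2), groundTruth(sc))

  empty <- sampleScene(sceneConfig(objectCounts = c(cell = 0, cluster = 0,
                                                    colony = 0), seed = 1L))
  expect_equal(nrow(sceneObjects(empty)), 0L)
  expect_equal(nrow(groundTruth(empty)), 0L)
})

test_that("scene configuration rejects invalid geometry", {
  expect_error(sceneConfig(imageSize = c(0L, 10L)), "positive")
  expect_error(sceneConfig(sliceSpacing = -1), "positive")
  expect_error(sceneConfig(dof = 50, candidateDepth = 40), "candidateDepth")
})

test_that("ground truth is consistent with the visible objects", {
  cfg <- smallConfig(seed = 21L)
  sc <- sampleScene(cfg)
  obj <- sceneObjects(sc)
  gt <- groundTruth(sc)
  zs <- (seq_len(cfg@nSlices) - 1L) * cfg@sliceSpacing
  visible <- obj$object_id[vapply(seq_len(nrow(obj)), function(i)
    any(abs(zs - obj$focal_z[i]) <= cfg@candidateDepth), logical(1))]
  expect_setequal(unique(gt$object_id), visible)
  ## labels: true class within dof, candidate within candidate depth
  for (r in seq_len(nrow(gt))) {
    i <- match(gt$object_id[r], obj$object_id)
    dz <- abs(gt$slice[r] * cfg@sliceSpacing - obj$focal_z[i])
    expect_lte(dz, cfg@candidateDepth)
    expect_equal(gt$label[r],
                 if (dz <= cfg@dof) obj$true_class[i] else "candidate")
  }
  ## boxes within image bounds
  expect_true(all(gt$x >= 0 & gt$y >= 0))
  expect_true(all(gt$x + gt$w <= cfg@imageSize[1]))
  expect_true(all(gt$y + gt$h <= cfg@imageSize[2]))
})

test_that("rendering is deterministic, with a constant blank background", {
  cfg <- smallConfig(seed = 3L)
  sc <- sampleScene(cfg)
  expect_identical(renderStack(sc), renderStack(sc))
  blank <- sampleScene(sceneConfig(imageSize = c(64L, 64L), nSlices = 2L,
                                   objectCounts = c(cell = 0, cluster = 0,
                                                    colony = 0), seed = 5L))
  stk <- renderStack(blank)
  expect_true(all(stk == 1))
})

test_that("defocus blur reduces edge sharpness monotonically", {
  ## one colony centred in z; focus score along slices must peak at the
  ## focal plane and decrease with |dz| (noiseless render)
  cfg <- sceneConfig(imageSize = c(200L, 200L), nSlices = 7L,
                     objectCounts = c(cell = 0, cluster = 0, colony = 1),
                     seed = 8L)
  sc <- sampleScene(cfg)
  obj <- sceneObjects(sc)
  stk <- renderStack(sc)
  gt <- groundTruth(sc)
  scores <- vapply(seq_len(nrow(gt)), function(r)
    focusScore(stk[, , gt$slice[r] + 1L], gt[r, c("x", "y", "w", "h")]),
    numeric(1))
  dz <- abs(gt$slice * cfg@sliceSpacing - obj$focal_z[1])
  ord <- order(dz)
  expect_true(all(diff(scores[ord]) <= 1e-6))
  expect_gt(scores[which.min(dz)], scores[which.max(dz)])
})

test_that("zero drift keeps ground-truth centres fixed across slices", {
  cfg <- smallConfig(seed = 13L, driftSigma = 0)
  gt <- groundTruth(sampleScene(cfg))
  for (id in unique(gt$object_id)) {
    g <- gt[gt$object_id == id, ]
    ## unclipped boxes share one centre
    inner <- g[g$x > 0 & g$y > 0 &
               g$x + g$w < cfg@imageSize[1] & g$y + g$h < cfg@imageSize[2], ]
    if (nrow(inner) > 1) {
      expect_lt(diff(range(inner$x + inner$w / 2)), 1e-9)
      expect_lt(diff(range(inner$y + inner$h / 2)), 1e-9)
    }
  }
  drifted <- groundTruth(sampleScene(smallConfig(seed = 13L,
                                                 driftSigma = 2)))
  centres <- drifted$x + drifted$w / 2
  byObj <- split(centres, drifted$object_id)
  expect_true(any(vapply(byObj, function(v)
    length(v) > 1 && diff(range(v)) > 0.1, logical(1))))
})

test_that("growth is arrested at full inhibition and errors on bad input", {
  obj <- sceneObjects(sampleScene(smallConfig(seed = 2L)))
  g <- growthConfig(timepoints = c(0, 24, 48),
                    inhibition = function(c) rep(1, length(c)), seed = 4L)
  ts <- simulateGrowth(obj, g, concentration = 100)
  for (tp in names(ts))
    expect_identical(ts[[tp]]$cell_count, obj$cell_count)
  expect_error(simulateGrowth(obj, g, concentration = -1), "non-negative")
})

test_that("an uninhibited single cell typically reaches colony size by 60 h", {
  ## 12 h doubling: E[count at 60 h] = 2^5 = 32 >= 15; check the reached
  ## fraction against an independent Monte-Carlo oracle
  p <- 2^(1 / 12) - 1
  nRep <- 200
  fracPkg <- mean(vapply(seq_len(nRep), function(i) {
    obj <- data.frame(object_id = 1L, x_um = 0, y_um = 0, focal_z = 0,
                      cell_count = 1L, radius_um = 5,
                      true_class = "cell", stringsAsFactors = FALSE)
    g <- growthConfig(timepoints = c(0, 60), baseRate = p, seed = i)
    tail(simulateGrowth(obj, g, 0), 1)[[1]]$cell_count >= 15
  }, logical(1)))
  fracOracle <- mean(vapply(seq_len(nRep), function(i)
    oracleGrowCell(60, p, seed = 100000 + i) >= 15, logical(1)))
  expect_gt(fracPkg, 0.5)
  expect_lt(abs(fracPkg - fracOracle), 0.15)
})

test_that("stronger inhibition yields fewer cells on average", {
  obj <- data.frame(object_id = 1:20, x_um = 0, y_um = 0, focal_z = 0,
                    cell_count = 1L, radius_um = 5,
                    true_class = "cell", stringsAsFactors = FALSE)
  inh <- inhibition4PL(ic50 = 10)
  finalMean <- function(conc) {
    vals <- vapply(1:5, function(i) {
      g <- growthConfig(timepoints = c(0, 48), seed = i, inhibition = inh)
      mean(tail(simulateGrowth(obj, g, conc), 1)[[1]]$cell_count)
    }, numeric(1))
    mean(vals)
  }
  expect_gte(finalMean(1), finalMean(100))
})

test_that("simulated dose-response follows the four-parameter logistic", {
  ## midpoint identity at c = IC50
  mid <- simulateDoseResponse(list(top = 0.9, bottom = 0.1, logIC50 = 1,
                                   hill = -1.3),
                              concentrations = 10, nRep = 2, noiseSd = 0,
                              seed = 1)
  expect_equal(mid$response, rep(0.5, 2), tolerance = 1e-12)
  ## asymptotes: inhibition curve (hill < 0) rises to top as c -> 0
  lo <- simulateDoseResponse(list(top = 1, bottom = 0, logIC50 = 1,
                                  hill = -1),
                             concentrations = 1e-9, nRep = 1, noiseSd = 0,
                             seed = 1)
  expect_equal(lo$response, 1, tolerance = 1e-6)
  ## direct evaluation: 1 / (1 + 10^(1*(1-2))) = 10/11
  dr <- simulateDoseResponse(list(top = 1, bottom = 0, logIC50 = 1,
                                  hill = 1),
                             concentrations = 100, nRep = 1, noiseSd = 0,
                             seed = 1)
  expect_equal(dr$response, 1 / (1 + 10^(1 * (1 - 2))), tolerance = 1e-12)
  expect_equal(dr$response, 0.9090909, tolerance = 1e-6)
  ## determinism and input validation
  a <- simulateDoseResponse(list(top = 1, bottom = 0, logIC50 = 1,
                                 hill = -1), c(1, 10, 100), 3, 0.1, seed = 9)
  b <- simulateDoseResponse(list(top = 1, bottom = 0, logIC50 = 1,
                                 hill = -1), c(1, 10, 100), 3, 0.1, seed = 9)
  expect_identical(a, b)
  expect_error(simulateDoseResponse(list(top = 1, bottom = 0, logIC50 = 1,
                                         hill = -1), c(-1, 10), 1, 0, 1),
               "positive")
})

test_that("dataset planning multiplies base images by augmentation factor", {
  expect_equal(planDataset(82, 2), 246L)
  expect_equal(planDataset(10, 0), 10L)
  expect_equal(planDataset(0, 5), 0L)
  expect_error(planDataset(-1, 2), "non-negative")
})
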