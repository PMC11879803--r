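#' Sample a synthetic 3D scene and its per-slice ground truth
#'
#' Draws a population of blob-like objects (single cells, clusters,
#' colonies) at random lateral positions and focal depths inside a
#' Z-stack, together with the per-slice ground-truth annotation a human
#' annotator would produce: on slices within the depth of field the object
#' carries its true class; on slices moderately out of focus it is
#' labelled \code{candidate}; beyond the candidate depth it is invisible
#' and gets no box. Object placement uses rejection sampling so that all
#' objects are separated by at least \code{minSeparation} edge to edge.
#'
#' All sampling is driven by \code{config@seed}; repeated calls with the
#' same configuration return identical scenes.
#'
#' @param config A \code{\link{sceneConfig}} object.
#' @return A \code{\link[=SyntheticScene]{SyntheticScene}}.
#' @examples
#' sc <- sampleScene(sceneConfig(objectCounts = c(cell = 2, cluster = 1,
#'                                                colony = 1), seed = 3))
#' sceneObjects(sc)
#' @seealso \code{\link{renderStack}}, \code{\link{groundTruth}}
#' @export
sampleScene <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  .withSeed(config@seed, {
    counts <- config@objectCounts
    sampleRange <- function(rng, n) {
      if (n == 0L) return(integer(0))
      if (rng[1] == rng[2]) rep(rng[1], n)
      else sample(seq(rng[1], rng[2]), n, replace = TRUE)
    }
    ## colonies first (largest), then clusters, then cells: eases packing
    cellCounts <- c(sampleRange(config@colonyCells, counts[["colony"]]),
                    sampleRange(config@clusterCells, counts[["cluster"]]),
                    rep(1L, counts[["cell"]]))
    nObj <- length(cellCounts)

    fieldW <- config@imageSize[1] * config@pixelSize
    fieldH <- config@imageSize[2] * config@pixelSize
    radius <- config@cellRadius * sqrt(cellCounts)

    xs <- ys <- numeric(nObj)
    for (i in seq_len(nObj)) {
      margin <- radius[i] + config@minSeparation / 2
      if (2 * margin >= fieldW || 2 * margin >= fieldH)
        stop("field too small for object of radius ", round(radius[i], 1),
             " um")
      ok <- FALSE
      for (attempt in seq_len(5000L)) {
        px <- runif(1, margin, fieldW - margin)
        py <- runif(1, margin, fieldH - margin)
        if (i == 1L) { ok <- TRUE }
        else {
          prev <- seq_len(i - 1L)
          gap <- sqrt((xs[prev] - px)^2 + (ys[prev] - py)^2) -
            radius[prev] - radius[i]
          ok <- all(gap >= config@minSeparation)
        }
        if (ok) { xs[i] <- px; ys[i] <- py; break }
      }
      if (!ok)
        stop("could not place ", nObj, " objects with minSeparation ",
             config@minSeparation, " um; enlarge the field or reduce counts")
    }

    zMax <- (config@nSlices - 1L) * config@sliceSpacing
    focalZ <- runif(nObj, 0, zMax)

    objects <- data.frame(
      object_id = seq_len(nObj),
      x_um = xs, y_um = ys, focal_z = focalZ,
      cell_count = cellCounts,
      radius_um = radius,
      true_class = classFromCellCount(pmax(cellCounts, 1L)),
      stringsAsFactors = FALSE)
    if (nObj == 0L)
      objects <- objects[0, , drop = FALSE]

    ## per-slice positional drift: seeded random walk in px, zero at slice 0
    drift <- do.call(rbind, lapply(seq_len(nObj), function(i) {
      steps <- config@nSlices
      if (config@driftSigma > 0 && steps > 1L) {
        dx <- cumsum(c(0, rnorm(steps - 1L, 0, config@driftSigma)))
        dy <- cumsum(c(0, rnorm(steps - 1L, 0, config@driftSigma)))
      } else dx <- dy <- numeric(steps)
      data.frame(object_id = i, slice = seq_len(steps) - 1L,
                 dx = dx, dy = dy)
    }))
    if (is.null(drift))
      drift <- data.frame(object_id = integer(0), slice = integer(0),
                          dx = numeric(0), dy = numeric(0))

    gt <- .buildGroundTruth(objects, drift, config)
    new("SyntheticScene", objects = objects, groundTruth = gt,
        drift = drift, config = config)
  })
}

## Ground-truth box half-width: visible radius plus one blur sigma, the
## 16%-contrast contour of the rendered edge profile.
.gtHalfWidth <- function(radiusUm, dz, config) {
  sigma <- config@blurBase + config@blurSlope * dz
  (radiusUm + sigma) / config@pixelSize
}

.buildGroundTruth <- function(objects, drift, config) {
  empty <- data.frame(slice = integer(0), object_id = integer(0),
                      x = numeric(0), y = numeric(0),
                      w = numeric(0), h = numeric(0),
                      label = character(0), stringsAsFactors = FALSE)
  if (!nrow(objects)) return(empty)
  W <- config@imageSize[1]; H <- config@imageSize[2]
  rows <- vector("list", config@nSlices)
  for (s in seq_len(config@nSlices) - 1L) {
    z <- s * config@sliceSpacing
    dz <- abs(z - objects$focal_z)
    vis <- which(dz <= config@candidateDepth)
    if (!length(vis)) next
    d <- drift[drift$slice == s, ]
    d <- d[match(objects$object_id[vis], d$object_id), ]
    cx <- objects$x_um[vis] / config@pixelSize + d$dx
    cy <- objects$y_um[vis] / config@pixelSize + d$dy
    hw <- .gtHalfWidth(objects$radius_um[vis], dz[vis], config)
    x0 <- pmax(cx - hw, 0); y0 <- pmax(cy - hw, 0)
    x1 <- pmin(cx + hw, W); y1 <- pmin(cy + hw, H)
    lab <- ifelse(dz[vis] <= config@dof, objects$true_class[vis], "candidate")
    df <- data.frame(slice = s, object_id = objects$object_id[vis],
                     x = x0, y = y0, w = x1 - x0, h = y1 - y0,
                     label = lab, stringsAsFactors = FALSE)
    rows[[s + 1L]] <- df[df$w >= 1 & df$h >= 1, , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Render a synthetic Z-stack
#'
#' Renders each slice of the scene as an 8-bit-style grayscale image on a
#' white background (intensity 1). Every object appears as a dark disk
#' with a Gaussian edge profile: the radial intensity deficit is
#' \code{A * pnorm((r - d) / sigma)}, where \code{sigma} (the edge
#' softness, in um) grows linearly with the object's defocus
#' \code{|slice_z - focal_z|} and the contrast \code{A} is attenuated as
#' \code{exp(-(dz / candidateDepth)^2)}. Object centres follow the
#' per-slice drift walk drawn by \code{\link{sampleScene}}, so rendered
#' positions agree exactly with the ground-truth boxes. Additive Gaussian
#' noise of sd \code{noiseSigma} is applied last, seeded independently of
#' scene sampling.
#'
#' @param scene A \code{\link[=SyntheticScene]{SyntheticScene}}.
#' @return A numeric array of dimension (width, height, nSlices) with
#'   values in [0, 1]; the first index is the x pixel coordinate.
#' @examples
#' sc <- sampleScene(sceneConfig(objectCounts = c(cell = 1, cluster = 0,
#'                                                colony = 0),
#'                               imageSize = c(96L, 96L), nSlices = 3L,
#'                               seed = 2))
#' stk <- renderStack(sc)
#' dim(stk)
#' @export
renderStack <- function(scene) {
  stopifnot(is(scene, "SyntheticScene"))
  config <- scene@config
  W <- config@imageSize[1]; H <- config@imageSize[2]
  stack <- array(1, dim = c(W, H, config@nSlices))
  objects <- scene@objects
  drift <- scene@drift
  for (s in seq_len(config@nSlices) - 1L) {
    img <- matrix(1, W, H)
    if (nrow(objects)) {
      z <- s * config@sliceSpacing
      d <- drift[drift$slice == s, ]
      for (i in seq_len(nrow(objects))) {
        dz <- abs(z - objects$focal_z[i])
        if (dz > config@candidateDepth) next
        sigmaPx <- (config@blurBase + config@blurSlope * dz) / config@pixelSize
        rPx <- objects$radius_um[i] / config@pixelSize
        A <- config@amplitude * exp(-(dz / config@candidateDepth)^2)
        di <- d[d$object_id == objects$object_id[i], ]
        cx <- objects$x_um[i] / config@pixelSize + di$dx
        cy <- objects$y_um[i] / config@pixelSize + di$dy
        ext <- rPx + 4 * sigmaPx
        ix <- max(1L, floor(cx - ext)):min(W, ceiling(cx + ext) + 1L)
        iy <- max(1L, floor(cy - ext)):min(H, ceiling(cy + ext) + 1L)
        if (!length(ix) || !length(iy)) next
        dx2 <- (ix - 0.5 - cx)^2
        dy2 <- (iy - 0.5 - cy)^2
        dist <- sqrt(outer(dx2, dy2, `+`))
        img[ix, iy] <- img[ix, iy] - A * pnorm((rPx - dist) / sigmaPx)
      }
    }
    stack[, , s + 1L] <- img
  }
  if (config@noiseSigma > 0) {
    stack <- .withSeed(config@seed + 1L,
      stack + array(rnorm(length(stack), 0, config@noiseSigma), dim(stack)))
  }
  stack[stack < 0] <- 0
  stack[stack > 1] <- 1
  stack
}

#' Stochastic clonal growth under drug inhibition
#'
#' Evolves the cell count of each object forward in time by a seeded
#' branching process: in every 1-hour step each cell divides independently
#' with probability \code{baseRate * (1 - inhibition(concentration))}.
#' Classes and radii are re-derived from the cell count at every
#' timepoint, so a single seeded cell can progress cell -> cluster ->
#' colony; at full inhibition counts never increase.
#'
#' @param objects Object table as in \code{sceneObjects}, or a
#'   \code{SyntheticScene}.
#' @param growth A \code{\link{growthConfig}}.
#' @param concentration Drug concentration in nM (>= 0).
#' @return Named list of object tables, one per timepoint (names are the
#'   timepoints in hours).
#' @examples
#' obj <- sceneObjects(sampleScene(sceneConfig(
#'   objectCounts = c(cell = 3, cluster = 0, colony = 0), seed = 5)))
#' ts <- simulateGrowth(obj, growthConfig(timepoints = c(0, 24, 48),
#'                                        seed = 5), concentration = 0)
#' sapply(ts, function(x) sum(x$cell_count))
#' @export
simulateGrowth <- function(objects, growth, concentration = 0) {
  if (is(objects, "SyntheticScene")) objects <- sceneObjects(objects)
  stopifnot(is(growth, "GrowthConfig"))
  validObject(growth)
  if (length(concentration) != 1L || is.na(concentration) || concentration < 0)
    stop("concentration must be a single non-negative value (nM)")
  inh <- growth@inhibition(concentration)
  if (inh < 0 || inh > 1) stop("inhibition factor must be in [0, 1]")
  p <- growth@baseRate * (1 - inh)
  p <- min(max(p, 0), 1)
  tp <- growth@timepoints
  unitRadius <- if (nrow(objects))
    objects$radius_um / sqrt(objects$cell_count) else numeric(0)

  .withSeed(growth@seed, {
    out <- vector("list", length(tp))
    names(out) <- as.character(tp)
    counts <- objects$cell_count
    now <- tp[1]
    snapshot <- function(counts) {
      o <- objects
      if (nrow(o)) {
        o$cell_count <- counts
        o$radius_um <- unitRadius * sqrt(counts)
        o$true_class <- classFromCellCount(counts)
      }
      o
    }
    out[[1]] <- snapshot(counts)
    for (k in seq_along(tp)[-1]) {
      span <- tp[k] - now
      wholeHours <- floor(span)
      frac <- span - wholeHours
      if (p > 0 && length(counts)) {
        for (h in seq_len(wholeHours))
          counts <- counts + rbinom(length(counts), counts, p)
        if (frac > 1e-9) {
          pf <- (1 + p)^frac - 1
          counts <- counts + rbinom(length(counts), counts, pf)
        }
      }
      now <- tp[k]
      out[[k]] <- snapshot(counts)
    }
    out
  })
}

#' Four-parameter logistic curve
#'
#' The sigmoidal dose-response model
#' \eqn{y = bottom + (top - bottom) / (1 + 10^{(logIC50 - x) \cdot hill})}
#' evaluated at \eqn{x = \log_{10}} concentration. With this
#' parameterization the response at \code{x = logIC50} is the midpoint
#' \code{(top + bottom) / 2}; inhibition curves (response falling with
#' concentration) have \code{hill < 0}.
#'
#' @param x Numeric vector of log10 concentrations.
#' @param top,bottom Upper/lower response asymptotes.
#' @param logIC50 log10 of the half-maximal concentration.
#' @param hill Hill slope (negative for inhibition curves).
#' @return Numeric vector of responses.
#' @examples
#' fourPL(log10(100), top = 1, bottom = 0, logIC50 = 1, hill = 1)
#' @export
fourPL <- function(x, top, bottom, logIC50, hill) {
  bottom + (top - bottom) / (1 + 10^((logIC50 - x) * hill))
}

#' Fractional growth inhibition as a function of concentration
#'
#' Convenience constructor of an inhibition function for
#' \code{\link{growthConfig}}: a Hill curve rising from 0 (no drug
#' effect) to 1 (full arrest) with half-maximal inhibition at
#' \code{ic50}.
#'
#' @param ic50 Concentration of half-maximal inhibition, nM.
#' @param hill Hill coefficient (> 0), default 1.
#' @return A function mapping concentration (nM) to inhibition in [0, 1].
#' @examples
#' f <- inhibition4PL(ic50 = 50)
#' f(c(0, 50, 1e6))
#' @export
inhibition4PL <- function(ic50, hill = 1) {
  force(ic50); force(hill)
  function(conc) ifelse(conc <= 0, 0, 1 / (1 + (ic50 / conc)^hill))
}

#' Simulate a normalized dose-response table
#'
#' Generates replicate normalized responses (clusters + colonies relative
#' to vehicle control) from a known four-parameter logistic truth with
#' seeded Gaussian noise, emulating the 5-point dilution-series design of
#' a drug-screening colony-forming assay.
#'
#' @param truth Named list or vector with elements \code{top},
#'   \code{bottom}, \code{logIC50}, \code{hill}.
#' @param concentrations Positive concentrations in nM.
#' @param nRep Replicates per concentration (>= 1), default 3.
#' @param noiseSd Sd of additive Gaussian noise on the response scale,
#'   default 0.05.
#' @param seed Integer seed.
#' @return A data.frame with columns \code{concentration},
#'   \code{replicate}, \code{response}.
#' @examples
#' simulateDoseResponse(list(top = 1, bottom = 0, logIC50 = log10(20),
#'                           hill = -1),
#'                      concentrations = 500 / 5^(0:4), nRep = 2,
#'                      noiseSd = 0, seed = 1)
#' @export
simulateDoseResponse <- function(truth, concentrations, nRep = 3L,
                                 noiseSd = 0.05, seed = 1L) {
  if (any(concentrations <= 0)) stop("concentrations must be positive (nM)")
  if (nRep < 1L) stop("nRep must be >= 1")
  truth <- as.list(truth)
  mu <- fourPL(log10(concentrations), truth$top, truth$bottom,
               truth$logIC50, truth$hill)
  .withSeed(seed, {
    df <- expand.grid(replicate = seq_len(nRep),
                      concentration = concentrations)
    df <- df[order(df$concentration, df$replicate), c(2, 1)]
    df$response <- rep(mu[order(concentrations)], each = nRep) +
      rnorm(nrow(df), 0, noiseSd)
    rownames(df) <- NULL
    df
  })
}

#' Training-set size after augmentation
#'
#' Bookkeeping for a detector training dataset in which every base image
#' is augmented into a fixed number of additional images: the total is
#' \code{nBase * (1 + nAugPerBase)}.
#'
#' @param nBase Number of base images (>= 0).
#' @param nAugPerBase Augmented copies per base image (>= 0).
#' @return Integer total number of training images.
#' @examples
#' planDataset(82, 2)
#' @export
planDataset <- function(nBase, nAugPerBase) {
  if (nBase < 0 || nAugPerBase < 0) stop("inputs must be non-negative")
  as.integer(nBase) * (1L + as.integer(nAugPerBase))
}
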