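#' @rdname DetectorConfig
#' @export
setClass("DetectorConfig",
  representation(intensityThreshold = "numeric", minArea = "numeric",
                 cellArea = "numeric", focusThreshold = "numeric",
                 confidenceThreshold = "numeric", nmsIou = "numeric"))

setValidity("DetectorConfig", function(object) {
  msg <- character()
  if (object@minArea > object@cellArea)
    msg <- c(msg, "minArea must not exceed cellArea")
  if (object@focusThreshold < 0) msg <- c(msg, "focusThreshold must be >= 0")
  if (object@confidenceThreshold < 0 || object@confidenceThreshold > 1)
    msg <- c(msg, "confidenceThreshold must be in [0,1]")
  if (object@nmsIou < 0 || object@nmsIou > 1)
    msg <- c(msg, "nmsIou must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Classical detector configuration
#'
#' Parameters of the reference blob detector: segmentation threshold
#' (adaptive Otsu by default), minimum component area, the pixel area of
#' one cell-equivalent (used to convert blob area to a cell count), the
#' focus-score threshold separating in-focus from candidate objects, the
#' confidence floor and the non-maximum-suppression IoU.
#'
#' Defaults are calibrated to the default \code{\link{sceneConfig}} optics
#' (1.5 um/px, 5 um cell radius); for other scene geometries build the
#' config with \code{\link{detectorConfigForScene}}.
#'
#' @param intensityThreshold Fixed darkness threshold on the
#'   background-flattened image, or \code{NA} (default) for adaptive Otsu.
#' @param minArea Minimum connected-component area in px^2 (default 12).
#' @param cellArea Area of one cell-equivalent in px^2
#'   (default \code{pi * (5 / 1.5)^2}).
#' @param focusThreshold Focus-score cut-off; blobs scoring below it are
#'   labelled \code{candidate} (if at least 2 cell-equivalents) or dropped.
#' @param confidenceThreshold Minimum detection confidence in [0, 1].
#' @param nmsIou Non-maximum-suppression IoU threshold (default 0.5).
#' @return A \code{DetectorConfig} object.
#' @aliases DetectorConfig-class DetectorConfig
#' @seealso \code{\link{detectSlice}}, \code{\link{detectorConfigForScene}}
#' @export
detectorConfig <- function(intensityThreshold = NA_real_, minArea = 12,
                           cellArea = pi * (5 / 1.5)^2,
                           focusThreshold = focusThresholdFor(1.95),
                           confidenceThreshold = 0.05, nmsIou = 0.5) {
  new("DetectorConfig",
      intensityThreshold = as.numeric(intensityThreshold),
      minArea = as.numeric(minArea), cellArea = as.numeric(cellArea),
      focusThreshold = as.numeric(focusThreshold),
      confidenceThreshold = as.numeric(confidenceThreshold),
      nmsIou = as.numeric(nmsIou))
}

setMethod("show", "DetectorConfig", function(object) {
  cat("DetectorConfig: threshold",
      if (is.na(object@intensityThreshold)) "adaptive (Otsu)"
      else object@intensityThreshold,
      "| minArea", object@minArea, "px^2 | cellArea",
      signif(object@cellArea, 4), "px^2\n")
  cat("  focusThreshold", signif(object@focusThreshold, 4),
      "| confidence >=", object@confidenceThreshold,
      "| NMS IoU", object@nmsIou, "\n")
})

#' Focus-score value of an edge of given softness
#'
#' Closed-form focus score produced by \code{\link{focusScore}} for a
#' large disk whose edge profile is \code{pnorm((r - d) / sigma)}: after
#' the detector's 3x3 mean smoothing, the peak central-difference gradient
#' relative to the contrast is
#' \code{(pnorm(2 / sigma) + pnorm(1 / sigma) - 1) / 3}. Used to translate
#' an optical blur width into a focus threshold.
#'
#' @param sigmaPx Edge softness in pixels.
#' @return The focus score of such an edge (1/px units).
#' @examples
#' focusThresholdFor(c(1, 2.6, 8))
#' @export
focusThresholdFor <- function(sigmaPx) {
  (pnorm(2 / sigmaPx) + pnorm(1 / sigmaPx) - 1) / 3
}

#' Detector configuration matched to a scene's optics
#'
#' Derives \code{cellArea} from the scene's cell radius and pixel size and
#' the focus threshold from its blur model: an object is accepted as
#' 
#' in-focus while its predicted edge softness is at most that of an object
#' defocused by \code{slack * dof}. The default slack below 1 deliberately
#' narrows the in-focus band: blob area (measured at half contrast)
#' inflates with blur, so borderline-defocused objects are safer labelled
#' candidate, while every object still presents at least one slice within
#' half the slice spacing of its focal plane where it scores sharp.
#'
#' @param scene A \code{\link{sceneConfig}} or
#'   \code{\link[=SyntheticScene]{SyntheticScene}}.
#' @param slack Multiple of the depth of field at which the focus
#'   threshold is placed (default 0.8).
#' @param ... Further arguments passed to \code{\link{detectorConfig}}.
#' @return A \code{DetectorConfig}.
#' @examples
#' detectorConfigForScene(sceneConfig())
#' @export
detectorConfigForScene <- function(scene, slack = 0.8, ...) {
  cfg <- if (is(scene, "SyntheticScene")) scene@config else scene
  stopifnot(is(cfg, "SceneConfig"))
  sigmaPx <- (cfg@blurBase + cfg@blurSlope * cfg@dof * slack) / cfg@pixelSize
  detectorConfig(cellArea = pi * (cfg@cellRadius / cfg@pixelSize)^2,
                 focusThreshold = focusThresholdFor(sigmaPx), ...)
}

## 3x3 mean filter with replicate padding; input/output matrices [x, y].
.meanFilter3 <- function(m) {
  W <- nrow(m); H <- ncol(m)
  if (W < 2L || H < 2L) return(m)
  p <- m[c(1L, seq_len(W), W), c(1L, seq_len(H), H)]
  out <- matrix(0, W, H)
  for (dx in 0:2) for (dy in 0:2)
    out <- out + p[dx + seq_len(W), dy + seq_len(H)]
  out / 9
}

#' Sharpness of the image content inside a bounding box
#'
#' Normalized high-frequency energy of the patch: the image is smoothed
#' with a 3x3 mean filter, central-difference gradients are taken, and the
#' peak gradient magnitude is divided by the patch's intensity range.
#' Constant patches score 0; the score is invariant to adding a constant
#' intensity offset and decreases monotonically with defocus blur.
#'
#' @param image Grayscale image matrix (first index = x).
#' @param box Named numeric vector or one-row data.frame with \code{x},
#'   \code{y}, \code{w}, \code{h} (pixels, 0-based, half-open).
#' @return Non-negative focus score (1/px units).
#' @examples
#' img <- matrix(1, 32, 32); img[10:20, 10:20] <- 0
#' focusScore(img, c(x = 5, y = 5, w = 22, h = 22))
#' @export
focusScore <- function(image, box) {
  box <- as.list(box)
  if (box$w <= 0 || box$h <= 0) stop("degenerate bounding box")
  W <- nrow(image); H <- ncol(image)
  ix <- max(1L, floor(box$x) + 1L):min(W, ceiling(box$x + box$w))
  iy <- max(1L, floor(box$y) + 1L):min(H, ceiling(box$y + box$h))
  if (length(ix) < 4L || length(iy) < 4L) stop("bounding box too small")
  patch <- .meanFilter3(image[ix, iy])
  rng <- diff(range(patch))
  if (rng < 1e-12) return(0)
  nx <- nrow(patch); ny <- ncol(patch)
  gx <- (patch[3:nx, 2:(ny - 1)] - patch[1:(nx - 2), 2:(ny - 1)]) / 2
  gy <- (patch[2:(nx - 1), 3:ny] - patch[2:(nx - 1), 1:(ny - 2)]) / 2
  max(sqrt(gx^2 + gy^2)) / rng
}

#' Segment one slice into candidate blobs
#'
#' Background-flattens the image (darkness = median intensity minus
#' intensity), thresholds it (Otsu by default), and extracts connected
#' components of at least \code{minArea} pixels. Each component is then
#' refined around its own peak contrast \code{M}: the bounding box is
#' taken from the connected region above \code{0.16 M} (the one-sigma
#' contour of a Gaussian edge) and the reported \code{area} is the number
#' of pixels above \code{0.5 M}, which for a blurred disk is a
#' blur-invariant estimate of the in-focus disk area.
#'
#' @param image Grayscale image matrix (first index = x), intensities in
#'   [0, 1], dark objects on a light background.
#' @param config A \code{\link{detectorConfig}}.
#' @return data.frame with columns \code{x}, \code{y}, \code{w}, \code{h}
#'   (pixel box, 0-based half-open), \code{area} (half-contrast pixel
#'   count) and \code{peak} (peak darkness contrast).
#' @export
segmentSlice <- function(image, config = detectorConfig()) {
  if (length(image) == 0L) stop("empty image")
  if (!is.matrix(image)) stop("image must be a matrix")
  W <- nrow(image); H <- ncol(image)
  empty <- data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                      h = numeric(0), area = numeric(0), peak = numeric(0))
  dark <- median(image) - image
  dark[dark < 0] <- 0
  if (max(dark) < 1e-9) return(empty)
  thr <- if (is.na(config@intensityThreshold))
    EBImage::otsu(EBImage::Image(dark), range = c(0, max(dark)))
  else config@intensityThreshold
  mask <- dark > thr
  if (!any(mask)) return(empty)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= config@minArea)
  if (!length(keep)) return(empty)

  out <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    idx <- which(lab == keep[k], arr.ind = TRUE)
    peakRel <- which.max(dark[idx])
    peakXY <- idx[peakRel, ]
    M <- dark[peakXY[1], peakXY[2]]
    ## refinement window: component extent plus a margin, grown until the
    ## 0.16 M contour of this blob is fully contained (a dim, strongly
    ## defocused blob can extend well beyond its above-threshold core)
    ext <- pmax(3L, ceiling(0.75 * c(diff(range(idx[, 1])) + 1L,
                                     diff(range(idx[, 2])) + 1L)))
    for (grow in 1:6) {
      wx <- max(1L, min(idx[, 1]) - ext[1]):min(W, max(idx[, 1]) + ext[1])
      wy <- max(1L, min(idx[, 2]) - ext[2]):min(H, max(idx[, 2]) + ext[2])
      sub <- dark[wx, wy, drop = FALSE]
      subMask <- sub >= 0.1587 * M
      subLab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(subMask)))
      own <- subLab[match(peakXY[1], wx), match(peakXY[2], wy)]
      if (own == 0) break
      sel <- which(subLab == own, arr.ind = TRUE)
      touches <- (min(sel[, 1]) == 1L && wx[1] > 1L) ||
        (max(sel[, 1]) == nrow(sub) && wx[length(wx)] < W) ||
        (min(sel[, 2]) == 1L && wy[1] > 1L) ||
        (max(sel[, 2]) == ncol(sub) && wy[length(wy)] < H)
      if (!touches) break
      ext <- ext * 2L
    }
    if (own == 0) next
    x0 <- wx[min(sel[, 1])] - 1; x1 <- wx[max(sel[, 1])]
    y0 <- wy[min(sel[, 2])] - 1; y1 <- wy[max(sel[, 2])]
    area <- sum(sub[sel] >= 0.5 * M)
    out[[k]] <- data.frame(x = x0, y = y0, w = x1 - x0, h = y1 - y0,
                           area = area, peak = M)
  }
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) return(empty)
  res <- unique(res)
  rownames(res) <- NULL
  res
}

#' Classify a blob from its area and focus score
#'
#' Converts the half-contrast blob area to cell-equivalents
#' \code{n = round(area / cellArea)} and applies the hierarchical class
#' scheme: an in-focus blob (focus score at or above the threshold) is a
#' \code{cell} (n = 1), \code{cluster} (2--14) or \code{colony} (>= 15);
#' an out-of-focus blob of at least 2 cell-equivalents is a
#' \code{candidate}; an out-of-focus blob smaller than that is discarded
#' (returns \code{NULL}). Confidence is the bounded product of the focus
#' margin and the size margin (distance of \code{area / cellArea} from the
#' nearest class boundary), always strictly below 1.
#'
#' @param area Blob area in px^2 (> 0).
#' @param focus Focus score of the blob (>= 0).
#' @param config A \code{\link{detectorConfig}}.
#' @return A list with \code{label} and \code{confidence}, or \code{NULL}
#'   when the blob is rejected.
#' @examples
#' cfg <- detectorConfig()
#' classifyBlob(area = 10 * cfg@cellArea, focus = cfg@focusThreshold * 2,
#'              config = cfg)
#' @export
classifyBlob <- function(area, focus, config = detectorConfig()) {
  if (area <= 0) stop("area must be positive")
  nCont <- area / config@cellArea
  n <- max(1L, as.integer(roundHalfUp(nCont)))
  thr <- config@focusThreshold
  focusComp <- if (thr <= 0) 1 else focus / (focus + thr)
  inFocus <- focus >= thr
  if (inFocus) {
    label <- classFromCellCount(n)
    bounds <- switch(label,
                     cell = c(0.5, 1.5),
                     cluster = c(1.5, 14.5),
                     colony = c(14.5, Inf))
    sizeComp <- min(1, 2 * min(nCont - bounds[1], bounds[2] - nCont))
    conf <- focusComp * max(sizeComp, 0)
  } else {
    if (n < 2L) return(NULL)
    sizeComp <- min(1, (nCont - 1.5) / 2)
    conf <- (1 - focusComp) * max(sizeComp, 0)
  }
  list(label = if (inFocus) label else "candidate",
       confidence = min(conf, 0.999))
}

#' Non-maximum suppression
#'
#' Greedy suppression of redundant detections on one slice: detections are
#' visited in order of decreasing confidence and any detection overlapping
#' an already-kept one with IoU at or above the threshold is discarded.
#' Idempotent.
#'
#' @param detections Detections data.frame (\code{x,y,w,h,label,conf}).
#' @param iouThreshold Suppression IoU in [0, 1].
#' @return The surviving subset, in decreasing confidence order.
#' @export
nmsFilter <- function(detections, iouThreshold = 0.5) {
  if (!nrow(detections)) return(detections)
  ord <- order(-detections$conf, detections$x, detections$y)
  detections <- detections[ord, , drop = FALSE]
  keep <- logical(nrow(detections))
  for (i in seq_len(nrow(detections))) {
    if (any(keep)) {
      ious <- boxIoU(detections[i, ], detections[keep, , drop = FALSE])
      if (any(ious >= iouThreshold)) next
    }
    keep[i] <- TRUE
  }
  out <- detections[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect and classify objects on one slice
#'
#' Reference classical detector: segment (\code{\link{segmentSlice}}),
#' score sharpness (\code{\link{focusScore}}), classify
#' (\code{\link{classifyBlob}}), drop detections below the confidence
#' threshold, and apply non-maximum suppression. Any component with the
#' same image -> detections contract (for example one reading a file of
#' precomputed neural-network detections, see
#' \code{\link{readYoloBoxes}}) can substitute this function upstream of
#' the tracker.
#'
#' @param image Grayscale image matrix (first index = x).
#' @param config A \code{\link{detectorConfig}}.
#' @param sliceIndex 0-based slice index attached to the output.
#' @return Detections data.frame with columns \code{slice}, \code{x},
#'   \code{y}, \code{w}, \code{h}, \code{label}, \code{conf}.
#' @seealso \code{\link{detectStack}}, \code{\link{trackStack}}
#' @export
detectSlice <- function(image, config = detectorConfig(), sliceIndex = 0L) {
  blobs <- segmentSlice(image, config)
  if (!nrow(blobs)) return(.emptyDetections())
  rows <- vector("list", nrow(blobs))
  for (i in seq_len(nrow(blobs))) {
    fs <- focusScore(image, blobs[i, c("x", "y", "w", "h")])
    cl <- classifyBlob(blobs$area[i], fs, config)
    if (is.null(cl)) next
    if (cl$confidence < config@confidenceThreshold) next
    rows[[i]] <- data.frame(slice = as.integer(sliceIndex),
                            x = blobs$x[i], y = blobs$y[i],
                            w = blobs$w[i], h = blobs$h[i],
                            label = cl$label, conf = cl$confidence,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(.emptyDetections())
  out <- nmsFilter(out, config@nmsIou)
  out$slice <- as.integer(out$slice)
  rownames(out) <- NULL
  out
}

#' Detect objects on every slice of a Z-stack
#'
#' @param stack Numeric array (width, height, nSlices) as returned by
#'   \code{\link{renderStack}}, or a list of image matrices.
#' @param config A \code{\link{detectorConfig}}.
#' @return Detections data.frame over all slices (0-based \code{slice}).
#' @export
detectStack <- function(stack, config = detectorConfig()) {
  slices <- if (is.list(stack)) stack
  else lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  out <- do.call(rbind, lapply(seq_along(slices), function(i)
    detectSlice(slices[[i]], config, sliceIndex = i - 1L)))
  if (is.null(out)) return(.emptyDetections())
  rownames(out) <- NULL
  out
}
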