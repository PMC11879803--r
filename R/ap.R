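## All-point interpolated area under a precision-recall curve.
.apFromPR <- function(tp, fp, nGt) {
  if (nGt == 0L) return(NA_real_)
  if (!length(tp)) return(0)
  cumTp <- cumsum(tp); cumFp <- cumsum(fp)
  rec <- cumTp / nGt
  prec <- cumTp / (cumTp + cumFp)
  mrec <- c(0, rec)
  mpre <- c(1, prec)
  for (i in rev(seq_along(mpre))[-1])
    mpre[i] <- max(mpre[i], mpre[i + 1])
  sum(diff(mrec) * mpre[-1])
}

#' Detector evaluation: per-class AP50, mAP50 and confusion matrix
#'
#' Matches detections to ground-truth boxes per class by confidence-ranked
#' greedy assignment at the given IoU threshold (each ground-truth box is
#' matched at most once), integrates the all-point interpolated
#' precision-recall curve into the average precision, and averages across
#' classes with ground-truth instances into the mAP. The confusion matrix
#' assigns every detection to the class of its best-IoU ground-truth box
#' (any class, IoU at or above the threshold, greedy by decreasing IoU) or
#' to \code{background}; ground-truth boxes left unmatched count in the
#' \code{background} prediction row.
#'
#' @param detections Detections data.frame (\code{slice, x, y, w, h,
#'   label, conf}).
#' @param gtBoxes Ground-truth boxes data.frame (\code{slice, x, y, w, h,
#'   label}).
#' @param iouThreshold Match IoU threshold (default 0.5).
#' @param classes Classes to evaluate (default \code{\link{objectClasses}}).
#' @return List with \code{perClass} (data.frame: class, images,
#'   instances, n_detections, precision, recall, ap50), \code{map50}
#'   (mean over classes with instances) and \code{confusion} (matrix,
#'   prediction rows x ground-truth columns, including background).
#' @seealso \code{\link{detectStack}}
#' @export
averagePrecision <- function(detections, gtBoxes, iouThreshold = 0.5,
                             classes = objectClasses()) {
  perClass <- do.call(rbind, lapply(classes, function(cl) {
    det <- detections[detections$label == cl, , drop = FALSE]
    det <- det[order(-det$conf), , drop = FALSE]
    gt <- gtBoxes[gtBoxes$label == cl, , drop = FALSE]
    nGt <- nrow(gt)
    tp <- fp <- numeric(nrow(det))
    gtUsed <- logical(nGt)
    for (i in seq_len(nrow(det))) {
      cand <- which(gt$slice == det$slice[i] & !gtUsed)
      hit <- FALSE
      if (length(cand)) {
        ious <- boxIoU(det[i, c("x", "y", "w", "h")],
                       gt[cand, , drop = FALSE])
        best <- which.max(ious)
        if (ious[best] >= iouThreshold) {
          gtUsed[cand[best]] <- TRUE
          hit <- TRUE
        }
      }
      if (hit) tp[i] <- 1 else fp[i] <- 1
    }
    data.frame(class = cl,
               images = length(unique(gt$slice)),
               instances = nGt,
               n_detections = nrow(det),
               precision = if (nrow(det)) sum(tp) / nrow(det) else NA_real_,
               recall = if (nGt) sum(tp) / nGt else NA_real_,
               ap50 = .apFromPR(tp, fp, nGt),
               stringsAsFactors = FALSE)
  }))
  rownames(perClass) <- NULL
  withGt <- perClass$instances > 0
  map50 <- if (any(withGt)) mean(perClass$ap50[withGt]) else NA_real_
  list(perClass = perClass, map50 = map50,
       confusion = .confusionMatrix(detections, gtBoxes, iouThreshold,
                                    classes))
}

.confusionMatrix <- function(detections, gtBoxes, iouThreshold, classes) {
  lev <- c(classes, "background")
  cm <- matrix(0L, length(lev), length(lev), dimnames = list(
    prediction = lev, truth = lev))
  for (s in sort(unique(c(detections$slice, gtBoxes$slice)))) {
    det <- detections[detections$slice == s, , drop = FALSE]
    gt <- gtBoxes[gtBoxes$slice == s, , drop = FALSE]
    detUsed <- logical(nrow(det)); gtUsed <- logical(nrow(gt))
    if (nrow(det) && nrow(gt)) {
      iou <- iouMatrix(det, gt)
      cand <- which(iou >= iouThreshold, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(-iou[cand]), , drop = FALSE]
        for (r in seq_len(nrow(cand))) {
          i <- cand[r, 1]; j <- cand[r, 2]
          if (detUsed[i] || gtUsed[j]) next
          detUsed[i] <- TRUE; gtUsed[j] <- TRUE
          cm[det$label[i], gt$label[j]] <- cm[det$label[i], gt$label[j]] + 1L
        }
      }
    }
    for (i in which(!detUsed))
      cm[det$label[i], "background"] <- cm[det$label[i], "background"] + 1L
    for (j in which(!gtUsed))
      cm["background", gt$label[j]] <- cm["background", gt$label[j]] + 1L
  }
  cm
}
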