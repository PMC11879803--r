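## Split a long-format track table into a named list of per-track tables.
.trackSplit <- function(tracks) {
  if (!nrow(tracks)) return(list())
  split(tracks, tracks$track_id)
}

## Track-level class of every track in a table (max over entry labels);
## tables without a label column get class "all".
.trackClasses <- function(tracks) {
  if (!nrow(tracks)) return(character(0))
  if (!"label" %in% names(tracks))
    return(setNames(rep("all", length(unique(tracks$track_id))),
                    sort(unique(tracks$track_id))))
  vapply(.trackSplit(tracks), classifyTrack, character(1))
}

.filterTracksByClass <- function(tracks, class) {
  if (identical(class, "all") || !nrow(tracks)) return(tracks)
  cls <- .trackClasses(tracks)
  keep <- names(cls)[cls == class]
  tracks[as.character(tracks$track_id) %in% keep, , drop = FALSE]
}

#' Identity measures for multi-object tracking
#'
#' Computes IDTP/IDFP/IDFN by a single global minimum-cost bipartite
#' matching between whole ground-truth and hypothesis trajectories: a
#' frame counts towards a pairing's overlap when both trajectories have a
#' box on that slice with IoU at or above the threshold; the matching
#' maximizes the total overlapped frames. IDTP is that optimum, IDFN the
#' remaining ground-truth frames, IDFP the remaining hypothesis frames;
#' IDF1 = 2 IDTP / (2 IDTP + IDFP + IDFN), IDP = IDTP / (IDTP + IDFP),
#' IDR = IDTP / (IDTP + IDFN).
#'
#' @param gt,hyp Track tables in long format (\code{track_id, slice, x, y,
#'   w, h}).
#' @param iouThreshold Frame-match IoU threshold (default 0.5).
#' @return List with \code{idtp}, \code{idfp}, \code{idfn}, \code{idf1},
#'   \code{idp}, \code{idr}.
#' @seealso \code{\link{evaluateTracking}}
#' @export
idMeasures <- function(gt, hyp, iouThreshold = 0.5) {
  gtT <- .trackSplit(gt); hyT <- .trackSplit(hyp)
  nG <- length(gtT); nH <- length(hyT)
  totalGt <- nrow(gt); totalHyp <- nrow(hyp)
  idtp <- 0
  if (nG && nH) {
    overlap <- matrix(0, nG, nH)
    for (i in seq_len(nG)) for (j in seq_len(nH)) {
      common <- intersect(gtT[[i]]$slice, hyT[[j]]$slice)
      if (!length(common)) next
      a <- gtT[[i]][match(common, gtT[[i]]$slice), ]
      b <- hyT[[j]][match(common, hyT[[j]]$slice), ]
      iou <- vapply(seq_along(common), function(k)
        boxIoU(a[k, c("x", "y", "w", "h")], b[k, , drop = FALSE]),
        numeric(1))
      overlap[i, j] <- sum(iou >= iouThreshold)
    }
    m <- solveAssignment(-overlap, forbidden = 1e6)
    if (nrow(m)) idtp <- sum(overlap[m])
  }
  idfn <- totalGt - idtp
  idfp <- totalHyp - idtp
  den <- 2 * idtp + idfp + idfn
  list(idtp = idtp, idfp = idfp, idfn = idfn,
       idf1 = if (den > 0) 2 * idtp / den else 0,
       idp = if (idtp + idfp > 0) idtp / (idtp + idfp) else 0,
       idr = if (idtp + idfn > 0) idtp / (idtp + idfn) else 0)
}

#' Frame-level GT/hypothesis correspondence (CLEAR-style)
#'
#' Sequential per-slice matching: pairs matched on the previous slice are
#' kept while both boxes persist with IoU at or above the threshold; the
#' remaining boxes are matched per slice by a minimum-cost assignment on
#' 1 - IoU. This is the correspondence underlying track coverage and ID
#' switch counting.
#'
#' @inheritParams idMeasures
#' @return data.frame with \code{slice}, \code{gt_id}, \code{hyp_id}, one
#'   row per matched frame.
#' @export
clearMatching <- function(gt, hyp, iouThreshold = 0.5) {
  out <- list()
  prev <- list()                        # gt_id (character) -> hyp_id
  slices <- sort(unique(gt$slice))
  for (s in slices) {
    g <- gt[gt$slice == s, , drop = FALSE]
    h <- hyp[hyp$slice == s, , drop = FALSE]
    if (!nrow(g)) next
    matchedG <- integer(0); matchedH <- integer(0)
    pairs <- list()
    ## keep persisting pairs first (in stable id order)
    for (gid in as.character(sort(unique(g$track_id)))) {
      hid <- prev[[gid]]
      if (is.null(hid)) next
      gi <- which(as.character(g$track_id) == gid)[1]
      hi <- which(as.character(h$track_id) == as.character(hid))
      if (!length(hi) || hi[1] %in% matchedH) next
      iou <- boxIoU(g[gi, c("x", "y", "w", "h")], h[hi[1], , drop = FALSE])
      if (iou >= iouThreshold) {
        pairs[[length(pairs) + 1L]] <-
          data.frame(slice = s, gt_id = g$track_id[gi],
                     hyp_id = h$track_id[hi[1]])
        matchedG <- c(matchedG, gi); matchedH <- c(matchedH, hi[1])
      }
    }
    gRem <- setdiff(seq_len(nrow(g)), matchedG)
    hRem <- setdiff(seq_len(nrow(h)), matchedH)
    if (length(gRem) && length(hRem)) {
      iou <- iouMatrix(g[gRem, , drop = FALSE], h[hRem, , drop = FALSE])
      cost <- 1 - iou
      cost[iou < iouThreshold] <- 1e6
      m <- solveAssignment(cost, forbidden = 1e6)
      if (nrow(m))
        pairs[[length(pairs) + 1L]] <-
          data.frame(slice = s, gt_id = g$track_id[gRem[m[, "row"]]],
                     hyp_id = h$track_id[hRem[m[, "col"]]])
    }
    if (length(pairs)) {
      pr <- do.call(rbind, pairs)
      out[[length(out) + 1L]] <- pr
      for (r in seq_len(nrow(pr)))
        prev[[as.character(pr$gt_id[r])]] <- pr$hyp_id[r]
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(slice = integer(0), gt_id = integer(0),
                      hyp_id = integer(0))
  res
}

#' Coverage category of a ground-truth track
#'
#' Classifies a trajectory by the fraction of its frames matched by the
#' tracker: at least 80\% mostly tracked, at most 20\% mostly lost,
#' anything in between partially tracked.
#'
#' @param matchedFrames Number of matched frames (>= 0).
#' @param totalFrames Number of ground-truth frames (> 0).
#' @return One of \code{"mostly_tracked"}, \code{"partially_tracked"},
#'   \code{"mostly_lost"}.
#' @examples
#' trackCoverage(5, 10)
#' @export
trackCoverage <- function(matchedFrames, totalFrames) {
  if (totalFrames <= 0) stop("empty ground-truth track")
  r <- matchedFrames / totalFrames
  if (r >= 0.8) "mostly_tracked"
  else if (r <= 0.2) "mostly_lost"
  else "partially_tracked"
}

#' Count identity switches
#'
#' An ID switch is an event where the hypothesis identity matched to a
#' ground-truth object changes between that object's consecutive matched
#' frames, under the sequential correspondence of
#' \code{\link{clearMatching}}.
#'
#' @inheritParams idMeasures
#' @return Non-negative integer count of switches.
#' @export
idSwitches <- function(gt, hyp, iouThreshold = 0.5) {
  fm <- clearMatching(gt, hyp, iouThreshold)
  if (!nrow(fm)) return(0L)
  sum(vapply(split(fm, fm$gt_id), function(g) {
    g <- g[order(g$slice), ]
    sum(g$hyp_id[-1] != g$hyp_id[-nrow(g)])
  }, numeric(1)))
}

#' Full tracking evaluation against ground truth
#'
#' Computes identity measures, coverage counts and ID switches for one
#' dataset, optionally restricted to tracks of one class (the track-level
#' class is the hierarchical maximum of the entry labels; only ground
#' truth and hypotheses of that class are then compared, as in class-wise
#' benchmark tables).
#'
#' @inheritParams idMeasures
#' @param class \code{"all"} (default) or one of
#'   \code{\link{objectClasses}}.
#' @return A \code{\link[=MOTScores]{MOTScores}} object.
#' @export
evaluateTracking <- function(gt, hyp, iouThreshold = 0.5, class = "all") {
  gt <- .filterTracksByClass(gt, class)
  hyp <- .filterTracksByClass(hyp, class)
  idm <- idMeasures(gt, hyp, iouThreshold)
  fm <- clearMatching(gt, hyp, iouThreshold)
  gtT <- .trackSplit(gt)
  cov <- vapply(names(gtT), function(id) {
    matched <- sum(fm$gt_id == gtT[[id]]$track_id[1])
    trackCoverage(matched, nrow(gtT[[id]]))
  }, character(1))
  new("MOTScores",
      idtp = idm$idtp, idfp = idm$idfp, idfn = idm$idfn,
      idf1 = idm$idf1, idp = idm$idp, idr = idm$idr,
      nObjects = length(gtT),
      mostlyTracked = sum(cov == "mostly_tracked"),
      partiallyTracked = sum(cov == "partially_tracked"),
      mostlyLost = sum(cov == "mostly_lost"),
      idSwitches = as.numeric(idSwitches(gt, hyp, iouThreshold)),
      evalClass = class)
}

#' Average per-dataset tracking scores
#'
#' Produces the "Average" rows of a benchmark-style score table: the
#' arithmetic mean of every column across datasets, per class, plus
#' tracked-share percentages derived from the averaged counts
#' (\code{100 * mean(MT) / mean(n)} and so on). Score means are reported
#' unrounded and rounded (half-up) to 3 decimals; percentages to 1
#' decimal.
#'
#' @param scores data.frame with columns \code{dataset}, \code{class},
#'   \code{n_objects}, \code{mostly_tracked}, \code{partially_tracked},
#'   \code{mostly_lost}, \code{idf1}, \code{idp}, \code{idr} (one row per
#'   dataset x class), e.g. stacked \code{as.data.frame(MOTScores)} rows.
#' @return data.frame with one row per class: unrounded means, rounded
#'   means (\code{*_rounded}) and \code{mt_percent}, \code{pt_percent},
#'   \code{ml_percent}.
#' @export
summarizeScores <- function(scores) {
  need <- c("class", "n_objects", "mostly_tracked", "partially_tracked",
            "mostly_lost", "idf1", "idp", "idr")
  if (!all(need %in% names(scores)))
    stop("scores must contain columns: ", paste(need, collapse = ", "))
  if ("dataset" %in% names(scores)) {
    classSets <- split(scores$class, scores$dataset)
    ref <- sort(unique(scores$class))
    if (!all(vapply(classSets, function(x)
      identical(sort(unique(x)), ref), logical(1))))
      stop("inconsistent class sets across datasets")
  }
  out <- do.call(rbind, lapply(split(scores, scores$class), function(g) {
    m <- vapply(g[, setdiff(need, "class")], mean, numeric(1))
    data.frame(class = g$class[1],
               n_objects = m[["n_objects"]],
               mostly_tracked = m[["mostly_tracked"]],
               partially_tracked = m[["partially_tracked"]],
               mostly_lost = m[["mostly_lost"]],
               idf1 = m[["idf1"]], idp = m[["idp"]], idr = m[["idr"]],
               idf1_rounded = roundHalfUp(m[["idf1"]], 3),
               idp_rounded = roundHalfUp(m[["idp"]], 3),
               idr_rounded = roundHalfUp(m[["idr"]], 3),
               mt_percent = roundHalfUp(100 * m[["mostly_tracked"]] /
                                          m[["n_objects"]], 1),
               pt_percent = roundHalfUp(100 * m[["partially_tracked"]] /
                                          m[["n_objects"]], 1),
               ml_percent = roundHalfUp(100 * m[["mostly_lost"]] /
                                          m[["n_objects"]], 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Joint detection-and-tracking optimization objective
#'
#' The product of IDF1 and the fraction of ground-truth objects that are
#' mostly or partially tracked. Including the tracked share emphasizes
#' recall: a tracker scoring well must both keep identities and account
#' for most objects.
#'
#' @param scores A \code{\link[=MOTScores]{MOTScores}} object or a list /
#'   one-row data.frame with \code{idf1}, \code{mostly_tracked},
#'   \code{partially_tracked}, \code{n_objects}.
#' @return Objective value in [0, 1].
#' @examples
#' trackingObjective(list(idf1 = 0.5, mostly_tracked = 5,
#'                        partially_tracked = 0, n_objects = 10))
#' @export
trackingObjective <- function(scores) {
  if (is(scores, "MOTScores"))
    scores <- list(idf1 = scores@idf1, mostly_tracked = scores@mostlyTracked,
                   partially_tracked = scores@partiallyTracked,
                   n_objects = scores@nObjects)
  if (scores$n_objects <= 0) stop("n_objects must be positive")
  scores$idf1 * (scores$mostly_tracked + scores$partially_tracked) /
    scores$n_objects
}

#' Seeded random search over detector/tracker hyperparameters
#'
#' Samples parameter vectors uniformly from a box-constrained space,
#' evaluates each with a user-supplied objective function, and returns the
#' best point and the full search history. Deterministic given the seed
#' and a deterministic objective; any search backend honouring the same
#' interface may substitute it.
#'
#' @param space Named list of length-2 numeric ranges, e.g.
#'   \code{list(maxGap = c(0, 5), matchIouHigh = c(0.1, 0.9))}.
#' @param evaluate Function taking a named list of parameters and
#'   returning a single numeric objective (larger is better).
#' @param nIter Number of evaluations (default 100).
#' @param seed Integer seed.
#' @return List with \code{bestParams} (named list), \code{bestValue} and
#'   \code{history} (data.frame of sampled parameters and objectives).
#' @export
tuneParameters <- function(space, evaluate, nIter = 100L, seed = 1L) {
  if (!length(space)) stop("empty parameter space")
  stopifnot(all(vapply(space, length, integer(1)) == 2L))
  .withSeed(seed, {
    draws <- as.data.frame(lapply(space, function(rng)
      runif(nIter, rng[1], rng[2])))
    obj <- vapply(seq_len(nIter), function(i)
      evaluate(as.list(draws[i, , drop = FALSE])), numeric(1))
    history <- cbind(iteration = seq_len(nIter), draws, objective = obj)
    best <- which.max(obj)
    list(bestParams = as.list(draws[best, , drop = FALSE]),
         bestValue = obj[best], history = history)
  })
}
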