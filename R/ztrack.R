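#' Intersection over union of bounding boxes
#'
#' Boxes are axis-aligned, given as \code{x, y, w, h} in pixels with the
#' half-open convention \code{[x, x + w)}. \code{boxIoU} compares one box
#' against each row of a table; \code{iouMatrix} computes the full
#' pairwise matrix between two tables.
#'
#' @param a Named vector or one-row data.frame with \code{x,y,w,h}.
#' @param b data.frame of boxes.
#' @return \code{boxIoU}: numeric vector of IoU values in [0, 1].
#' @examples
#' boxIoU(c(x = 0, y = 0, w = 10, h = 10),
#'        data.frame(x = 5, y = 0, w = 10, h = 10))
#' @export
boxIoU <- function(a, b) {
  a <- as.list(a)
  ix <- pmax(0, pmin(a$x + a$w, b$x + b$w) - pmax(a$x, b$x))
  iy <- pmax(0, pmin(a$y + a$h, b$y + b$h) - pmax(a$y, b$y))
  inter <- ix * iy
  union <- a$w * a$h + b$w * b$h - inter
  ifelse(union > 0, inter / union, 0)
}

#' @rdname boxIoU
#' @param A,B data.frames of boxes (\code{x,y,w,h}).
#' @return \code{iouMatrix}: an \code{nrow(A) x nrow(B)} matrix.
#' @export
iouMatrix <- function(A, B) {
  if (!nrow(A) || !nrow(B)) return(matrix(0, nrow(A), nrow(B)))
  m <- vapply(seq_len(nrow(B)), function(j)
    boxIoU(B[j, c("x", "y", "w", "h")], A), numeric(nrow(A)))
  matrix(m, nrow = nrow(A), ncol = nrow(B))
}

#' @rdname TrackerConfig
#' @export
setClass("TrackerConfig",
  representation(highConf = "numeric", lowConf = "numeric",
                 matchIouHigh = "numeric", matchIouLow = "numeric",
                 maxGap = "integer", minLength = "integer"))

setValidity("TrackerConfig", function(object) {
  msg <- character()
  if (object@lowConf > object@highConf)
    msg <- c(msg, "lowConf must not exceed highConf")
  rng <- c(object@highConf, object@lowConf, object@matchIouHigh,
           object@matchIouLow)
  if (any(rng < 0 | rng > 1)) msg <- c(msg, "thresholds must lie in [0,1]")
  if (object@maxGap < 0L) msg <- c(msg, "maxGap must be >= 0")
  if (object@minLength < 1L) msg <- c(msg, "minLength must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Z-axis tracker configuration
#'
#' Parameters of the two-stage IoU association: detections at or above
#' \code{highConf} drive the first association stage (and may start new
#' tracks); detections between \code{lowConf} and \code{highConf} are only
#' used in the second, more permissive stage to keep existing tracks
#' alive, in the spirit of two-stage trackers such as ByteTrack/BoT-SORT.
#' A track missing from more than \code{maxGap} consecutive slices is
#' terminated; within the gap it remains eligible for re-association.
#' There is no motion model: the predicted box is the last observed box,
#' appropriate for the quasi-static drift of objects along a Z-stack.
#'
#' @param highConf First-stage confidence threshold (default 0.35).
#' @param lowConf Second-stage confidence floor (default 0.05).
#' @param matchIouHigh Minimum IoU accepted in stage 1 (default 0.15; the
#'   permissive gate absorbs the large box-scale changes of an object
#'   defocusing between adjacent slices).
#' @param matchIouLow Minimum IoU accepted in stage 2 (default 0.4).
#' @param maxGap Slices a track may go unmatched before termination
#'   (default 3).
#' @param minLength Minimum number of entries for a track to be kept
#'   (default 1).
#' @return A \code{TrackerConfig} object.
#' @aliases TrackerConfig-class TrackerConfig
#' @seealso \code{\link{trackStack}}, \code{\link{associateDetections}}
#' @export
trackerConfig <- function(highConf = 0.35, lowConf = 0.05,
                          matchIouHigh = 0.15, matchIouLow = 0.4,
                          maxGap = 3L, minLength = 1L) {
  new("TrackerConfig", highConf = as.numeric(highConf),
      lowConf = as.numeric(lowConf),
      matchIouHigh = as.numeric(matchIouHigh),
      matchIouLow = as.numeric(matchIouLow),
      maxGap = as.integer(maxGap), minLength = as.integer(minLength))
}

setMethod("show", "TrackerConfig", function(object) {
  cat("TrackerConfig: conf high/low", object@highConf, "/", object@lowConf,
      "| IoU high/low", object@matchIouHigh, "/", object@matchIouLow,
      "| maxGap", object@maxGap, "| minLength", object@minLength, "\n")
})

#' Two-stage association of detections to open tracks
#'
#' Stage 1 matches detections with confidence at or above
#' \code{highConf} to the tracks' last observed boxes by a globally
#' cost-optimal assignment on cost 1 - IoU, accepting pairs with IoU at
#' least \code{matchIouHigh}. Stage 2 matches the tracks left over to the
#' remaining low-confidence detections (confidence in
#' [\code{lowConf}, \code{highConf})) at IoU at least \code{matchIouLow}.
#' Each stage's assignment is the exact minimum-cost solution.
#'
#' @param trackBoxes data.frame of open tracks' predicted boxes with
#'   columns \code{track_id, x, y, w, h}.
#' @param detections Detections data.frame for a single slice
#'   (\code{x, y, w, h, conf}; all \code{slice} values equal if present).
#' @param config A \code{\link{trackerConfig}}.
#' @return List with \code{matches} (data.frame \code{track_id},
#'   \code{det} row index into \code{detections}, \code{stage}),
#'   \code{unmatchedTracks} (track ids) and \code{unmatchedDetections}
#'   (row indices of unmatched detections with confidence >=
#'   \code{highConf}; low-confidence leftovers are discarded).
#' @export
associateDetections <- function(trackBoxes, detections,
                                config = trackerConfig()) {
  if (nrow(detections) && "slice" %in% names(detections) &&
      length(unique(detections$slice)) > 1L)
    stop("detections must all belong to one slice")
  BIG <- 1e6
  matchCost <- function(tb, det, minIou) {
    iou <- iouMatrix(tb, det)
    cost <- 1 - iou
    cost[iou < minIou] <- BIG
    cost
  }
  highIdx <- which(detections$conf >= config@highConf)
  lowIdx <- which(detections$conf >= config@lowConf &
                  detections$conf < config@highConf)
  matches <- data.frame(track_id = integer(0), det = integer(0),
                        stage = integer(0))
  openIds <- trackBoxes$track_id

  if (nrow(trackBoxes) && length(highIdx)) {
    cost <- matchCost(trackBoxes, detections[highIdx, , drop = FALSE],
                      config@matchIouHigh)
    m <- solveAssignment(cost, forbidden = BIG)
    if (nrow(m))
      matches <- rbind(matches,
                       data.frame(track_id = trackBoxes$track_id[m[, "row"]],
                                  det = highIdx[m[, "col"]], stage = 1L))
  }
  remTracks <- trackBoxes[!trackBoxes$track_id %in% matches$track_id, ,
                          drop = FALSE]
  if (nrow(remTracks) && length(lowIdx)) {
    cost <- matchCost(remTracks, detections[lowIdx, , drop = FALSE],
                      config@matchIouLow)
    m <- solveAssignment(cost, forbidden = BIG)
    if (nrow(m))
      matches <- rbind(matches,
                       data.frame(track_id = remTracks$track_id[m[, "row"]],
                                  det = lowIdx[m[, "col"]], stage = 2L))
  }
  list(matches = matches,
       unmatchedTracks = setdiff(openIds, matches$track_id),
       unmatchedDetections = setdiff(highIdx, matches$det))
}

#' Merge per-slice detections into unique 2.5D object tracks
#'
#' Runs two-stage IoU association slice by slice along the Z axis:
#' matched tracks extend and reset their gap counter; unmatched tracks
#' accumulate gap and are terminated once the gap exceeds \code{maxGap}
#' (while within the gap they can be re-identified); unmatched
#' high-confidence detections start new tracks. Track ids are unique and
#' never reused, every detection is used at most once, and the result is
#' invariant to the ordering of detections within a slice (detections are
#' canonicalized by decreasing confidence, then position, before
#' association).
#'
#' @param detections Detections data.frame over slices (\code{slice, x, y,
#'   w, h, label, conf}), or a list of per-slice data.frames.
#' @param config A \code{\link{trackerConfig}}.
#' @return Tracks in long format: data.frame with \code{track_id},
#'   \code{slice}, \code{x}, \code{y}, \code{w}, \code{h}, \code{label},
#'   \code{conf}, one row per track entry, slices strictly increasing
#'   within a track.
#' @seealso \code{\link{classifyTracks}}, \code{\link{countObjects}}
#' @export
trackStack <- function(detections, config = trackerConfig()) {
  if (is.list(detections) && !is.data.frame(detections)) {
    detections <- do.call(rbind, lapply(seq_along(detections), function(i) {
      d <- detections[[i]]
      if (nrow(d)) d$slice <- i - 1L
      d
    }))
  }
  if (is.null(detections) || !nrow(detections)) return(.emptyTracks())
  .assertBoxes(detections, "detections")

  tracks <- list()      # each: list(id, rows = list of row dfs, gap, open)
  nextId <- 1L
  sliceRange <- seq(min(detections$slice), max(detections$slice))
  for (s in sliceRange) {
    dets <- detections[detections$slice == s, , drop = FALSE]
    dets <- dets[order(-dets$conf, dets$x, dets$y, dets$w, dets$h), ,
                 drop = FALSE]
    openIdx <- which(vapply(tracks, function(t) t$open, logical(1)))
    trackBoxes <- if (length(openIdx)) {
      do.call(rbind, lapply(openIdx, function(i) {
        last <- tracks[[i]]$rows[[length(tracks[[i]]$rows)]]
        data.frame(track_id = tracks[[i]]$id, x = last$x, y = last$y,
                   w = last$w, h = last$h)
      }))
    } else data.frame(track_id = integer(0), x = numeric(0), y = numeric(0),
                      w = numeric(0), h = numeric(0))

    assoc <- associateDetections(trackBoxes, dets, config)
    idMap <- vapply(tracks, function(t) t$id, integer(1))
    if (nrow(assoc$matches)) {
      for (r in seq_len(nrow(assoc$matches))) {
        ti <- which(idMap == assoc$matches$track_id[r])
        entry <- dets[assoc$matches$det[r], , drop = FALSE]
        tracks[[ti]]$rows <- c(tracks[[ti]]$rows, list(entry))
        tracks[[ti]]$gap <- 0L
      }
    }
    for (ti in openIdx) {
      if (tracks[[ti]]$id %in% assoc$matches$track_id) next
      tracks[[ti]]$gap <- tracks[[ti]]$gap + 1L
      if (tracks[[ti]]$gap > config@maxGap) tracks[[ti]]$open <- FALSE
    }
    for (d in assoc$unmatchedDetections) {
      tracks[[length(tracks) + 1L]] <-
        list(id = nextId, rows = list(dets[d, , drop = FALSE]),
             gap = 0L, open = TRUE)
      nextId <- nextId + 1L
    }
  }

  kept <- Filter(function(t) length(t$rows) >= config@minLength, tracks)
  if (!length(kept)) return(.emptyTracks())
  out <- do.call(rbind, lapply(kept, function(t) {
    df <- do.call(rbind, t$rows)
    df$track_id <- t$id
    df
  }))
  out <- out[, c("track_id", "slice", "x", "y", "w", "h", "label", "conf")]
  out <- out[order(out$track_id, out$slice), ]
  rownames(out) <- NULL
  out
}

#' Hierarchical classification of a track
#'
#' The class of a trajectory is the maximum of the classes observed along
#' it, under the hierarchy \code{candidate < cell < cluster < colony}: a
#' typical trajectory enters as an out-of-focus candidate, resolves to its
#' true class near its focal plane, and blurs back to candidate, so the
#' maximum recovers the true class as long as it is detected on at least
#' one slice.
#'
#' @param labels Character vector of per-slice labels of one track (or a
#'   track data.frame with a \code{label} column).
#' @return The track's class, a single character string.
#' @examples
#' classifyTrack(c("candidate", "cluster", "colony", "candidate"))
#' @export
classifyTrack <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  if (!length(labels)) stop("empty track")
  .CLASS_LEVELS[max(classRank(labels)) + 1L]
}

#' Classify every track in a track table
#'
#' @param tracks Tracks in long format (see \code{\link{trackStack}}).
#' @return data.frame with one row per track: \code{track_id},
#'   \code{class}, \code{n_entries}, \code{first_slice}, \code{last_slice}.
#' @export
classifyTracks <- function(tracks) {
  if (!nrow(tracks))
    return(data.frame(track_id = integer(0), class = character(0),
                      n_entries = integer(0), first_slice = integer(0),
                      last_slice = integer(0), stringsAsFactors = FALSE))
  ids <- sort(unique(tracks$track_id))
  do.call(rbind, lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    data.frame(track_id = id, class = classifyTrack(tr$label),
               n_entries = nrow(tr), first_slice = min(tr$slice),
               last_slice = max(tr$slice), stringsAsFactors = FALSE)
  }))
}
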