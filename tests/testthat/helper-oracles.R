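## Brute-force and cross-language oracles, plus small scenario builders.
## These share no code with the package internals they check.

## All permutations of 1..n as a matrix (n! rows).
allPerms <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- allPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, p + (p >= i))))
}

## Exhaustive minimum-cost square assignment: total cost over all
## permutations (pads rectangular input with zero columns/rows).
bruteAssignmentCost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  s <- max(n, m)
  padded <- matrix(0, s, s)
  padded[seq_len(n), seq_len(m)] <- cost
  perms <- allPerms(s)
  min(apply(perms, 1, function(p) sum(padded[cbind(seq_len(s), p)])))
}

## Exhaustive maximum total trajectory overlap (IDTP oracle).
bruteMaxOverlap <- function(overlap) {
  n <- nrow(overlap); m <- ncol(overlap)
  if (n == 0L || m == 0L) return(0)
  s <- max(n, m)
  padded <- matrix(0, s, s)
  padded[seq_len(n), seq_len(m)] <- overlap
  perms <- allPerms(s)
  max(apply(perms, 1, function(p) sum(padded[cbind(seq_len(s), p)])))
}

## Independent IoU (interval arithmetic written from scratch).
oracleIoU <- function(a, b) {
  overlap1d <- function(lo1, len1, lo2, len2)
    max(0, min(lo1 + len1, lo2 + len2) - max(lo1, lo2))
  inter <- overlap1d(a[1], a[3], b[1], b[3]) *
    overlap1d(a[2], a[4], b[2], b[4])
  denom <- a[3] * a[4] + b[3] * b[4] - inter
  if (denom <= 0) 0 else inter / denom
}

## Trajectory overlap matrix computed with the independent IoU.
oracleOverlapMatrix <- function(gt, hyp, thr) {
  gids <- sort(unique(gt$track_id)); hids <- sort(unique(hyp$track_id))
  ov <- matrix(0, length(gids), length(hids))
  for (i in seq_along(gids)) for (j in seq_along(hids)) {
    g <- gt[gt$track_id == gids[i], ]
    h <- hyp[hyp$track_id == hids[j], ]
    common <- intersect(g$slice, h$slice)
    cnt <- 0
    for (s in common) {
      ga <- unlist(g[g$slice == s, c("x", "y", "w", "h")])
      ha <- unlist(h[h$slice == s, c("x", "y", "w", "h")])
      if (oracleIoU(ga, ha) >= thr) cnt <- cnt + 1
    }
    ov[i, j] <- cnt
  }
  ov
}

## Cross-language oracle: scipy linear_sum_assignment implementation.
pythonOracle <- function(gt, hyp, iouThreshold = 0.5) {
  script <- system.file("oracle", "idf1_oracle.py", package = "ClonoTrack")
  stopifnot(nzchar(script))
  inFile <- tempfile(fileext = ".json")
  on.exit(unlink(inFile))
  asRows <- function(df) lapply(seq_len(nrow(df)), function(i)
    list(track_id = df$track_id[i], slice = df$slice[i],
         x = df$x[i], y = df$y[i], w = df$w[i], h = df$h[i]))
  jsonlite::write_json(list(gt = asRows(gt), hyp = asRows(hyp),
                            iou = iouThreshold),
                       inFile, auto_unbox = TRUE, digits = NA)
  out <- system2("python", c(script, inFile), stdout = TRUE)
  jsonlite::fromJSON(paste(out, collapse = ""))
}

## Random track-table scenario: up to maxTracks GT objects with boxes
## drifting over consecutive slices, plus a perturbed/dropped hypothesis.
randomScenario <- function(seed, maxTracks = 5L, maxSlices = 20L) {
  set.seed(seed)
  nG <- sample(1:maxTracks, 1)
  field <- 200
  gt <- do.call(rbind, lapply(seq_len(nG), function(id) {
    len <- sample(3:maxSlices, 1)
    start <- sample(0:(maxSlices - len), 1)
    w <- runif(1, 8, 30); h <- runif(1, 8, 30)
    x <- runif(1, 0, field - w); y <- runif(1, 0, field - h)
    dx <- cumsum(c(0, rnorm(len - 1, 0, 1.5)))
    dy <- cumsum(c(0, rnorm(len - 1, 0, 1.5)))
    data.frame(track_id = id, slice = start + seq_len(len) - 1L,
               x = x + dx, y = y + dy, w = w, h = h)
  }))
  ## hypothesis: jitter boxes, drop some frames, sometimes split an id
  hyp <- gt
  keep <- runif(nrow(hyp)) > 0.15
  hyp <- hyp[keep, , drop = FALSE]
  hyp$x <- hyp$x + rnorm(nrow(hyp), 0, 2)
  hyp$y <- hyp$y + rnorm(nrow(hyp), 0, 2)
  split <- runif(nrow(hyp)) < 0.1
  hyp$track_id[split] <- hyp$track_id[split] + 100L
  rownames(hyp) <- NULL
  list(gt = gt, hyp = hyp)
}

## Perfect ground-truth detections of a sampled scene, usable as tracker
## input (confidence 1).
gtDetections <- function(scene) {
  gt <- groundTruth(scene)
  data.frame(slice = gt$slice, x = gt$x, y = gt$y, w = gt$w, h = gt$h,
             label = gt$label, conf = 1, stringsAsFactors = FALSE)
}

gtAsTrackTable <- function(scene) {
  gt <- groundTruth(scene)
  data.frame(track_id = gt$object_id, slice = gt$slice,
             x = gt$x, y = gt$y, w = gt$w, h = gt$h,
             label = gt$label, stringsAsFactors = FALSE)
}

## Minimal, independent growth simulator used as a Monte-Carlo oracle.
oracleGrowCell <- function(hours, pPerHour, seed) {
  set.seed(seed)
  n <- 1L
  for (h in seq_len(hours)) n <- n + rbinom(1, n, pPerHour)
  n
}
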