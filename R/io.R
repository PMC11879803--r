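## Class index <-> label mapping used by the YOLO-style and MOT-style
## dialects: 0 = candidate, 1 = cell, 2 = cluster, 3 = colony.
.classIndex <- function(label) classRank(label)
.classLabel <- function(index) {
  out <- rep(NA_character_, length(index))
  ok <- !is.na(index) & index >= 0 & index <= 3
  out[ok] <- .CLASS_LEVELS[index[ok] + 1L]
  out
}

#' Read YOLO-style normalized bounding boxes for one slice
#'
#' Parses lines of \code{class_index x_center y_center width height}
#' (all coordinates normalized to [0, 1], optionally followed by a
#' confidence) into pixel-space half-open boxes. Class indices are
#' 0 = candidate, 1 = cell, 2 = cluster, 3 = colony.
#'
#' @param path Path to the text file (one line per box; may be empty).
#' @param imageSize Integer (width, height) in px.
#' @return data.frame with \code{label}, \code{x}, \code{y}, \code{w},
#'   \code{h} and, when present in the file, \code{conf}.
#' @seealso \code{\link{writeYoloBoxes}}
#' @export
readYoloBoxes <- function(path, imageSize) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(label = character(0), x = numeric(0), y = numeric(0),
                      w = numeric(0), h = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  rows <- lapply(seq_along(lines), function(i) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(f) < 5L || anyNA(f[1:5]))
      stop("parse error at line ", i, " of ", path)
    if (any(f[2:5] < 0 | f[2:5] > 1))
      stop("normalized value out of [0,1] at line ", i, " of ", path)
    if (!f[1] %in% 0:3)
      stop("unknown class index ", f[1], " at line ", i, " of ", path)
    data.frame(label = .classLabel(f[1]),
               x = (f[2] - f[4] / 2) * imageSize[1],
               y = (f[3] - f[5] / 2) * imageSize[2],
               w = f[4] * imageSize[1], h = f[5] * imageSize[2],
               conf = if (length(f) >= 6L) f[6] else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (all(is.na(out$conf))) out$conf <- NULL
  out
}

#' Write boxes in YOLO-style normalized text
#'
#' @param boxes data.frame with \code{label}, \code{x}, \code{y},
#'   \code{w}, \code{h} and optionally \code{conf}.
#' @param path Output text file.
#' @param imageSize Integer (width, height) in px.
#' @return Invisibly, \code{path}.
#' @export
writeYoloBoxes <- function(boxes, path, imageSize) {
  lines <- character(0)
  if (nrow(boxes)) {
    xc <- (boxes$x + boxes$w / 2) / imageSize[1]
    yc <- (boxes$y + boxes$h / 2) / imageSize[2]
    lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                     .classIndex(boxes$label), xc, yc,
                     boxes$w / imageSize[1], boxes$h / imageSize[2])
    if ("conf" %in% names(boxes) && !all(is.na(boxes$conf)))
      lines <- paste(lines, sprintf("%.4f", boxes$conf))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read MOTChallenge-style track annotations
#'
#' Parses CSV lines \code{frame,id,bb_left,bb_top,bb_width,bb_height,
#' conf,class,visibility}. Frames are 1-based in the file and converted
#' to 0-based slice indices; entries are sorted by slice within each
#' track; duplicate (frame, id) pairs are an error. The class field is
#' interpreted with the package's 0-based class indices where possible.
#'
#' @param path Path to the annotation file.
#' @return Track table: data.frame with \code{track_id}, \code{slice},
#'   \code{x}, \code{y}, \code{w}, \code{h}, \code{conf}, \code{label}.
#' @seealso \code{\link{writeMOT}}
#' @export
readMOT <- function(path) {
  empty <- .emptyTracks()
  raw <- tryCatch(read.csv(path, header = FALSE), error = function(e) NULL)
  if (is.null(raw) || !nrow(raw)) return(empty)
  if (ncol(raw) < 6L) stop("MOT file needs at least 6 comma-separated fields")
  names(raw)[1:6] <- c("frame", "id", "x", "y", "w", "h")
  conf <- if (ncol(raw) >= 7L) raw[[7]] else rep(1, nrow(raw))
  cls <- if (ncol(raw) >= 8L) suppressWarnings(as.integer(raw[[8]]))
         else rep(NA_integer_, nrow(raw))
  if (anyDuplicated(raw[, c("frame", "id")]))
    stop("duplicate (frame, id) entries in ", path)
  out <- data.frame(track_id = as.integer(raw$id),
                    slice = as.integer(raw$frame) - 1L,
                    x = raw$x, y = raw$y, w = raw$w, h = raw$h,
                    label = .classLabel(cls), conf = as.numeric(conf),
                    stringsAsFactors = FALSE)
  out <- out[order(out$track_id, out$slice), ]
  rownames(out) <- NULL
  out
}

#' Write tracks in MOTChallenge result/ground-truth format
#'
#' Writes \code{frame,id,bb_left,bb_top,bb_width,bb_height,conf,class,
#' visibility} lines with 1-based frames. Ground truth is written with
#' conf = 1 and visibility = 1; results carry the detection confidence
#' (4 decimals) and -1 in the last field.
#'
#' @param tracks Track table (long format).
#' @param path Output file.
#' @param groundTruth Write ground-truth conventions? (default FALSE).
#' @return Invisibly, \code{path}.
#' @export
writeMOT <- function(tracks, path, groundTruth = FALSE) {
  if (!nrow(tracks)) { writeLines(character(0), path); return(invisible(path)) }
  cls <- if ("label" %in% names(tracks)) .classIndex(tracks$label)
         else rep(-1L, nrow(tracks))
  conf <- if (groundTruth || !"conf" %in% names(tracks))
    rep(1, nrow(tracks)) else tracks$conf
  lines <- sprintf("%d,%d,%.4f,%.4f,%.4f,%.4f,%.4f,%d,%d",
                   tracks$slice + 1L, tracks$track_id,
                   tracks$x, tracks$y, tracks$w, tracks$h,
                   conf, cls, if (groundTruth) 1L else -1L)
  writeLines(lines, path)
  invisible(path)
}

#' Write a Z-stack to disk
#'
#' Either a zero-padded PNG slice sequence (\code{slice_000.png}, ...)
#' into a directory, or a single multi-page TIFF.
#'
#' @param stack Numeric array (width, height, nSlices), values in [0, 1].
#' @param path Output directory (png) or file path (tiff).
#' @param format \code{"png"} (default) or \code{"tiff"}.
#' @return Invisibly, \code{path}.
#' @seealso \code{\link{readStack}}
#' @export
writeStack <- function(stack, path, format = c("png", "tiff")) {
  format <- match.arg(format)
  n <- dim(stack)[3]
  if (format == "png") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n))
      png::writePNG(t(stack[, , i]),
                    file.path(path, sprintf("slice_%03d.png", i - 1L)))
  } else {
    tiff::writeTIFF(lapply(seq_len(n), function(i) t(stack[, , i])),
                    path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Read a Z-stack from disk
#'
#' Accepts a directory of PNG slices (sorted by name) or a multi-page
#' TIFF file.
#'
#' @param path Stack directory or TIFF file.
#' @return Numeric array (width, height, nSlices) in [0, 1].
#' @export
readStack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no PNG slices found in ", path)
    slices <- lapply(files, function(f) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3L) m <- m[, , 1]
      t(m)
    })
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    slices <- lapply(tiff::readTIFF(path, all = TRUE), t)
  } else stop("path is neither a directory of PNGs nor a TIFF file")
  array(unlist(slices), dim = c(dim(slices[[1]]), length(slices)))
}

#' Read a flat key = value configuration file
#'
#' INI-style parser: \code{key = value} lines, \code{#} or \code{;}
#' comments, optional \code{[section]} headers (keys inside a section are
#' prefixed \code{section.key}). Values are converted to numeric or
#' logical where possible; comma-separated values become vectors.
#'
#' @param path Path to the configuration file.
#' @return Named list of values.
#' @export
readConfigFile <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[#;].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- ""
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3L) stop("cannot parse config line: ", ln)
    key <- trimws(kv[2]); val <- trimws(gsub("[\"']", "", kv[3]))
    if (nzchar(section)) key <- paste(section, key, sep = ".")
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num
      else if (all(toupper(parts) %in% c("TRUE", "FALSE")))
        as.logical(toupper(parts))
      else if (length(parts) > 1L) parts else val
  }
  out
}
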