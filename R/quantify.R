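#' Count unique objects per class in a tracked stack
#'
#' Tallies classified tracks by their final hierarchical class.
#' Candidate-only tracks (objects never seen in focus) are counted
#' separately and excluded from the cell/cluster/colony totals.
#'
#' @param tracks Classified tracks: output of \code{\link{classifyTracks}}
#'   (or raw \code{\link{trackStack}} output, which is classified first).
#' @param well,roi,timepoint Optional identifiers attached to the result.
#' @return One-row data.frame with \code{well}, \code{roi},
#'   \code{timepoint}, \code{n_cells}, \code{n_clusters},
#'   \code{n_colonies}, \code{n_candidates}.
#' @examples
#' countObjects(data.frame(track_id = 1:4,
#'                         class = c("colony", "cluster", "cluster",
#'                                   "candidate")))
#' @export
countObjects <- function(tracks, well = NA_character_, roi = NA_character_,
                         timepoint = NA_real_) {
  if (nrow(tracks) && !"class" %in% names(tracks))
    tracks <- classifyTracks(tracks)
  tab <- table(factor(tracks$class, levels = .CLASS_LEVELS))
  data.frame(well = well, roi = roi, timepoint = timepoint,
             n_cells = as.integer(tab[["cell"]]),
             n_clusters = as.integer(tab[["cluster"]]),
             n_colonies = as.integer(tab[["colony"]]),
             n_candidates = as.integer(tab[["candidate"]]),
             stringsAsFactors = FALSE)
}

#' Plating efficiency
#'
#' Percentage of colony-forming input cells:
#' \code{100 * colonies_end / denominator}. The denominator is either the
#' number of cells seeded into the well (\code{"seeded"}) or the number of
#' single cells actually observed at the start timepoint
#' (\code{"observed_start"}, the default, matching an automated per-ROI
#' workflow where the imaged field sees only part of the well).
#'
#' @param coloniesEnd Colonies counted at the final timepoint (>= 0).
#' @param denominator Cells seeded or observed at start (> 0).
#' @param mode \code{"observed_start"} or \code{"seeded"}.
#' @return One-row data.frame with \code{pe_percent}, \code{colonies_end},
#'   \code{denominator}, \code{denominator_mode}.
#' @examples
#' platingEfficiency(20, 100)
#' @export
platingEfficiency <- function(coloniesEnd, denominator,
                              mode = c("observed_start", "seeded")) {
  mode <- match.arg(mode)
  if (denominator <= 0) stop("denominator must be positive")
  if (coloniesEnd < 0) stop("coloniesEnd must be >= 0")
  data.frame(pe_percent = 100 * coloniesEnd / denominator,
             colonies_end = coloniesEnd, denominator = denominator,
             denominator_mode = mode, stringsAsFactors = FALSE)
}

#' Survival fraction after treatment
#'
#' \code{SF = colonies_treated / (cells_seeded * pe)}, where \code{pe} is
#' the plating efficiency of the untreated control expressed as a fraction
#' in (0, 1]. The untreated control evaluated against its own plating
#' efficiency gives SF = 1.
#'
#' @param coloniesTreated Colonies formed after treatment (>= 0).
#' @param cellsSeeded Cells seeded (> 0).
#' @param pe Control plating efficiency as a fraction in (0, 1].
#' @return Survival fraction (>= 0).
#' @examples
#' survivalFraction(10, 100, 0.2)
#' @export
survivalFraction <- function(coloniesTreated, cellsSeeded, pe) {
  if (cellsSeeded <= 0) stop("cellsSeeded must be positive")
  if (pe <= 0) stop("pe must be positive (survival fraction undefined)")
  coloniesTreated / (cellsSeeded * pe)
}

#' Total axial height of a Z-stack
#'
#' The assay convention counts one slice spacing per slice, so 25 slices
#' at 30 um separation cover 750 um (not 24 x 30).
#'
#' @param nSlices Number of slices (>= 1).
#' @param spacing Slice separation in um (> 0).
#' @return Height in um.
#' @examples
#' stackHeight(25, 30)
#' @export
stackHeight <- function(nSlices, spacing) {
  if (any(nSlices < 1)) stop("nSlices must be >= 1")
  if (any(spacing <= 0)) stop("spacing must be positive")
  nSlices * spacing
}

#' Replicate-averaged count time series
#'
#' Groups per-stack counts by condition, concentration, timepoint and
#' class and reports the mean and standard error of the mean
#' (\code{sd / sqrt(n)}) across replicates (well x ROI combinations).
#' Missing timepoints are left absent, never imputed. With a single
#' replicate the SEM is reported as 0 and flagged.
#'
#' @param counts data.frame of \code{\link{countObjects}} rows, with
#'   additional grouping columns \code{condition} and (optionally)
#'   \code{concentration}.
#' @return Long data.frame with \code{condition}, \code{concentration},
#'   \code{timepoint}, \code{class}, \code{n}, \code{mean}, \code{sem},
#'   \code{single_replicate}.
#' @examples
#' cnt <- rbind(
#'   cbind(condition = "ctrl", countObjects(data.frame(track_id = 1,
#'     class = "colony"), well = "A", roi = "1", timepoint = 96)),
#'   cbind(condition = "ctrl", countObjects(data.frame(track_id = 1:2,
#'     class = c("colony", "colony")), well = "A", roi = "2",
#'     timepoint = 96)))
#' assembleTimeSeries(cnt)
#' @export
assembleTimeSeries <- function(counts) {
  if (!nrow(counts)) stop("no counts supplied")
  if (!"condition" %in% names(counts)) counts$condition <- "all"
  if (!"concentration" %in% names(counts)) counts$concentration <- NA_real_
  dup <- duplicated(counts[, c("condition", "concentration", "well", "roi",
                               "timepoint")])
  if (any(dup))
    stop("duplicate (well, roi, timepoint) entries in counts")
  classCols <- c(cell = "n_cells", cluster = "n_clusters",
                 colony = "n_colonies", candidate = "n_candidates")
  long <- do.call(rbind, lapply(names(classCols), function(cl) {
    data.frame(condition = counts$condition,
               concentration = counts$concentration,
               timepoint = counts$timepoint,
               class = cl, count = counts[[classCols[[cl]]]],
               stringsAsFactors = FALSE)
  }))
  key <- paste(long$condition, long$concentration, long$timepoint,
               long$class, sep = "\r")
  out <- do.call(rbind, lapply(unique(key), function(k) {
    g <- long[key == k, ]
    n <- nrow(g)
    data.frame(condition = g$condition[1], concentration = g$concentration[1],
               timepoint = g$timepoint[1], class = g$class[1], n = n,
               mean = mean(g$count),
               sem = if (n > 1) sd(g$count) / sqrt(n) else 0,
               single_replicate = n == 1L, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$condition, out$concentration, out$timepoint,
                   match(out$class, .CLASS_LEVELS)), ]
  rownames(out) <- NULL
  out
}
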