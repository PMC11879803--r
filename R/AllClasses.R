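#' @import methods
#' @importFrom stats rnorm runif rbinom median sd var setNames lm coef
#'   predict pnorm complete.cases residuals
#' @importFrom utils read.csv write.csv head tail
#' @importFrom tools md5sum
NULL

## Hierarchical object classes, ordered by relevance. A candidate is an
## out-of-focus object hypothesised to resolve into a cluster/colony on a
## neighbouring focal plane; the remaining three are ordered by size.
.CLASS_LEVELS <- c("candidate", "cell", "cluster", "colony")

#' Hierarchical object class scheme
#'
#' The four object classes used throughout the package, in hierarchical
#' order: \code{candidate < cell < cluster < colony}. Track classification
#' takes the maximum class observed along a trajectory under this order.
#'
#' @return Character vector of the four class names, lowest first.
#' @examples
#' objectClasses()
#' @export
objectClasses <- function() .CLASS_LEVELS

#' Derive the object class from a cell count
#'
#' Single cells are class \code{cell}, groups of 2--14 cells are
#' \code{cluster}, and groups of 15 or more cells are \code{colony}. The
#' partition is total: every positive integer maps to exactly one class.
#'
#' @param cellCount Integer vector of cell counts (>= 1).
#' @return Character vector of classes, same length as \code{cellCount}.
#' @examples
#' classFromCellCount(c(1, 2, 14, 15, 40))
#' @export
classFromCellCount <- function(cellCount) {
  if (any(cellCount < 1))
    stop("cellCount must be >= 1")
  ifelse(cellCount == 1L, "cell",
         ifelse(cellCount <= 14L, "cluster", "colony"))
}

#' Rank of an object class in the hierarchy
#'
#' @param label Character vector of class names.
#' @return Integer rank, 0 (candidate) through 3 (colony).
#' @examples
#' classRank(c("candidate", "colony"))
#' @export
classRank <- function(label) {
  r <- match(label, .CLASS_LEVELS) - 1L
  if (anyNA(r))
    stop("unknown class label: ",
         paste(setdiff(label, .CLASS_LEVELS), collapse = ", "))
  r
}

## ---------------------------------------------------------------------------
## SceneConfig
## ---------------------------------------------------------------------------

#' @rdname SceneConfig
#' @export
setClass("SceneConfig",
  representation(
    nSlices       = "integer",
    sliceSpacing  = "numeric",
    imageSize     = "integer",
    pixelSize     = "numeric",
    objectCounts  = "integer",
    clusterCells  = "integer",
    colonyCells   = "integer",
    cellRadius    = "numeric",
    minSeparation = "numeric",
    driftSigma    = "numeric",
    noiseSigma    = "numeric",
    blurBase      = "numeric",
    blurSlope     = "numeric",
    dof           = "numeric",
    candidateDepth = "numeric",
    amplitude     = "numeric",
    seed          = "integer"
  )
)

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@nSlices < 1L) msg <- c(msg, "nSlices must be >= 1")
  if (object@sliceSpacing <= 0) msg <- c(msg, "sliceSpacing must be > 0")
  if (length(object@imageSize) != 2L || any(object@imageSize <= 0L))
    msg <- c(msg, "imageSize must be two positive integers (width, height)")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (!all(c("cell", "cluster", "colony") %in% names(object@objectCounts)))
    msg <- c(msg, "objectCounts must be named cell/cluster/colony")
  if (any(object@objectCounts < 0L)) msg <- c(msg, "objectCounts must be >= 0")
  if (object@dof <= 0) msg <- c(msg, "dof must be > 0")
  if (object@candidateDepth <= object@dof)
    msg <- c(msg, "candidateDepth must exceed dof")
  if (object@driftSigma < 0 || object@noiseSigma < 0)
    msg <- c(msg, "driftSigma and noiseSigma must be >= 0")
  if (object@blurSlope <= 0) msg <- c(msg, "blurSlope must be > 0")
  if (object@amplitude <= 0 || object@amplitude > 1)
    msg <- c(msg, "amplitude must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Synthetic scene configuration
#'
#' Parameters of the synthetic Z-stack generator: stack geometry, object
#' census per class, optics (depth of field, defocus blur growth), and
#' nuisance processes (per-slice positional drift, additive noise). The
#' defaults emulate a 10x brightfield colony-forming assay: 19 slices at
#' 30 um spacing, 1.5 um/px sampling, ~5 um single-cell radius with object
#' area proportional to cell count.
#'
#' @param nSlices Number of Z slices (default 19).
#' @param sliceSpacing Axial slice separation in um (default 30).
#' @param imageSize Image width and height in px (default c(512, 512)).
#' @param pixelSize Lateral sampling in um/px (default 1.5).
#' @param objectCounts Named integer vector: objects per class, names
#'   \code{cell}, \code{cluster}, \code{colony}.
#' @param clusterCells Inclusive integer range of cells per cluster
#'   (default 3--12; must stay within the 2--14 cluster definition).
#' @param colonyCells Inclusive integer range of cells per colony
#'   (default 18--60; must be >= 15).
#' @param cellRadius In-focus radius of one cell in um (default 5); an
#'   object of n cells gets radius \code{cellRadius * sqrt(n)} so that its
#'   area is n cell-equivalents.
#' @param minSeparation Minimum edge-to-edge distance between objects in um
#'   (default 25); placement uses rejection sampling.
#' @param driftSigma Random-walk step of the object centre per slice, in px
#'   (default 0).
#' @param noiseSigma Additive Gaussian intensity noise sd, on the [0, 1]
#'   intensity scale (default 0).
#' @param blurBase Edge softness of a perfectly focused object, in um
#'   (default 1).
#' @param blurSlope Growth of edge softness per um of defocus
#'   (default 0.12, dimensionless um/um).
#' @param dof In-focus half-depth in um: slices within \code{dof} of an
#'   object's focal plane see it sharp and truly classifiable (default 20).
#' @param candidateDepth Maximum defocus in um at which an object is still
#'   visible as an out-of-focus candidate (default 90); beyond it the
#'   object leaves no ground-truth box.
#' @param amplitude Peak intensity contrast of an in-focus object against
#'   the background, in (0, 1] (default 0.6).
#' @param seed Integer seed; all sampling is deterministic given it.
#' @return A \code{SceneConfig} object.
#' @seealso \code{\link{sampleScene}}, \code{\link{renderStack}}
#' @examples
#' cfg <- sceneConfig(objectCounts = c(cell = 2, cluster = 1, colony = 1),
#'                    seed = 1)
#' cfg
#' @aliases SceneConfig-class SceneConfig
#' @export
sceneConfig <- function(nSlices = 19L, sliceSpacing = 30, imageSize = c(512L, 512L),
                        pixelSize = 1.5,
                        objectCounts = c(cell = 5L, cluster = 3L, colony = 2L),
                        clusterCells = c(3L, 12L), colonyCells = c(18L, 60L),
                        cellRadius = 5, minSeparation = 25,
                        driftSigma = 0, noiseSigma = 0,
                        blurBase = 1, blurSlope = 0.12,
                        dof = 20, candidateDepth = 90,
                        amplitude = 0.6, seed = 1L) {
  if (any(imageSize <= 0) || sliceSpacing <= 0)
    stop("image size and slice spacing must be positive")
  oc <- setNames(rep(0L, 3L), c("cell", "cluster", "colony"))
  oc[names(objectCounts)] <- as.integer(objectCounts)
  new("SceneConfig",
      nSlices = as.integer(nSlices), sliceSpacing = as.numeric(sliceSpacing),
      imageSize = as.integer(imageSize), pixelSize = as.numeric(pixelSize),
      objectCounts = oc,
      clusterCells = as.integer(clusterCells), colonyCells = as.integer(colonyCells),
      cellRadius = as.numeric(cellRadius), minSeparation = as.numeric(minSeparation),
      driftSigma = as.numeric(driftSigma), noiseSigma = as.numeric(noiseSigma),
      blurBase = as.numeric(blurBase), blurSlope = as.numeric(blurSlope),
      dof = as.numeric(dof), candidateDepth = as.numeric(candidateDepth),
      amplitude = as.numeric(amplitude), seed = as.integer(seed))
}

setMethod("show", "SceneConfig", function(object) {
  cat("SceneConfig:", object@nSlices, "slices x", object@sliceSpacing,
      "um (stack height", stackHeight(object@nSlices, object@sliceSpacing),
      "um)\n")
  cat("  field:", object@imageSize[1], "x", object@imageSize[2], "px at",
      object@pixelSize, "um/px\n")
  cat("  objects:", paste(names(object@objectCounts), object@objectCounts,
                          sep = "=", collapse = ", "), "\n")
  cat("  optics: dof", object@dof, "um, candidate depth",
      object@candidateDepth, "um, blur slope", object@blurSlope, "\n")
  cat("  nuisance: drift", object@driftSigma, "px/slice, noise sd",
      object@noiseSigma, "| seed", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## SyntheticScene
## ---------------------------------------------------------------------------

#' @rdname SyntheticScene
#' @export
setClass("SyntheticScene",
  representation(objects = "data.frame", groundTruth = "data.frame",
                 drift = "data.frame", config = "SceneConfig"))

setValidity("SyntheticScene", function(object) {
  msg <- character()
  needObj <- c("object_id", "x_um", "y_um", "focal_z", "cell_count",
               "radius_um", "true_class")
  if (!all(needObj %in% names(object@objects)))
    msg <- c(msg, "objects table lacks required columns")
  needGT <- c("slice", "object_id", "x", "y", "w", "h", "label")
  if (!all(needGT %in% names(object@groundTruth)))
    msg <- c(msg, "groundTruth table lacks required columns")
  if (nrow(object@groundTruth) &&
      !all(object@groundTruth$object_id %in% object@objects$object_id))
    msg <- c(msg, "groundTruth references unknown object ids")
  if (nrow(object@objects) &&
      !identical(object@objects$true_class,
                 classFromCellCount(object@objects$cell_count)))
    msg <- c(msg, "true_class inconsistent with cell_count")
  if (length(msg)) msg else TRUE
})

#' Synthetic scene: ground-truth 3D objects plus per-slice annotations
#'
#' Container returned by \code{\link{sampleScene}}. The \code{objects} slot
#' holds one row per 3D object (position, focal depth, cell count, radius,
#' true class); \code{groundTruth} holds one row per (slice, object) pair
#' with the pixel-space bounding box and the label visible on that slice
#' (true class when in focus, \code{candidate} when moderately defocused,
#' absent beyond the candidate depth).
#'
#' @section Accessors:
#' \code{sceneObjects(x)}, \code{groundTruth(x)}, \code{sceneConfigOf(x)}.
#'
#' @aliases SyntheticScene-class SyntheticScene sceneObjects groundTruth
#'   sceneConfigOf
#' @seealso \code{\link{sampleScene}}
#' @name SyntheticScene
NULL

#' @export
setGeneric("sceneObjects", function(x) standardGeneric("sceneObjects"))
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @export
setGeneric("sceneConfigOf", function(x) standardGeneric("sceneConfigOf"))
#' @export
setGeneric("sceneDrift", function(x) standardGeneric("sceneDrift"))

#' @rdname SyntheticScene
setMethod("sceneObjects", "SyntheticScene", function(x) x@objects)
#' @rdname SyntheticScene
setMethod("groundTruth", "SyntheticScene", function(x) x@groundTruth)
#' @rdname SyntheticScene
setMethod("sceneConfigOf", "SyntheticScene", function(x) x@config)
#' @rdname SyntheticScene
setMethod("sceneDrift", "SyntheticScene", function(x) x@drift)

setMethod("show", "SyntheticScene", function(object) {
  tab <- table(factor(object@objects$true_class, levels = .CLASS_LEVELS[-1]))
  cat("SyntheticScene:", nrow(object@objects), "objects (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  cat("  ground truth:", nrow(object@groundTruth), "boxes over",
      length(unique(object@groundTruth$slice)), "slices\n")
})

## ---------------------------------------------------------------------------
## GrowthConfig
## ---------------------------------------------------------------------------

#' @rdname GrowthConfig
#' @export
setClass("GrowthConfig",
  representation(timepoints = "numeric", baseRate = "numeric",
                 inhibition = "function", seed = "integer"))

setValidity("GrowthConfig", function(object) {
  msg <- character()
  if (is.unsorted(object@timepoints))
    msg <- c(msg, "timepoints must be sorted ascending")
  if (object@baseRate <= 0) msg <- c(msg, "baseRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' Growth simulation configuration
#'
#' Parameters of the stochastic clonal-growth model: each cell divides in a
#' 1-hour step with probability \code{baseRate * (1 - inhibition(conc))},
#' so an uninhibited population doubles on average every
#' \code{log(2)/log(1 + baseRate)} hours. The default base rate
#' \code{2^(1/12) - 1} gives a 12 h doubling time, under which a single
#' seeded cell is expected to pass the 15-cell colony threshold at about
#' 60 h, matching the onset behaviour of B-ALL colony-forming cultures.
#'
#' @param timepoints Observation times in hours, sorted ascending.
#' @param baseRate Per-cell division probability per hour (> 0).
#' @param inhibition Function mapping concentration (nM) to a growth
#'   inhibition factor in [0, 1]; 1 means full arrest. Default: no drug
#'   effect (always 0).
#' @param seed Integer seed for the division process.
#' @return A \code{GrowthConfig} object.
#' @aliases GrowthConfig-class GrowthConfig
#' @seealso \code{\link{simulateGrowth}}, \code{\link{inhibition4PL}}
#' @examples
#' growthConfig(timepoints = seq(0, 96, by = 12), seed = 7)
#' @export
growthConfig <- function(timepoints = seq(0, 96, by = 12),
                         baseRate = 2^(1 / 12) - 1,
                         inhibition = function(conc) rep(0, length(conc)),
                         seed = 1L) {
  new("GrowthConfig", timepoints = as.numeric(timepoints),
      baseRate = as.numeric(baseRate), inhibition = inhibition,
      seed = as.integer(seed))
}

setMethod("show", "GrowthConfig", function(object) {
  cat("GrowthConfig:", length(object@timepoints), "timepoints,",
      min(object@timepoints), "to", max(object@timepoints), "h\n")
  cat("  division prob/h:", signif(object@baseRate, 4),
      "(doubling every", signif(log(2) / log1p(object@baseRate), 4),
      "h); seed", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## MOTScores
## ---------------------------------------------------------------------------

#' @rdname MOTScores
#' @export
setClass("MOTScores",
  representation(
    idtp = "numeric", idfp = "numeric", idfn = "numeric",
    idf1 = "numeric", idp = "numeric", idr = "numeric",
    nObjects = "numeric",
    mostlyTracked = "numeric", partiallyTracked = "numeric",
    mostlyLost = "numeric",
    idSwitches = "numeric",
    evalClass = "character"
  )
)

setValidity("MOTScores", function(object) {
  msg <- character()
  tot <- object@mostlyTracked + object@partiallyTracked + object@mostlyLost
  if (isTRUE(abs(tot - object@nObjects) > 1e-9))
    msg <- c(msg, "MT + PT + ML must equal nObjects")
  den <- 2 * object@idtp + object@idfp + object@idfn
  if (den > 0 && abs(object@idf1 - 2 * object@idtp / den) > 1e-9)
    msg <- c(msg, "idf1 inconsistent with idtp/idfp/idfn")
  if (length(msg)) msg else TRUE
})

#' Identity-based tracking scores
#'
#' Identity measures (IDTP/IDFP/IDFN and the derived IDF1/IDP/IDR),
#' trajectory coverage counts (mostly tracked > 80\% of frames, partially
#' tracked 20--80\%, mostly lost <= 20\%) and ID switches for one
#' evaluation dataset, optionally restricted to one object class.
#'
#' @aliases MOTScores-class MOTScores
#' @seealso \code{\link{evaluateTracking}}, \code{\link{idMeasures}},
#'   \code{\link{trackingObjective}}
#' @name MOTScores
NULL

setMethod("show", "MOTScores", function(object) {
  cat("MOTScores (", object@evalClass, "): ", object@nObjects,
      " GT objects\n", sep = "")
  cat(sprintf("  idf1 %.3f  idp %.3f  idr %.3f  (idtp %g, idfp %g, idfn %g)\n",
              object@idf1, object@idp, object@idr,
              object@idtp, object@idfp, object@idfn))
  cat(sprintf("  mostly tracked %g, partially tracked %g, mostly lost %g; %g ID switch(es)\n",
              object@mostlyTracked, object@partiallyTracked,
              object@mostlyLost, object@idSwitches))
})

#' Convert MOTScores to a one-row data.frame
#'
#' @param x A \code{MOTScores} object.
#' @param row.names,optional,... Passed for S3 compatibility; ignored.
#' @return A one-row \code{data.frame} with the score columns.
#' @export
as.data.frame.MOTScores <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(class = x@evalClass, n_objects = x@nObjects,
             mostly_tracked = x@mostlyTracked,
             partially_tracked = x@partiallyTracked,
             mostly_lost = x@mostlyLost,
             idf1 = x@idf1, idp = x@idp, idr = x@idr,
             idtp = x@idtp, idfp = x@idfp, idfn = x@idfn,
             id_switches = x@idSwitches,
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## DoseResponseFit
## ---------------------------------------------------------------------------

#' @rdname DoseResponseFit
#' @export
setClass("DoseResponseFit",
  representation(model = "character", coefficients = "numeric",
                 ic50 = "numeric", rSquared = "numeric",
                 converged = "logical", details = "list"))

setValidity("DoseResponseFit", function(object) {
  msg <- character()
  if (!object@model %in% c("fourPL", "linear"))
    msg <- c(msg, "model must be 'fourPL' or 'linear'")
  if (object@model == "fourPL" &&
      !all(c("top", "bottom", "logIC50", "hill") %in% names(object@coefficients)))
    msg <- c(msg, "fourPL fit needs top/bottom/logIC50/hill coefficients")
  if (object@model == "linear" &&
      !all(c("intercept", "slope") %in% names(object@coefficients)))
    msg <- c(msg, "linear fit needs intercept/slope coefficients")
  if (length(msg)) msg else TRUE
})

#' Dose-response fit result
#'
#' Parameters of a four-parameter logistic (4PL) fit
#' \eqn{y = bottom + (top - bottom) / (1 + 10^{(logIC50 - x) hill})}
#' on \eqn{x = \log_{10}} concentration, or of a linear fallback fit, with
#' the derived IC50 in nM, the coefficient of determination and a
#' convergence flag.
#'
#' @section Accessors: \code{ic50(x)} returns the IC50 in nM;
#'   \code{coef(x)} the fitted parameters; \code{modelType(x)} the model
#'   family used.
#' @aliases DoseResponseFit-class DoseResponseFit ic50 modelType
#' @seealso \code{\link{fit4PL}}, \code{\link{fitLinearIC50}},
#'   \code{\link{selectAndFit}}
#' @name DoseResponseFit
NULL

#' @export
setGeneric("ic50", function(x) standardGeneric("ic50"))
#' @rdname DoseResponseFit
setMethod("ic50", "DoseResponseFit", function(x) x@ic50)

#' @export
setGeneric("modelType", function(x) standardGeneric("modelType"))
#' @rdname DoseResponseFit
setMethod("modelType", "DoseResponseFit", function(x) x@model)

#' @rdname DoseResponseFit
#' @param object,... For the \code{coef} method: the fit object.
#' @export
setMethod("coef", "DoseResponseFit", function(object, ...) object@coefficients)

setMethod("show", "DoseResponseFit", function(object) {
  cat("DoseResponseFit [", object@model, "]",
      if (!object@converged) " (NOT converged)", "\n", sep = "")
  co <- object@coefficients
  cat(" ", paste(names(co), signif(co, 5), sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  IC50 = %.4g nM,  r^2 = %.4f\n", object@ic50, object@rSquared))
})
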