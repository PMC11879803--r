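## Evaluate expr under a local RNG state seeded with `seed`; the caller's
## global RNG stream is left untouched.
.withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.5 -> 1), the convention used for
#' reported percentages and score tables, unlike base \code{round}'s
#' round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits (default 0).
#' @return Rounded numeric vector.
#' @examples
#' roundHalfUp(c(0.5, 1.5, 2.45), c(0, 0, 1))
#' @export
roundHalfUp <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

## Empty detections table with the canonical column set.
.emptyDetections <- function() {
  data.frame(slice = integer(0), x = numeric(0), y = numeric(0),
             w = numeric(0), h = numeric(0),
             label = character(0), conf = numeric(0),
             stringsAsFactors = FALSE)
}

## Empty tracks table (long format, one row per track entry).
.emptyTracks <- function() {
  data.frame(track_id = integer(0), slice = integer(0),
             x = numeric(0), y = numeric(0), w = numeric(0), h = numeric(0),
             label = character(0), conf = numeric(0),
             stringsAsFactors = FALSE)
}

.assertBoxes <- function(df, what = "boxes") {
  if (!nrow(df)) return(invisible(df))
  if (any(df$w <= 0) || any(df$h <= 0))
    stop(what, " must have positive width and height")
  invisible(df)
}
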