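#' Normalize treated counts to the vehicle control
#'
#' Divides each treated replicate's clusters + colonies total by the mean
#' of the vehicle-control replicates, so the control maps to mean 1.0.
#'
#' @param treated data.frame with columns \code{concentration} (nM, > 0),
#'   \code{replicate} and \code{total} (clusters + colonies count), or
#'   columns \code{clusters} and \code{colonies} which are then summed.
#' @param control Numeric vector of control totals (clusters + colonies
#'   per control replicate); its mean must be positive.
#' @return A dose-response table: data.frame with \code{concentration},
#'   \code{replicate}, \code{response}.
#' @examples
#' normalizeToControl(data.frame(concentration = c(10, 10),
#'                               replicate = 1:2, total = c(5, 7)),
#'                    control = c(8, 10, 12))
#' @export
normalizeToControl <- function(treated, control) {
  if (!"total" %in% names(treated)) {
    if (all(c("clusters", "colonies") %in% names(treated)))
      treated$total <- treated$clusters + treated$colonies
    else stop("treated needs a 'total' or 'clusters'+'colonies' columns")
  }
  if (any(treated$concentration <= 0))
    stop("concentrations must be positive")
  ctrlMean <- mean(control)
  if (!is.finite(ctrlMean) || ctrlMean <= 0)
    stop("control mean must be positive")
  data.frame(concentration = treated$concentration,
             replicate = treated$replicate,
             response = treated$total / ctrlMean)
}

.checkDoseTable <- function(table) {
  need <- c("concentration", "response")
  if (!all(need %in% names(table)))
    stop("dose-response table needs columns concentration and response")
  if (any(table$concentration <= 0))
    stop("concentrations must be strictly positive")
  table[complete.cases(table[, need]), , drop = FALSE]
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \eqn{y = bottom + (top - bottom)/(1 + 10^{(logIC50 - x) hill})} on
#' \eqn{x = \log_{10}} concentration, via Levenberg-Marquardt. Self-starting
#' defaults: top = max response, bottom = min response, logIC50 = median x,
#' hill = -1 for falling data (+1 for rising). The IC50 is
#' \code{10^logIC50} nM. Requires at least 4 distinct concentrations;
#' non-convergence is flagged but parameters are still returned.
#'
#' @param table Dose-response table (\code{concentration} in nM,
#'   \code{response}; replicate rows allowed in any order).
#' @param init Optional named list of starting values
#'   (\code{top, bottom, logIC50, hill}).
#' @return A \code{\link[=DoseResponseFit]{DoseResponseFit}}.
#' @examples
#' tab <- simulateDoseResponse(list(top = 1, bottom = 0,
#'                                  logIC50 = log10(50), hill = -1),
#'                             concentrations = 500 / 5^(0:4),
#'                             nRep = 3, noiseSd = 0, seed = 1)
#' fit4PL(tab)
#' @export
fit4PL <- function(table, init = NULL) {
  table <- .checkDoseTable(table)
  x <- log10(table$concentration)
  y <- table$response
  if (length(unique(table$concentration)) < 4L)
    stop("fit4PL needs >= 4 distinct concentrations; ",
         "consider fitLinearIC50")
  rising <- if (length(unique(x)) > 1 && var(x) > 0)
    coef(lm(y ~ x))[2] > 0 else TRUE
  start <- list(top = max(y), bottom = min(y), logIC50 = median(x),
                hill = if (rising) 1 else -1)
  if (!is.null(init)) start[names(init)] <- init
  residFn <- function(p) y - fourPL(x, p[1], p[2], p[3], p[4])
  fit <- tryCatch(
    minpack.lm::nls.lm(par = unlist(start), fn = residFn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    co <- unlist(start)
    converged <- FALSE
    details <- list(error = conditionMessage(fit))
  } else {
    co <- fit$par
    ## info codes 1-3 signal convergence in x, f or both
    converged <- fit$info %in% 1:3
    details <- list(message = fit$message, niter = fit$niter)
  }
  resid <- residFn(co)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot > 0) 1 - sum(resid^2) / ssTot else NA_real_
  new("DoseResponseFit", model = "fourPL",
      coefficients = co[c("top", "bottom", "logIC50", "hill")],
      ic50 = unname(10^co[["logIC50"]]),
      rSquared = r2, converged = isTRUE(converged), details = details)
}

#' Linear-regression IC50 estimate
#'
#' Ordinary least squares of the normalized response on log10
#' concentration; the IC50 is the concentration at which the fitted line
#' crosses the half-response level:
#' \code{10^((level - intercept) / slope)}. Used when a sigmoidal fit is
#' not identifiable (fewer than 4 concentrations, or degenerate data).
#'
#' @param table Dose-response table (see \code{\link{fit4PL}}).
#' @param level Response level defining the IC50 on the normalized scale
#'   (default 0.5, i.e. half the vehicle control).
#' @return A \code{\link[=DoseResponseFit]{DoseResponseFit}} with
#'   \code{model = "linear"}.
#' @examples
#' fitLinearIC50(data.frame(concentration = c(1, 100),
#'                          response = c(1, 0)))
#' @export
fitLinearIC50 <- function(table, level = 0.5) {
  table <- .checkDoseTable(table)
  if (length(unique(table$concentration)) < 2L)
    stop("fitLinearIC50 needs >= 2 distinct concentrations")
  x <- log10(table$concentration)
  y <- table$response
  fit <- lm(y ~ x)
  co <- coef(fit)
  if (abs(co[2]) < 1e-12)
    stop("zero slope: IC50 undefined for a flat response")
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot > 0) 1 - sum(residuals(fit)^2) / ssTot else NA_real_
  new("DoseResponseFit", model = "linear",
      coefficients = c(intercept = unname(co[1]), slope = unname(co[2])),
      ic50 = unname(10^((level - co[1]) / co[2])),
      rSquared = r2, converged = TRUE, details = list(level = level))
}

#' Fit a dose-response curve with automatic model selection
#'
#' Attempts the four-parameter logistic fit first; if its preconditions
#' fail (fewer than 4 distinct concentrations), it does not converge, or
#' it returns a non-finite/absurd IC50, falls back to the linear
#' regression estimate. The chosen route is recorded in the result's
#' \code{details$route}.
#'
#' @param table Dose-response table (see \code{\link{fit4PL}}).
#' @param level IC50 crossing level for the linear fallback (default 0.5).
#' @return A \code{\link[=DoseResponseFit]{DoseResponseFit}}.
#' @export
selectAndFit <- function(table, level = 0.5) {
  table <- .checkDoseTable(table)
  fourOk <- length(unique(table$concentration)) >= 4L
  if (fourOk) {
    fit <- tryCatch(fit4PL(table), error = function(e) NULL)
    if (!is.null(fit) && fit@converged && is.finite(fit@ic50) &&
        fit@ic50 > 0) {
      fit@details$route <- "fourPL"
      return(fit)
    }
  }
  lin <- tryCatch(fitLinearIC50(table, level = level), error = function(e) e)
  if (inherits(lin, "error"))
    stop("both sigmoidal and linear fits failed: ", conditionMessage(lin))
  lin@details$route <- if (fourOk) "linear_fallback" else "linear"
  lin
}
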