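## 4PL fitting, EC-quantile inversion, normalized log-dose AUC, and the
## delta-AUC combination call.

#' Construct a DoseResponseCurve directly from parameters
#'
#' @param eMin,eMax lower/upper plateaus (% viability)
#' @param ec50 midpoint dose, uM
#' @param hill slope (> 0)
#' @param rss residual sum of squares (0 for an exact curve)
#' @param nPoints number of points behind the fit
#' @param degenerate flat-data flag
#' @return a [DoseResponseCurve-class]
#' @export
doseResponseCurve <- function(eMin, eMax, ec50, hill, rss = 0,
                              nPoints = 0L, degenerate = FALSE) {
  new("DoseResponseCurve", eMin = as.numeric(eMin), eMax = as.numeric(eMax),
      ec50 = as.numeric(ec50), hill = as.numeric(hill),
      rss = as.numeric(rss), nPoints = as.integer(nPoints),
      degenerate = degenerate)
}

fourPL <- function(d, eMin, eMax, ec50, hill) {
  eMin + (eMax - eMin) / (1 + (d / ec50)^hill)
}

#' @rdname predictResponse
#' @export
setMethod("predictResponse", "DoseResponseCurve", function(object, dose) {
  fourPL(dose, object@eMin, object@eMax, object@ec50, object@hill)
})

setMethod("show", "DoseResponseCurve", function(object) {
  cat(sprintf(
    "DoseResponseCurve: eMax %.3g -> eMin %.3g, EC50 %.4g uM, hill %.3g%s\n",
    object@eMax, object@eMin, object@ec50, object@hill,
    if (object@degenerate) " [degenerate: flat data]" else ""))
  if (object@nPoints > 0)
    cat(sprintf("  fit to %d points, RSS %.4g\n", object@nPoints, object@rss))
})

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `r(d) = eMin + (eMax - eMin)/(1 + (d/ec50)^hill)`
#' (viability orientation: response falls with dose). Zero-dose points are
#' legal and anchor `eMax`. The fit is multi-start -- `ec50` initialized at
#' each observed positive dose crossed with hill starts 0.5, 1 and 2 -- and
#' the best residual sum of squares wins. Parameters are bounded:
#' `eMin, eMax` in [-10, 120], `ec50` within 1e-4x the smallest to 1e4x the
#' largest observed positive dose, `hill` in [0.1, 10]. Flat data (zero
#' response variance) yields a degenerate flat curve rather than an error.
#'
#' @param doses numeric vector, uM (>= 4 distinct positive doses)
#' @param responses numeric vector, % viability
#' @return a [DoseResponseCurve-class]
#' @export
fit4PL <- function(doses, responses) {
  stopifnot(length(doses) == length(responses), all(is.finite(doses)),
            all(is.finite(responses)), all(doses >= 0))
  posDoses <- unique(doses[doses > 0])
  if (length(posDoses) < 4L)
    stop("need at least 4 distinct positive doses to fit a 4PL")
  n <- length(doses)
  if (stats::var(responses) == 0)
    return(doseResponseCurve(responses[1], responses[1],
                             ec50 = stats::median(posDoses), hill = 1,
                             rss = 0, nPoints = n, degenerate = TRUE))
  lower <- c(eMin = -10, eMax = -10,
             lec50 = log(1e-4 * min(posDoses)), lhill = log(0.1))
  upper <- c(eMin = 120, eMax = 120,
             lec50 = log(1e4 * max(posDoses)), lhill = log(10))
  df <- data.frame(d = doses, r = responses)
  best <- NULL
  for (e0 in posDoses) {
    for (h0 in c(0.5, 1, 2)) {
      start <- list(eMin = max(min(responses), -10),
                    eMax = min(max(responses), 120),
                    lec50 = log(e0), lhill = log(h0))
      fit <- tryCatch(
        minpack.lm::nlsLM(
          r ~ eMin + (eMax - eMin) / (1 + (d / exp(lec50))^exp(lhill)),
          data = df, start = start, lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(rss = rss, coef = stats::coef(fit))
    }
  }
  if (is.null(best))
    stop("4PL fit failed from every start")
  cf <- best$coef
  eMin <- unname(cf["eMin"]); eMax <- unname(cf["eMax"])
  if (eMin > eMax) {   # keep viability orientation; near-flat fits only
    mid <- (eMin + eMax) / 2
    eMin <- eMax <- mid
  }
  doseResponseCurve(eMin, eMax, exp(unname(cf["lec50"])),
                    exp(unname(cf["lhill"])), best$rss, n, FALSE)
}

#' Dose at a given fraction of the curve's effect
#'
#' Closed-form inversion of the 4PL: the dose at which the response equals
#' `eMax - q * (eMax - eMin)`; `q = 0.5` returns EC50, `q = 0.1` the EC10.
#'
#' @param curve a non-degenerate [DoseResponseCurve-class]
#' @param q fraction of the maximal effect, in (0, 1)
#' @return dose in uM
#' @export
ecQuantile <- function(curve, q) {
  if (q <= 0 || q >= 1) stop("q must lie strictly between 0 and 1")
  if (curve@degenerate) stop("EC quantile undefined for a flat curve")
  curve@ec50 * (q / (1 - q))^(1 / curve@hill)
}

#' Normalized area under a dose-response curve
#'
#' Trapezoidal integral of `response/100` over log10(dose), divided by the
#' log10-dose span, so a flat 100%-viability profile scores exactly 1 and a
#' flat 50% profile 0.5. Doses must be positive (drop the zero-dose anchor
#' before integrating).
#'
#' @param doses positive doses, uM (>= 2 distinct)
#' @param responses % viability at those doses
#' @return normalized AUC (dimensionless)
#' @export
aucLogDose <- function(doses, responses) {
  stopifnot(length(doses) == length(responses))
  if (any(doses <= 0))
    stop("aucLogDose requires positive doses (handle dose 0 upstream)")
  o <- order(doses)
  x <- log10(doses[o]); y <- responses[o] / 100
  if (length(unique(x)) < 2L) stop("need at least 2 distinct doses")
  span <- x[length(x)] - x[1]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) / span
}

#' Delta-AUC and the combination call
#'
#' Compares a compound's monotherapy dose-response with its response in
#' combination with an anchor drug on the same dose grid.
#' `deltaAUC = auc(mono) - auc(combo)` (positive when the combination
#' lowers viability more), and the combination flag is raised when the
#' combination reduces viability by more than `reductionPct` percentage
#' points relative to monotherapy at one or more doses.
#'
#' @param doses shared positive dose grid, uM
#' @param mono,combo % viability vectors on that grid
#' @param reductionPct per-dose viability-reduction threshold (default 10)
#' @return list with `deltaAUC`, `combines` (logical), `maxDeficit`
#'   (largest per-dose viability deficit, percentage points)
#' @export
deltaAUC <- function(doses, mono, combo, reductionPct = 10) {
  if (length(mono) != length(doses) || length(combo) != length(doses))
    stop("mono/combo must share the dose grid")
  deficit <- mono - combo
  list(deltaAUC = aucLogDose(doses, mono) - aucLogDose(doses, combo),
       combines = any(deficit > reductionPct),
       maxDeficit = max(deficit))
}
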