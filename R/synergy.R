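## ZIP synergy scoring of dose-combination matrices, with Bliss excess as
## the model-free cross-check.

#' Construct a CombinationMatrix
#'
#' @param drug1Id,drug2Id drug identifiers (drug 1 runs down the rows)
#' @param doses1,doses2 ascending dose vectors in uM, first element 0
#' @param viability % viability matrix, rows = doses1, cols = doses2
#' @param replicates optional list of replicate viability matrices; when
#'   given, `viability` should be their mean
#' @return a [CombinationMatrix-class]
#' @export
combinationMatrix <- function(drug1Id, drug2Id, doses1, doses2, viability,
                              replicates = list()) {
  new("CombinationMatrix", drug1Id = drug1Id, drug2Id = drug2Id,
      doses1 = as.numeric(doses1), doses2 = as.numeric(doses2),
      viability = viability, replicates = replicates)
}

setMethod("show", "CombinationMatrix", function(object) {
  cat(sprintf("CombinationMatrix %s x %s: %dx%d doses%s\n",
              object@drug1Id, object@drug2Id,
              length(object@doses1), length(object@doses2),
              if (length(object@replicates))
                sprintf(" (%d replicates)", length(object@replicates))
              else ""))
  cat(sprintf("  untreated cell: %.1f%% viability\n",
              object@viability[1, 1]))
})

#' Fractional inhibition from percent viability
#'
#' `y = clamp((100 - viability)/100, 0, 1)`. Growth stimulation above 100%
#' viability clamps to zero inhibition.
#'
#' @param viability numeric vector/matrix, % viability
#' @return fractional inhibition in [0, 1], same shape
#' @export
inhibition <- function(viability) {
  stopifnot(all(is.finite(viability)))
  pmin(pmax((100 - viability) / 100, 0), 1)
}

#' ZIP/Bliss expected combination inhibition
#'
#' The zero-interaction expectation for two independent drugs on the
#' fractional-inhibition scale: `y1 + y2 - y1*y2`.
#'
#' @param y1,y2 fractional inhibitions in [0, 1]
#' @return expected combination inhibition
#' @export
zipExpected <- function(y1, y2) {
  if (any(y1 < 0 | y1 > 1 | y2 < 0 | y2 > 1))
    stop("inhibitions must lie in [0, 1]")
  y1 + y2 - y1 * y2
}

## Conditional 4PL on the inhibition scale with the zero-dose asymptote
## pinned at y0: y(d) = y0 + (yMax - y0) / (1 + (ec50/d)^hill).
## Returns fitted values at the observed doses, or NULL when flat/failed.
fitConditional <- function(doses, yObs, y0) {
  if (stats::var(yObs) < 1e-12) return(NULL)
  df <- data.frame(d = doses, y = yObs)
  lower <- c(yMax = -0.2, lec50 = log(1e-4 * min(doses)), lhill = log(0.1))
  upper <- c(yMax = 1.2, lec50 = log(1e4 * max(doses)), lhill = log(10))
  best <- NULL
  for (e0 in doses) {
    for (h0 in c(0.5, 1, 2)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ y0 + (yMax - y0) / (1 + (exp(lec50) / d)^exp(lhill)),
          data = df,
          start = list(yMax = max(yObs), lec50 = log(e0), lhill = log(h0)),
          lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 150)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(rss = rss, fit = fit)
    }
  }
  if (is.null(best)) return(NULL)
  as.numeric(stats::fitted(best$fit))
}

#' Per-well ZIP delta surface
#'
#' The ZIP score of each combination cell: (i) fit a 4PL to each
#' monotherapy axis; (ii) at each fixed positive dose of drug 1, fit a
#' conditional 4PL across drug-2 doses with its zero-dose asymptote pinned
#' to drug 1's fitted monotherapy inhibition at that dose; (iii) the
#' symmetric fits with the drugs' roles swapped; (iv) the fitted
#' combination inhibition of a cell is the average of the two conditional
#' fits; (v) `delta[i,j] = 100 * (yFitted - zipExpected(y1_i, y2_j))` for
#' cells with both doses positive. Cells whose conditional fits are
#' degenerate (flat data) fall back to the observed inhibition and are
#' counted in the `fallback` attribute.
#'
#' @param m a [CombinationMatrix-class] with >= 4 positive doses per drug
#' @return numeric matrix shaped like the viability matrix; NA on the
#'   monotherapy axes; attribute `fallback` = number of fallback cells
#' @seealso [zipSynergy()], [blissExcessMatrix()]
#' @export
zipDeltaMatrix <- function(m) {
  stopifnot(is(m, "CombinationMatrix"))
  d1 <- m@doses1; d2 <- m@doses2
  if (sum(d1 > 0) < 4L || sum(d2 > 0) < 4L)
    stop("need at least 4 positive doses per drug for the conditional fits")
  yObs <- inhibition(m@viability)
  fit1 <- fit4PL(d1, m@viability[, 1])
  fit2 <- fit4PL(d2, m@viability[1, ])
  y1 <- pmin(pmax(1 - predictResponse(fit1, d1) / 100, 0), 1)
  y2 <- pmin(pmax(1 - predictResponse(fit2, d2) / 100, 0), 1)
  i1 <- which(d1 > 0); i2 <- which(d2 > 0)
  fb <- 0L
  yRow <- matrix(NA_real_, nrow(yObs), ncol(yObs))  # drug2 swept at fixed d1
  for (i in i1) {
    f <- fitConditional(d2[i2], yObs[i, i2], y0 = y1[i])
    if (is.null(f)) { f <- yObs[i, i2]; fb <- fb + 1L }
    yRow[i, i2] <- f
  }
  yCol <- matrix(NA_real_, nrow(yObs), ncol(yObs))  # drug1 swept at fixed d2
  for (j in i2) {
    f <- fitConditional(d1[i1], yObs[i1, j], y0 = y2[j])
    if (is.null(f)) { f <- yObs[i1, j]; fb <- fb + 1L }
    yCol[i1, j] <- f
  }
  yC <- (yRow + yCol) / 2
  delta <- matrix(NA_real_, nrow(yObs), ncol(yObs))
  for (i in i1) for (j in i2)
    delta[i, j] <- 100 * (yC[i, j] - zipExpected(y1[i], y2[j]))
  dimnames(delta) <- list(d1, d2)
  attr(delta, "fallback") <- fb
  delta
}

#' Overall, most-synergistic-area, and threshold classification
#'
#' `overallSynergy` is the arithmetic mean of the defined delta cells (both
#' doses positive). `msaScore` is the maximum mean over all contiguous
#' `window x window` submatrices of the defined delta region; if the region
#' is smaller than the window, the largest available square is used with a
#' warning. `classifySynergy` applies the inclusive threshold.
#'
#' @param delta a delta matrix from [zipDeltaMatrix()] (NA axes allowed)
#' @param window msa window edge (default 3)
#' @param score a synergy score
#' @param threshold classification bound (default 5)
#' @return numeric score, or logical for `classifySynergy`
#' @export
overallSynergy <- function(delta) mean(delta, na.rm = TRUE)

#' @rdname overallSynergy
#' @export
msaScore <- function(delta, window = 3L) {
  keepR <- rowSums(!is.na(delta)) > 0
  keepC <- colSums(!is.na(delta)) > 0
  d <- delta[keepR, keepC, drop = FALSE]
  w <- min(window, nrow(d), ncol(d))
  if (w < window)
    warning("delta region smaller than the msa window; using ", w, "x", w)
  best <- -Inf
  for (i in seq_len(nrow(d) - w + 1L))
    for (j in seq_len(ncol(d) - w + 1L)) {
      v <- mean(d[i:(i + w - 1L), j:(j + w - 1L)])
      if (is.finite(v) && v > best) best <- v
    }
  best
}

#' @rdname overallSynergy
#' @export
classifySynergy <- function(score, threshold = 5) score >= threshold

#' Full ZIP synergy report for one combination matrix
#'
#' Runs [zipDeltaMatrix()], [overallSynergy()], [msaScore()] and the
#' threshold classification, returning a [SynergyReport-class].
#'
#' @param m a [CombinationMatrix-class]
#' @param threshold synergy-classification bound (default 5, inclusive)
#' @param window msa window edge (default 3)
#' @return a [SynergyReport-class]
#' @export
zipSynergy <- function(m, threshold = 5, window = 3L) {
  delta <- zipDeltaMatrix(m)
  ov <- overallSynergy(delta)
  new("SynergyReport", method = "ZIP", delta = unclass(delta),
      overallScore = ov, msaScore = msaScore(delta, window),
      msaWindow = as.integer(window),
      synergistic = classifySynergy(ov, threshold),
      threshold = threshold,
      fallbackCells = attr(delta, "fallback") %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname SynergyReport-class
#' @export
setMethod("deltaMatrix", "SynergyReport", function(object) object@delta)

#' @rdname SynergyReport-class
#' @export
setMethod("overallScore", "SynergyReport", function(object) object@overallScore)

#' @rdname SynergyReport-class
#' @export
setMethod("isSynergistic", "SynergyReport", function(object) object@synergistic)

setMethod("show", "SynergyReport", function(object) {
  cat(sprintf("SynergyReport (%s): overall %.2f, msa %.2f (%dx%d) -> %s\n",
              object@method, object@overallScore, object@msaScore,
              object@msaWindow, object@msaWindow,
              if (object@synergistic) "synergistic" else "not synergistic"))
  if (object@fallbackCells > 0)
    cat("  note:", object@fallbackCells,
        "conditional fits fell back to observed values\n")
})

#' Model-free Bliss excess surface
#'
#' `excess[i,j] = 100 * (yObs[i,j] - zipExpected(yObs[i,0], yObs[0,j]))`
#' computed directly from observed monotherapy cells -- no curve fitting.
#' Used as the internal oracle for the fitted ZIP surface; exactly
#' symmetric under drug swap.
#'
#' @param m a [CombinationMatrix-class]
#' @return numeric matrix, NA on the monotherapy axes
#' @export
blissExcessMatrix <- function(m) {
  stopifnot(is(m, "CombinationMatrix"))
  yObs <- inhibition(m@viability)
  excess <- matrix(NA_real_, nrow(yObs), ncol(yObs))
  i1 <- which(m@doses1 > 0); i2 <- which(m@doses2 > 0)
  for (i in i1) for (j in i2)
    excess[i, j] <- 100 * (yObs[i, j] - zipExpected(yObs[i, 1], yObs[1, j]))
  dimnames(excess) <- list(m@doses1, m@doses2)
  excess
}
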