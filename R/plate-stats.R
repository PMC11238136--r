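## Plate normalization, assay QC, and B-score hit calling.

#' Two-way median polish
#'
#' Tukey's iterative decomposition of a matrix into
#' `overall + rowEffect + colEffect + residual` by alternately sweeping out
#' row and column medians. Missing values are permitted and ignored by the
#' medians. Convergence is declared when every residual row and column
#' median is below `tol` in absolute value.
#'
#' @param x numeric matrix, at least 2x2, with at least one finite value in
#'   every row and column
#' @param maxIter maximum number of full row+column sweeps
#' @param tol convergence tolerance on residual medians
#' @return a [MedianPolishFit-class] object
#' @examples
#' fit <- medianPolish(matrix(c(1, 2, 3, 4), 2))
#' max(abs(fit@residuals))   # additive matrix: all residuals 0
#' @export
medianPolish <- function(x, maxIter = 20L, tol = 1e-6) {
  if (!is.matrix(x) || nrow(x) < 2L || ncol(x) < 2L)
    stop("median polish needs a matrix of at least 2x2")
  obs <- is.finite(x)
  emptyRows <- which(rowSums(obs) == 0L)
  if (length(emptyRows))
    stop("row(s) with no finite values: ", paste(emptyRows, collapse = ", "))
  emptyCols <- which(colSums(obs) == 0L)
  if (length(emptyCols))
    stop("column(s) with no finite values: ",
         paste(emptyCols, collapse = ", "))
  r <- x
  overall <- 0
  re <- numeric(nrow(x))
  ce <- numeric(ncol(x))
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    rm <- apply(r, 1L, stats::median, na.rm = TRUE)
    r <- r - rm
    re <- re + rm
    mc <- stats::median(ce)
    ce <- ce - mc
    overall <- overall + mc
    cm <- apply(r, 2L, stats::median, na.rm = TRUE)
    r <- sweep(r, 2L, cm)
    ce <- ce + cm
    mr <- stats::median(re)
    re <- re - mr
    overall <- overall + mr
    rowMed <- apply(r, 1L, stats::median, na.rm = TRUE)
    colMed <- apply(r, 2L, stats::median, na.rm = TRUE)
    if (max(abs(c(rowMed, colMed))) < tol) {
      converged <- TRUE
      break
    }
  }
  new("MedianPolishFit", overall = overall, rowEffects = re, colEffects = ce,
      residuals = r, nIterations = it, converged = converged)
}

#' Percent activity relative to negative controls
#'
#' Scales every well to percent of the plate's negative-control (vehicle)
#' median: `100 * signal / median(negative-control signals)`. Background
#' wells never enter the control median. The median percent activity over
#' the negative-control wells is exactly 100 by construction.
#'
#' @param plate a [PlateGrid-class]
#' @return numeric matrix of percent activity (NA where signal missing)
#' @export
percentActivity <- function(plate) {
  neg <- negativeControlSignals(plate)
  if (length(neg) < 4L)
    stop("plate ", plate@plateId,
         ": need at least 4 finite negative-control wells")
  med <- stats::median(neg)
  if (med <= 0)
    stop("plate ", plate@plateId, ": negative-control median is not positive")
  100 * plate@signal / med
}

#' Z-factor assay quality statistic
#'
#' `Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|` from the two
#' control arms, using sample standard deviations. Values approach 1 for
#' well-separated controls; the screen is flagged highly screenable when
#' `Z' >= screenableMin` (default 0.7).
#'
#' @param positive,negative numeric vectors of control signals (>= 2 each)
#' @param screenableMin screenability bound applied to the flag
#' @return list with `value` (the Z-factor, possibly negative) and
#'   `screenable` (logical)
#' @examples
#' zFactor(c(10, 10), c(100, 100, 110, 90))$value
#' @export
zFactor <- function(positive, negative, screenableMin = 0.7) {
  if (length(positive) < 2L || length(negative) < 2L)
    stop("need at least 2 values per control arm")
  mp <- mean(positive); mn <- mean(negative)
  if (mp == mn) stop("control means are equal: Z-factor undefined")
  z <- 1 - 3 * (stats::sd(positive) + stats::sd(negative)) / abs(mp - mn)
  list(value = z, screenable = z >= screenableMin)
}

## Median polish with all-missing rows/columns tolerated: such rows/columns
## (e.g. pure control columns masked out of effect estimation) get effect 0.
maskedPolish <- function(y, maxIter, tol) {
  obs <- is.finite(y)
  keepR <- rowSums(obs) > 0L
  keepC <- colSums(obs) > 0L
  fit <- medianPolish(y[keepR, keepC, drop = FALSE], maxIter, tol)
  re <- numeric(nrow(y)); re[keepR] <- fit@rowEffects
  ce <- numeric(ncol(y)); ce[keepC] <- fit@colEffects
  list(overall = fit@overall, rowEffects = re, colEffects = ce,
       nIterations = fit@nIterations, converged = fit@converged)
}

#' B-score plate normalization
#'
#' Computes per-well B-scores: the residual after removing row and column
#' positional effects by median polish, divided by a robust plate scale
#' (1.4826 x the median absolute deviation of the sample-well residuals).
#' Positional effects are estimated from sample wells only -- control wells
#' are masked out of the medians so that control columns cannot bias the
#' column effects -- but every measured well, controls included, receives a
#' score. By default the polish runs on log10 signal, matching the
#' multiplicative nature of luminescence plate artifacts; set
#' `logScale = FALSE` to polish raw signal.
#'
#' @param plate a [PlateGrid-class]
#' @param logScale polish log10 signal (default) or raw signal
#' @param maxIter,tol median polish controls
#' @return list with `bScore` (matrix), `madScale` (the robust scale,
#'   on the polished scale), `rowEffects`, `colEffects`, `overall`,
#'   `nIterations`, `converged`
#' @export
bScore <- function(plate, logScale = TRUE, maxIter = 20L, tol = 1e-6) {
  x <- plate@signal
  x[plate@role %in% "empty"] <- NA_real_
  if (logScale) {
    x[is.finite(x) & x <= 0] <- NA_real_
    x <- log10(x)
  }
  smp <- sampleMask(plate)
  if (sum(smp & is.finite(x)) < 8L)
    stop("plate ", plate@plateId,
         ": need at least 8 finite sample wells for a stable scale")
  y <- x
  y[!smp] <- NA_real_
  fit <- maskedPolish(y, maxIter, tol)
  res <- x - fit$overall - outer(fit$rowEffects, fit$colEffects, `+`)
  rs <- res[smp & is.finite(res)]
  madScale <- 1.4826 * stats::median(abs(rs - stats::median(rs)))
  if (madScale == 0)
    stop("plate ", plate@plateId, ": degenerate plate (sample-well MAD is 0)")
  c(list(bScore = res / madScale, madScale = madScale), fit)
}

#' Normalize one plate: percent activity, B-scores and QC
#'
#' Bundles [percentActivity()], [bScore()] and [zFactor()] (positive vs
#' negative control raw signals) for a plate.
#'
#' @inheritParams bScore
#' @return list with `percentActivity`, `bScore`, `madScale`, `zFactor`
#'   (list of value/screenable, or NULL when a control arm is absent)
#' @export
normalizePlate <- function(plate, logScale = TRUE, maxIter = 20L,
                           tol = 1e-6) {
  b <- bScore(plate, logScale = logScale, maxIter = maxIter, tol = tol)
  pos <- plate@signal[plate@role %in% "positive_control"]
  pos <- pos[is.finite(pos)]
  neg <- negativeControlSignals(plate)
  zf <- if (length(pos) >= 2L && length(neg) >= 2L) zFactor(pos, neg)
        else NULL
  list(percentActivity = percentActivity(plate), bScore = b$bScore,
       madScale = b$madScale, zFactor = zf)
}

#' Call hits from B-scores against the negative-control distribution
#'
#' A well is a down-hit when its B-score is at or below
#' `mean(negB) - k * sd(negB)`; up-hits are symmetric; `direction = "both"`
#' flags either tail. The boundary is inclusive.
#'
#' @param b numeric vector or matrix of B-scores
#' @param negB numeric vector of negative-control B-scores (>= 4)
#' @param k control-SD multiplier (default 3)
#' @param direction "down" (default; the screen seeks decreased signal),
#'   "up", or "both"
#' @return logical vector/matrix of hit flags (NA where `b` is NA)
#' @export
callHits <- function(b, negB, k = 3, direction = c("down", "up", "both")) {
  direction <- match.arg(direction)
  negB <- negB[is.finite(negB)]
  if (length(negB) < 4L)
    stop("need at least 4 finite negative-control B-scores")
  s <- stats::sd(negB)
  if (s == 0) stop("negative-control B-score SD is 0")
  m <- mean(negB)
  down <- b <= m - k * s
  up <- b >= m + k * s
  switch(direction, down = down, up = up, both = down | up)
}
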