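#' @import methods
NULL

WELL_ROLES <- c("sample", "negative_control", "positive_control",
                "background", "background_no_enzyme", "empty")

PLATE_DIMS <- list(`96` = c(8L, 12L), `384` = c(16L, 24L))

#' PlateGrid: one plate's annotated signal matrix for one channel
#'
#' A `PlateGrid` holds the raw readout of a single microtiter plate in a
#' single channel (luminescence or viability) together with per-well
#' annotation: role (sample, negative/positive control, background, empty),
#' compound identity, library of origin, and dose in micromolar. Wells are
#' addressed by 0-based (row, column) indices internally and displayed as
#' letter + zero-padded column ("A01"). Missing signal (`NA`) marks an empty
#' or unread well and is distinct from a measured zero.
#'
#' @slot plateId character(1) plate identifier.
#' @slot format integer(1), 96 or 384.
#' @slot channel character(1), "luminescence" or "viability".
#' @slot signal numeric matrix (8x12 or 16x24) of raw signal; `NA` allowed
#'   for empty wells; finite values must be >= 0.
#' @slot role character matrix of well roles (see `wellRoles`).
#' @slot compoundId character matrix; `NA` for non-sample wells.
#' @slot library character matrix; `NA` where not applicable.
#' @slot dose numeric matrix of doses in uM; `NA` for non-sample wells.
#'
#' @seealso [PlateGrid()] constructor, [readLongTable()], [percentActivity()],
#'   [bScore()]
#' @name PlateGrid-class
#' @aliases PlateGrid-class
#' @exportClass PlateGrid
setClass("PlateGrid",
  representation(
    plateId = "character",
    format = "integer",
    channel = "character",
    signal = "matrix",
    role = "matrix",
    compoundId = "matrix",
    library = "matrix",
    dose = "matrix"
  )
)

setValidity("PlateGrid", function(object) {
  msg <- character()
  if (length(object@plateId) != 1L || !nzchar(object@plateId))
    msg <- c(msg, "plateId must be a single non-empty string")
  if (!object@format %in% c(96L, 384L))
    msg <- c(msg, "format must be 96 or 384")
  if (!object@channel %in% c("luminescence", "viability"))
    msg <- c(msg, "channel must be 'luminescence' or 'viability'")
  dims <- PLATE_DIMS[[as.character(object@format)]]
  for (sl in c("signal", "role", "compoundId", "library", "dose")) {
    m <- slot(object, sl)
    if (!identical(dim(m), dims))
      msg <- c(msg, sprintf("%s must be %dx%d for a %d-well plate",
                            sl, dims[1], dims[2], object@format))
  }
  sig <- object@signal
  if (any(is.finite(sig) & sig < 0))
    msg <- c(msg, "signal must be non-negative where present")
  bad <- setdiff(unique(as.vector(object@role)), c(WELL_ROLES, NA))
  if (length(bad))
    msg <- c(msg, paste("unknown well role:", paste(bad, collapse = ", ")))
  nonempty <- object@role != "empty"
  if (any(nonempty & !is.finite(object@signal) & !is.na(object@signal)))
    msg <- c(msg, "non-empty wells must have finite or NA signal")
  if (length(msg)) msg else TRUE
})

#' MedianPolishFit: additive decomposition of a plate matrix
#'
#' Result of Tukey's two-way median polish: the input decomposes exactly as
#' `overall + rowEffects[i] + colEffects[j] + residuals[i,j]` for every cell
#' where the input was observed.
#'
#' @slot overall numeric(1) grand effect.
#' @slot rowEffects,colEffects numeric vectors of row/column effects.
#' @slot residuals numeric matrix of residuals (same dim as input).
#' @slot nIterations integer(1) sweeps performed.
#' @slot converged logical(1) whether effect changes fell below `tol`.
#' @seealso [medianPolish()]
#' @name MedianPolishFit-class
#' @exportClass MedianPolishFit
setClass("MedianPolishFit",
  representation(
    overall = "numeric",
    rowEffects = "numeric",
    colEffects = "numeric",
    residuals = "matrix",
    nIterations = "integer",
    converged = "logical"
  )
)

#' DoseResponseCurve: four-parameter logistic fit
#'
#' Parameters of `r(d) = eMin + (eMax - eMin) / (1 + (d/ec50)^hill)` with
#' response in percent viability (eMax is the zero-dose response, eMin the
#' infinite-dose plateau).
#'
#' @slot eMin,eMax numeric(1) lower/upper response plateaus (% viability).
#' @slot ec50 numeric(1) midpoint dose, uM.
#' @slot hill numeric(1) slope, positive.
#' @slot rss numeric(1) residual sum of squares of the fit.
#' @slot nPoints integer(1) number of data points fitted.
#' @slot degenerate logical(1) TRUE when the data carried no dose-response
#'   signal (flat), in which case eMin == eMax and ec50/hill are nominal.
#' @seealso [fit4PL()], [predictResponse()], [ecQuantile()]
#' @name DoseResponseCurve-class
#' @exportClass DoseResponseCurve
setClass("DoseResponseCurve",
  representation(
    eMin = "numeric", eMax = "numeric", ec50 = "numeric", hill = "numeric",
    rss = "numeric", nPoints = "integer", degenerate = "logical"
  )
)

setValidity("DoseResponseCurve", function(object) {
  msg <- character()
  if (object@ec50 <= 0) msg <- c(msg, "ec50 must be positive")
  if (object@hill <= 0) msg <- c(msg, "hill must be positive")
  if (object@eMin > object@eMax + 1e-9)
    msg <- c(msg, "eMin must not exceed eMax (viability orientation)")
  if (length(msg)) msg else TRUE
})

#' CombinationMatrix: a two-drug dose-combination response surface
#'
#' Two ascending dose vectors (first element 0 = monotherapy axes) and a
#' matrix of percent-viability responses; rows follow `doses1` (drug 1),
#' columns follow `doses2` (drug 2). Optional replicate surfaces are stored
#' alongside; `viability` is their mean when replicates are present.
#'
#' @slot drug1Id,drug2Id character(1) drug identifiers.
#' @slot doses1,doses2 numeric ascending dose vectors in uM, starting at 0.
#' @slot viability numeric matrix, % viability.
#' @slot replicates list of replicate viability matrices (possibly empty).
#' @seealso [combinationMatrix()], [zipDeltaMatrix()], [blissExcessMatrix()]
#' @name CombinationMatrix-class
#' @exportClass CombinationMatrix
setClass("CombinationMatrix",
  representation(
    drug1Id = "character", drug2Id = "character",
    doses1 = "numeric", doses2 = "numeric",
    viability = "matrix", replicates = "list"
  )
)

setValidity("CombinationMatrix", function(object) {
  msg <- character()
  for (nm in c("doses1", "doses2")) {
    d <- slot(object, nm)
    if (length(d) < 2L || d[1] != 0 || any(diff(d) <= 0))
      msg <- c(msg, sprintf("%s must be strictly ascending and start at 0", nm))
  }
  if (!identical(dim(object@viability),
                 c(length(object@doses1), length(object@doses2))))
    msg <- c(msg, "viability dims must match dose vector lengths")
  if (any(!is.finite(object@viability)))
    msg <- c(msg, "viability must be finite")
  for (r in object@replicates)
    if (!identical(dim(r), dim(object@viability)))
      msg <- c(msg, "replicate dims must match viability")
  if (length(msg)) msg else TRUE
})

#' SynergyReport: ZIP synergy scores for one combination matrix
#'
#' Per-well delta surface (percent-inhibition scale, defined where both
#' doses are positive), the overall score (mean of defined delta cells), the
#' most-synergistic-area score (maximum mean over contiguous square windows),
#' and the threshold classification.
#'
#' @slot method character(1), "ZIP".
#' @slot delta numeric matrix; `NA` on the monotherapy axes.
#' @slot overallScore numeric(1) mean of defined delta cells.
#' @slot msaScore numeric(1) most-synergistic-area score.
#' @slot msaWindow integer(1) window edge used for msa.
#' @slot synergistic logical(1) `overallScore >= threshold`.
#' @slot threshold numeric(1) classification bound applied.
#' @slot fallbackCells integer(1) cells where a degenerate conditional fit
#'   fell back to the observed value.
#' @seealso [zipSynergy()], [overallSynergy()], [msaScore()]
#' @name SynergyReport-class
#' @exportClass SynergyReport
setClass("SynergyReport",
  representation(
    method = "character", delta = "matrix",
    overallScore = "numeric", msaScore = "numeric", msaWindow = "integer",
    synergistic = "logical", threshold = "numeric",
    fallbackCells = "integer"
  )
)
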