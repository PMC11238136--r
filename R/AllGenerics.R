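#' @rdname PlateGrid-class
#' @param object a `PlateGrid`
#' @export
setGeneric("plateId", function(object) standardGeneric("plateId"))

#' @rdname PlateGrid-class
#' @export
setGeneric("plateFormat", function(object) standardGeneric("plateFormat"))

#' @rdname PlateGrid-class
#' @export
setGeneric("plateChannel", function(object) standardGeneric("plateChannel"))

#' @rdname PlateGrid-class
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))

#' @rdname PlateGrid-class
#' @export
setGeneric("wellRoles", function(object) standardGeneric("wellRoles"))

#' @rdname PlateGrid-class
#' @export
setGeneric("compoundIds", function(object) standardGeneric("compoundIds"))

#' @rdname PlateGrid-class
#' @export
setGeneric("wellDoses", function(object) standardGeneric("wellDoses"))

#' @rdname PlateGrid-class
#' @export
setGeneric("sampleMask", function(object) standardGeneric("sampleMask"))

#' Predicted response of a dose-response curve
#'
#' Evaluates the four-parameter logistic at the given doses. `predictResponse`
#' returns percent viability; dose 0 maps exactly to `eMax` and infinite dose
#' to `eMin`.
#'
#' @param object a `DoseResponseCurve`
#' @param dose numeric vector of doses, uM (0 allowed)
#' @return numeric vector of responses (% viability)
#' @export
setGeneric("predictResponse",
           function(object, dose) standardGeneric("predictResponse"))

#' @rdname SynergyReport-class
#' @param object a `SynergyReport`
#' @export
setGeneric("deltaMatrix", function(object) standardGeneric("deltaMatrix"))

#' @rdname SynergyReport-class
#' @export
setGeneric("overallScore", function(object) standardGeneric("overallScore"))

#' @rdname SynergyReport-class
#' @export
setGeneric("isSynergistic", function(object) standardGeneric("isSynergistic"))
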