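## Well-address conventions and PlateGrid construction/accessors.

plateDims <- function(format) {
  d <- PLATE_DIMS[[as.character(format)]]
  if (is.null(d)) stop("unsupported plate format: ", format)
  d
}

#' Well-address display and parsing
#'
#' Wells are indexed 0-based internally (`row` in 0..7 or 0..15, `column` in
#' 0..11 or 0..23) and displayed as a row letter plus a zero-padded column
#' number ("A01" .. "P24"). `wellName` and `parseWell` are exact inverses
#' over a plate format.
#'
#' @param row,column integer vectors, 0-based well coordinates
#' @param format plate format, 96 or 384
#' @param name character vector of well labels such as "B03"
#' @return `wellName`: character vector; `parseWell`: a data.frame with
#'   integer columns `row` and `column` (0-based).
#' @examples
#' wellName(1, 2)              # "B03"
#' parseWell("B03", 96)        # row 1, column 2
#' @export
wellName <- function(row, column, format = 96) {
  dims <- plateDims(format)
  if (any(row < 0 | row >= dims[1]))
    stop("row index out of range for ", format, "-well plate")
  if (any(column < 0 | column >= dims[2]))
    stop("column index out of range for ", format, "-well plate")
  paste0(LETTERS[row + 1L], formatC(column + 1L, width = 2, flag = "0"))
}

#' @rdname wellName
#' @export
parseWell <- function(name, format = 96) {
  dims <- plateDims(format)
  m <- regmatches(name, regexec("^([A-Pa-p])([0-9]{1,2})$", name))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("unparseable well address: ", paste(name[bad], collapse = ", "))
  row <- match(toupper(vapply(m, `[`, "", 2L)), LETTERS) - 1L
  col <- as.integer(vapply(m, `[`, "", 3L)) - 1L
  if (any(row >= dims[1]))
    stop("well row out of range for ", format, "-well plate: ",
         paste(name[row >= dims[1]], collapse = ", "))
  if (any(col < 0 | col >= dims[2]))
    stop("well column out of range for ", format, "-well plate: ",
         paste(name[col < 0 | col >= dims[2]], collapse = ", "))
  data.frame(row = row, column = col)
}

#' Construct a PlateGrid
#'
#' Builds an annotated plate from per-well matrices. Omitted annotation
#' matrices default to empty wells / missing annotation. Sample wells must
#' carry a compound id and a positive dose; control wells carry neither.
#'
#' @param plateId plate identifier
#' @param format 96 or 384
#' @param channel "luminescence" or "viability"
#' @param signal numeric matrix of raw signal (NA = empty/unread)
#' @param role character matrix of well roles
#' @param compoundId,library character matrices (optional)
#' @param dose numeric matrix of doses in uM (optional)
#' @return a [PlateGrid-class] object
#' @export
PlateGrid <- function(plateId, format, channel, signal, role,
                      compoundId = NULL, library = NULL, dose = NULL) {
  dims <- plateDims(format)
  blankChr <- matrix(NA_character_, dims[1], dims[2])
  blankNum <- matrix(NA_real_, dims[1], dims[2])
  if (is.null(compoundId)) compoundId <- blankChr
  if (is.null(library)) library <- blankChr
  if (is.null(dose)) dose <- blankNum
  storage.mode(signal) <- "double"
  storage.mode(dose) <- "double"
  obj <- new("PlateGrid", plateId = as.character(plateId),
             format = as.integer(format), channel = channel,
             signal = signal, role = role, compoundId = compoundId,
             library = library, dose = dose)
  smp <- obj@role == "sample" & !is.na(obj@role)
  if (any(smp & is.na(obj@compoundId)))
    stop("sample wells must carry a compound id (plate ", plateId, ")")
  if (any(smp & (is.na(obj@dose) | obj@dose <= 0)))
    stop("sample wells must carry a positive dose (plate ", plateId, ")")
  ctl <- obj@role %in% c("negative_control", "positive_control",
                         "background", "background_no_enzyme")
  if (any(ctl & !is.na(obj@compoundId)))
    stop("control wells must not carry a compound id (plate ", plateId, ")")
  obj
}

#' @rdname PlateGrid-class
#' @export
setMethod("plateId", "PlateGrid", function(object) object@plateId)

#' @rdname PlateGrid-class
#' @export
setMethod("plateFormat", "PlateGrid", function(object) object@format)

#' @rdname PlateGrid-class
#' @export
setMethod("plateChannel", "PlateGrid", function(object) object@channel)

#' @rdname PlateGrid-class
#' @export
setMethod("signalMatrix", "PlateGrid", function(object) object@signal)

#' @rdname PlateGrid-class
#' @export
setMethod("wellRoles", "PlateGrid", function(object) object@role)

#' @rdname PlateGrid-class
#' @export
setMethod("compoundIds", "PlateGrid", function(object) object@compoundId)

#' @rdname PlateGrid-class
#' @export
setMethod("wellDoses", "PlateGrid", function(object) object@dose)

#' @rdname PlateGrid-class
#' @export
setMethod("sampleMask", "PlateGrid",
          function(object) object@role == "sample" & !is.na(object@role))

setMethod("show", "PlateGrid", function(object) {
  tab <- table(factor(object@role[!is.na(object@role)], levels = WELL_ROLES))
  cat(sprintf("PlateGrid '%s' (%d-well, %s)\n", object@plateId,
              object@format, object@channel))
  cat("  wells:", paste(sprintf("%s=%d", names(tab)[tab > 0], tab[tab > 0]),
                        collapse = ", "), "\n")
  cat(sprintf("  signal: median %.4g over %d measured wells\n",
              stats::median(object@signal, na.rm = TRUE),
              sum(!is.na(object@signal))))
})

negativeControlSignals <- function(plate) {
  v <- plate@signal[plate@role %in% "negative_control"]
  v[is.finite(v)]
}
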