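## Knock-in design arithmetic: amplicon sizes, reading-frame checks, and
## donor-oligo accounting.

#' Expected knock-in amplicon size
#'
#' The targeted-allele PCR product is the wild-type amplicon plus the
#' inserted tag length (e.g. a 291 bp wild-type product with a 39 bp tag
#' yields 330 bp in correctly targeted clones).
#'
#' @param wtAmplicon wild-type amplicon length, bp
#' @param insertLength inserted sequence length, bp
#' @return targeted amplicon length, bp
#' @export
expectedAmplicon <- function(wtAmplicon, insertLength) {
  if (wtAmplicon < 0 || insertLength < 0)
    stop("lengths must be non-negative")
  as.integer(wtAmplicon + insertLength)
}

#' In-frame insertion check
#'
#' An insert preserves the downstream reading frame iff its length is a
#' multiple of 3.
#'
#' @param insertLength insert length, bp
#' @return logical
#' @export
frameCheck <- function(insertLength) {
  if (insertLength < 0) stop("length must be non-negative")
  insertLength %% 3 == 0
}

#' Scan a donor sequence for stop codons in a frame
#'
#' Reports the 1-based codon positions of TAA/TAG/TGA in the reading frame
#' starting at `frameOffset` (0, 1 or 2 bases in).
#'
#' @param donor DNA string (A/C/G/T only)
#' @param frameOffset 0-based frame offset
#' @return integer vector of codon positions (possibly empty)
#' @examples
#' stopScan("ATGTGA", 0)   # stop at codon 2
#' @export
stopScan <- function(donor, frameOffset = 0) {
  donor <- toupper(donor)
  if (grepl("[^ACGT]", donor))
    stop("donor contains non-ACGT characters")
  if (!frameOffset %in% 0:2) stop("frameOffset must be 0, 1 or 2")
  s <- substring(donor, frameOffset + 1)
  nCodons <- nchar(s) %/% 3
  if (nCodons == 0) return(integer(0))
  starts <- seq(1, by = 3, length.out = nCodons)
  codons <- substring(s, starts, starts + 2)
  which(codons %in% c("TAA", "TAG", "TGA"))
}

#' Donor-oligo accounting report
#'
#' Checks a single-stranded donor design: total length versus
#' `leftArm + insert + rightArm`, insert frame preservation, the expected
#' targeted amplicon size, and (when the insert sequence is given) whether
#' the donor contains the insert followed by an in-frame stop. Reported
#' inconsistencies are flagged, not resolved.
#'
#' @param donor donor DNA string
#' @param insertLength insert length, bp
#' @param leftArmLength,rightArmLength homology arm lengths, bp (optional)
#' @param wtAmplicon wild-type amplicon length, bp (optional)
#' @param insertSeq the insert DNA string (optional)
#' @return list: `donorLength`, `inFrame`, `targetedAmplicon` (or NA),
#'   `armAccountingConsistent` (or NA), `insertFound`, `stopAfterInsert`,
#'   `flags` (character vector of detected inconsistencies)
#' @export
donorReport <- function(donor, insertLength, leftArmLength = NA,
                        rightArmLength = NA, wtAmplicon = NA,
                        insertSeq = NULL) {
  donor <- toupper(donor)
  if (grepl("[^ACGT]", donor)) stop("donor contains non-ACGT characters")
  flags <- character()
  n <- nchar(donor)
  inFrame <- frameCheck(insertLength)
  if (!inFrame) flags <- c(flags, "insert length is not a multiple of 3")
  armsOk <- NA
  if (!is.na(leftArmLength) && !is.na(rightArmLength)) {
    armsOk <- n == leftArmLength + insertLength + rightArmLength
    if (!armsOk)
      flags <- c(flags, sprintf(
        "donor length %d != left %d + insert %d + right %d",
        n, leftArmLength, insertLength, rightArmLength))
  }
  insertFound <- NA
  stopAfter <- NA
  if (!is.null(insertSeq)) {
    insertSeq <- toupper(insertSeq)
    pos <- regexpr(insertSeq, donor, fixed = TRUE)[1]
    insertFound <- pos > 0
    if (!insertFound) flags <- c(flags, "insert sequence not found in donor")
    else {
      after <- substring(donor, pos + nchar(insertSeq),
                         pos + nchar(insertSeq) + 2)
      stopAfter <- after %in% c("TAA", "TAG", "TGA")
      if (!isTRUE(stopAfter))
        flags <- c(flags, "no stop codon immediately after the insert")
    }
  }
  list(donorLength = n, inFrame = inFrame,
       targetedAmplicon = if (is.na(wtAmplicon)) NA_integer_
                          else expectedAmplicon(wtAmplicon, insertLength),
       armAccountingConsistent = armsOk,
       insertFound = insertFound, stopAfterInsert = stopAfter,
       flags = flags)
}
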