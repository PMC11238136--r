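## Readers/writers for long-format plate tables and the hit table.

LONG_COLUMNS <- c("plate_id", "well", "compound_id", "library", "role",
                  "dose_uM", "channel", "signal")

#' Read a long-format plate table into PlateGrids
#'
#' The table must be delimited text (comma or tab, auto-detected from the
#' header) with columns `plate_id, well, compound_id, library, role, dose_uM,
#' channel, signal`. One [PlateGrid-class] is built per (plate, channel)
#' pair. Empty strings in `compound_id`/`library` and empty/NA `dose_uM` are
#' treated as absent annotation.
#'
#' @param path file path
#' @param format plate format: 96, 384 or "auto" (infer from the largest
#'   well address used on each plate)
#' @return named list of `PlateGrid` objects, names `"<plate_id>:<channel>"`
#' @details Duplicate (plate, well, channel) rows and unknown role tokens
#'   are errors; unparseable well addresses are reported with their line
#'   numbers.
#' @seealso [writeLongTable()]
#' @export
readLongTable <- function(path, format = "auto") {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          quote = "\"", comment.char = "")
  missing <- setdiff(LONG_COLUMNS, names(df))
  if (length(missing))
    stop("long table is missing columns: ", paste(missing, collapse = ", "))
  badRole <- !(df$role %in% WELL_ROLES)
  if (any(badRole))
    stop("unknown role token(s) at line(s) ",
         paste(which(badRole) + 1L, collapse = ", "), ": ",
         paste(unique(df$role[badRole]), collapse = ", "))
  key <- paste(df$plate_id, df$well, df$channel, sep = "|")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (plate, well, channel) entry: ", dup)
  }
  out <- list()
  for (pid in unique(df$plate_id)) {
    for (ch in unique(df$channel[df$plate_id == pid])) {
      sub <- df[df$plate_id == pid & df$channel == ch, , drop = FALSE]
      fmt <- format
      if (identical(format, "auto")) {
        ## parse permissively to find the footprint, then bind the format
        m <- regmatches(sub$well, regexec("^([A-Pa-p])([0-9]{1,2})$", sub$well))
        ok <- vapply(m, length, 1L) == 3L
        if (!all(ok))
          stop("unparseable well address at line(s) ",
               paste(rownames(sub)[!ok], collapse = ", "))
        rows <- match(toupper(vapply(m, `[`, "", 2L)), LETTERS)
        cols <- as.integer(vapply(m, `[`, "", 3L))
        fmt <- if (max(rows) > 8L || max(cols) > 12L) 384 else 96
      }
      dims <- plateDims(fmt)
      pw <- tryCatch(parseWell(sub$well, fmt), error = function(e)
        stop("plate ", pid, " (", ch, "): ", conditionMessage(e),
             call. = FALSE))
      sig <- matrix(NA_real_, dims[1], dims[2])
      role <- matrix("empty", dims[1], dims[2])
      cid <- matrix(NA_character_, dims[1], dims[2])
      lib <- matrix(NA_character_, dims[1], dims[2])
      dose <- matrix(NA_real_, dims[1], dims[2])
      idx <- cbind(pw$row + 1L, pw$column + 1L)
      sig[idx] <- as.numeric(sub$signal)
      role[idx] <- sub$role
      cid[idx] <- as.character(sub$compound_id)
      lib[idx] <- as.character(sub$library)
      dose[idx] <- as.numeric(sub$dose_uM)
      out[[paste0(pid, ":", ch)]] <-
        PlateGrid(pid, fmt, ch, sig, role, cid, lib, dose)
    }
  }
  out
}

#' Write PlateGrids as a long-format table
#'
#' Serializes non-empty wells of each plate to the delimited layout read by
#' [readLongTable()]. Signals are written with 15 significant digits so the
#' round-trip is lossless to at least 12.
#'
#' @param plates a `PlateGrid` or list of them
#' @param path output file path
#' @param sep field separator (default comma)
#' @return `path`, invisibly
#' @export
writeLongTable <- function(plates, path, sep = ",") {
  if (is(plates, "PlateGrid")) plates <- list(plates)
  rows <- lapply(plates, function(p) {
    keep <- which(p@role != "empty", arr.ind = TRUE)
    if (!nrow(keep)) return(NULL)
    data.frame(
      plate_id = p@plateId,
      well = wellName(keep[, 1] - 1L, keep[, 2] - 1L, p@format),
      compound_id = p@compoundId[keep],
      library = p@library[keep],
      role = p@role[keep],
      dose_uM = p@dose[keep],
      channel = p@channel,
      signal = p@signal[keep],
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- as.data.frame(
    stats::setNames(replicate(length(LONG_COLUMNS), character(0),
                              simplify = FALSE), LONG_COLUMNS))
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num))
    df[[j]] <- trimws(formatC(df[[j]], digits = 15, format = "g"))
  df[df == "NA"] <- NA
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

HIT_COLUMNS <- c("compound_id", "library", "dose_uM", "percent_activity",
                 "b_score", "percent_viability", "viability_z", "ratio",
                 "is_luminescence_hit", "passes_counter_screen")

#' Write the counter-screen hit table
#'
#' Writes one row per compound well with the columns of the published hit
#' tables (compound, % activity, B score, % viability, viability z, ratio,
#' flags), sorted by ratio descending with ties broken by B score ascending.
#' Numeric values are written with at least 3 decimal places.
#'
#' @param records data.frame with (at least) the columns listed above
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeHitTable <- function(records, path) {
  missing <- setdiff(HIT_COLUMNS, names(records))
  if (length(missing))
    stop("hit records are missing columns: ", paste(missing, collapse = ", "))
  df <- records[HIT_COLUMNS]
  if (nrow(df)) {
    num <- vapply(df, is.numeric, TRUE)
    if (any(!is.finite(as.matrix(df[num]))))
      stop("hit records must be finite")
    df <- df[order(-df$ratio, df$b_score), , drop = FALSE]
    for (j in which(num)) df[[j]] <- sprintf("%.3f", df[[j]])
  }
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
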