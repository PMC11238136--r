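## Viability counter-screen: the cytotoxicity ratio filter.

#' Viability : activity ratio
#'
#' `ratio = percentViability / max(percentActivity, activityFloor)`. A high
#' ratio marks a compound that suppresses the reporter signal without
#' killing cells -- the desired profile. The activity floor (default 0.1%)
#' prevents division blow-up for compounds that abolish the signal almost
#' completely while keeping their deliberately extreme ratios.
#'
#' @param percentViability,percentActivity numeric vectors, % of control
#' @param activityFloor denominator floor in percent (default 0.1)
#' @return numeric ratio vector
#' @examples
#' viabilityRatio(37.101, 9.296)   # 3.991
#' @export
viabilityRatio <- function(percentViability, percentActivity,
                           activityFloor = 0.1) {
  if (any(percentViability < 0) || any(percentActivity < 0))
    stop("percentages must be non-negative")
  percentViability / pmax(percentActivity, activityFloor)
}

#' Apply the counter-screen ratio cut-off
#'
#' Joins per-well luminescence records with their matched viability records
#' (by compound id and dose), computes the viability:activity ratio, and
#' flags compounds meeting the cut-off (inclusive; the default 2 encodes a
#' 2:1 viability:luminescence requirement). Compounds present in only one
#' channel are reported in `unmatched`, never silently dropped.
#'
#' @param lum data.frame with columns `compound_id`, `dose_uM`,
#'   `percent_activity` and optionally `b_score`, `library`
#' @param via data.frame with columns `compound_id`, `dose_uM`,
#'   `percent_viability` and optionally `viability_z`
#' @param cutoff ratio cut-off (default 2, inclusive)
#' @param activityFloor see [viabilityRatio()]
#' @return list with `results` (merged data.frame with `ratio` and `passes`)
#'   and `unmatched` (data.frame of one-channel compounds with a `channel`
#'   column)
#' @export
selectCounterHits <- function(lum, via, cutoff = 2, activityFloor = 0.1) {
  stopifnot(all(c("compound_id", "dose_uM", "percent_activity") %in%
                  names(lum)),
            all(c("compound_id", "dose_uM", "percent_viability") %in%
                  names(via)))
  keyL <- paste(lum$compound_id, lum$dose_uM)
  keyV <- paste(via$compound_id, via$dose_uM)
  onlyL <- !(keyL %in% keyV)
  onlyV <- !(keyV %in% keyL)
  unmatched <- rbind(
    data.frame(compound_id = lum$compound_id[onlyL],
               dose_uM = lum$dose_uM[onlyL],
               channel = rep("luminescence", sum(onlyL)),
               stringsAsFactors = FALSE),
    data.frame(compound_id = via$compound_id[onlyV],
               dose_uM = via$dose_uM[onlyV],
               channel = rep("viability", sum(onlyV)),
               stringsAsFactors = FALSE))
  merged <- merge(lum[!onlyL, , drop = FALSE], via[!onlyV, , drop = FALSE],
                  by = c("compound_id", "dose_uM"))
  merged$ratio <- viabilityRatio(merged$percent_viability,
                                 merged$percent_activity, activityFloor)
  merged$passes <- merged$ratio >= cutoff
  list(results = merged[order(-merged$ratio), , drop = FALSE],
       unmatched = unmatched)
}

#' Viability z-score against plate negative controls
#'
#' `(percentViability - mean(neg)) / sd(neg)` where `neg` are the
#' negative-control percent-viability values of the matching plate; mirrors
#' the published hit-table "Z score" column.
#'
#' @param percentViability numeric vector
#' @param negPercentViability negative-control percent viability (>= 2)
#' @return numeric z-scores
#' @export
viabilityZ <- function(percentViability, negPercentViability) {
  if (length(negPercentViability) < 2L)
    stop("need at least 2 negative-control viability values")
  s <- stats::sd(negPercentViability)
  if (s == 0) stop("negative-control viability SD is 0")
  (percentViability - mean(negPercentViability)) / s
}
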