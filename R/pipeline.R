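## Cascade orchestration: configuration, staged outputs, logging.

CONFIG_FIELDS <- c("hitK", "zFactorMin", "ratioCutoff", "comboReductionPct",
                   "synergyThreshold", "msaWindow", "logScale", "maxIter",
                   "tol", "activityFloor", "seed")

#' Cascade configuration
#'
#' Thresholds and numerical options for the full screening cascade. The
#' defaults are the published operating points: a 0.7 Z-factor
#' screenability gate, hits at 3 negative-control SDs of B-score, a 2:1
#' viability:luminescence counter-screen ratio, a 10-percentage-point
#' combination viability-reduction rule, and a ZIP synergy threshold of 5
#' with a 3x3 most-synergistic-area window.
#'
#' @param hitK B-score hit threshold, in negative-control SDs
#' @param zFactorMin plate screenability gate
#' @param ratioCutoff counter-screen viability:activity cut-off (inclusive)
#' @param comboReductionPct per-dose combination viability-reduction rule, %
#' @param synergyThreshold ZIP classification bound (inclusive)
#' @param msaWindow most-synergistic-area window edge
#' @param logScale run median polish on log10 signal
#' @param maxIter,tol median polish controls
#' @param activityFloor ratio denominator floor, %
#' @param seed integer seed for the simulated stages
#' @return classed list (`CascadeConfig`)
#' @export
cascadeConfig <- function(hitK = 3, zFactorMin = 0.7, ratioCutoff = 2,
                          comboReductionPct = 10, synergyThreshold = 5,
                          msaWindow = 3L, logScale = TRUE, maxIter = 20L,
                          tol = 1e-6, activityFloor = 0.1, seed = 1L) {
  stopifnot(hitK > 0, zFactorMin > 0, ratioCutoff > 0,
            comboReductionPct > 0, synergyThreshold > 0, msaWindow >= 2,
            maxIter >= 1, tol > 0, activityFloor > 0)
  structure(mget(CONFIG_FIELDS), class = "CascadeConfig")
}

#' Save / load a cascade configuration (YAML)
#'
#' @param config a [cascadeConfig()]
#' @param path YAML file path
#' @return `saveConfig`: `path` invisibly; `loadConfig`: a `CascadeConfig`
#' @export
saveConfig <- function(config, path) {
  stopifnot(inherits(config, "CascadeConfig"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname saveConfig
#' @export
loadConfig <- function(path) {
  x <- yaml::read_yaml(path)
  missing <- setdiff(CONFIG_FIELDS, names(x))
  if (length(missing))
    stop("config is missing fields: ", paste(missing, collapse = ", "))
  do.call(cascadeConfig, x[CONFIG_FIELDS])
}

#' Combination sub-screen setup for the simulated cascade
#'
#' Defines how combination matrices are generated for compounds surviving
#' the counter-screen: the candidate and anchor (PARP inhibitor) monotherapy
#' curves, their dose grids, the anchor dose column used for the delta-AUC
#' sub-screen (a low, roughly EC10-range anchor dose), the fraction of
#' surviving true hits designed to be synergistic, and the injected delta.
#'
#' @param candidateCurve,anchorCurve [DoseResponseCurve-class] monotherapy
#'   curves (candidate runs down the rows)
#' @param candidateDoses,anchorDoses dose grids in uM, starting at 0
#' @param anchorIdx column index of the anchor dose used for the
#'   combination sub-screen (2 = lowest positive anchor dose)
#' @param synergyFraction fraction of non-toxic true hits given synergy
#' @param synergyDelta injected delta for synergistic compounds (ZIP scale)
#' @param nReplicates,replicateCv replicate structure of each surface
#' @return classed list (`ComboSetup`)
#' @export
comboSetup <- function(candidateCurve = doseResponseCurve(40, 100, 0.25, 1),
                       anchorCurve = doseResponseCurve(30, 100, 5, 1.5),
                       candidateDoses = c(0, 0.03125, 0.0625, 0.125, 0.25,
                                          0.5, 1),
                       anchorDoses = c(0, 0.3125, 0.625, 1.25, 2.5, 5, 10),
                       anchorIdx = 2L, synergyFraction = 0.5,
                       synergyDelta = 15, nReplicates = 3L,
                       replicateCv = 0.02) {
  stopifnot(anchorIdx >= 2, anchorIdx <= length(anchorDoses),
            synergyFraction >= 0, synergyFraction <= 1, synergyDelta >= 0)
  structure(as.list(environment()), class = "ComboSetup")
}

cascadeLog <- function(...) message("[cascade] ", ...)

#' Run the full screening cascade on a simulated screen
#'
#' Reproduces the published screening flow end to end with known ground
#' truth: (01) simulate the primary luminescence screen and gate plates on
#' the Z-factor; (02) B-score normalization and hit calling against
#' negative controls; (03) the viability counter-screen ratio filter;
#' (04) the anchored combination sub-screen with the per-dose
#' viability-reduction rule and delta-AUC; (05) ZIP synergy scoring and
#' threshold classification. Stage outputs are written under `outDir`
#' (subdirectories `01_qc` .. `05_synergy` plus `summary.json`), and each
#' stage's compound set is a subset of the previous stage's.
#'
#' @param spec a [syntheticScreenSpec()]
#' @param config a [cascadeConfig()]
#' @param combo a [comboSetup()]
#' @param outDir output directory (created if needed); NULL = no files
#' @return (invisibly) list with `summary` (stage counts and compound ids),
#'   `truth` (ground truth incl. designed synergy flags), `records`
#'   (per-well scored table), `counter` (stage-03 table), `comboCalls`
#'   (stage-04 table), `synergy` (stage-05 table), `qc` (per-plate QC)
#' @export
runFullCascade <- function(spec, config = cascadeConfig(),
                           combo = comboSetup(), outDir = NULL) {
  stopifnot(inherits(spec, "SyntheticScreenSpec"),
            inherits(config, "CascadeConfig"),
            inherits(combo, "ComboSetup"))
  if (!is.null(outDir)) {
    for (d in c("01_qc", "02_hits", "03_counter", "04_combo", "05_synergy"))
      dir.create(file.path(outDir, d), recursive = TRUE,
                 showWarnings = FALSE)
  }
  sim <- simulatePrimaryScreen(spec)
  viaPlates <- simulateViabilityScreen(spec, sim$truth)
  truth <- sim$truth
  truth$compounds$is_synergistic <- withSeed(spec$seed + 3L, {
    eligible <- truth$compounds$is_true_hit & !truth$compounds$is_toxic
    flag <- rep(FALSE, nrow(truth$compounds))
    flag[eligible] <- stats::runif(sum(eligible)) < combo$synergyFraction
    flag
  })

  ## -- stage 01: per-plate QC and Z-factor gate (luminescence channel)
  qc <- data.frame(plate_id = character(), z_factor = numeric(),
                   mad_scale = numeric(), screenable = logical(),
                   stringsAsFactors = FALSE)
  records <- NULL
  for (p in sim$plates) {
    np <- normalizePlate(p, logScale = config$logScale,
                         maxIter = config$maxIter, tol = config$tol)
    zf <- if (is.null(np$zFactor)) NA_real_ else np$zFactor$value
    ok <- !is.na(zf) && zf >= config$zFactorMin
    qc <- rbind(qc, data.frame(plate_id = plateId(p), z_factor = zf,
                               mad_scale = np$madScale, screenable = ok))
    if (!ok) {
      cascadeLog("plate ", plateId(p), " fails the Z-factor gate (",
                 sprintf("%.3f", zf), " < ", config$zFactorMin,
                 "); excluded")
      next
    }
    smp <- sampleMask(p)
    negB <- np$bScore[wellRoles(p) == "negative_control"]
    hit <- callHits(np$bScore, negB, k = config$hitK, direction = "down")
    idx <- which(smp, arr.ind = TRUE)
    records <- rbind(records, data.frame(
      plate_id = plateId(p),
      well = wellName(idx[, 1] - 1L, idx[, 2] - 1L, plateFormat(p)),
      compound_id = compoundIds(p)[smp],
      library = p@library[smp],
      dose_uM = wellDoses(p)[smp],
      percent_activity = np$percentActivity[smp],
      b_score = np$bScore[smp],
      is_luminescence_hit = hit[smp],
      stringsAsFactors = FALSE))
  }
  stage1 <- unique(records$compound_id)
  hits <- records[records$is_luminescence_hit, , drop = FALSE]
  stage2 <- unique(hits$compound_id)
  cascadeLog("stage 02: ", length(stage2), " luminescence hits of ",
             length(stage1), " screened compounds")

  ## -- stage 03: viability counter-screen on the hits
  viaRecords <- NULL
  for (p in viaPlates) {
    pv <- percentActivity(p)   # viability channel: % of control viability
    negPv <- pv[wellRoles(p) == "negative_control"]
    smp <- sampleMask(p)
    viaRecords <- rbind(viaRecords, data.frame(
      compound_id = compoundIds(p)[smp],
      dose_uM = wellDoses(p)[smp],
      percent_viability = pv[smp],
      viability_z = viabilityZ(pv[smp], negPv[is.finite(negPv)]),
      stringsAsFactors = FALSE))
  }
  cs <- selectCounterHits(hits, viaRecords, cutoff = config$ratioCutoff,
                          activityFloor = config$activityFloor)
  counter <- cs$results
  stage3 <- unique(counter$compound_id[counter$passes])
  cascadeLog("stage 03: ", length(stage3), " of ", length(stage2),
             " hits pass the ", config$ratioCutoff, ":1 ratio cut-off")

  ## -- stage 04/05: anchored combination sub-screen, then ZIP synergy
  comboCalls <- NULL
  synergyRows <- NULL
  stage3sorted <- sort(stage3)
  matrices <- list()
  for (k in seq_along(stage3sorted)) {
    cid <- stage3sorted[k]
    d <- combo$synergyDelta *
      truth$compounds$is_synergistic[match(cid, truth$compounds$compound_id)]
    sf <- surfaceSpec(combo$candidateCurve, combo$anchorCurve,
                      doses1 = combo$candidateDoses,
                      doses2 = combo$anchorDoses, delta = d,
                      replicateCv = combo$replicateCv,
                      nReplicates = combo$nReplicates,
                      seed = spec$seed + 1000L + k)
    sm <- simulateCombinationMatrix(sf, drug1Id = cid, drug2Id = "anchor")
    matrices[[cid]] <- sm$matrix
    v <- sm$matrix@viability
    doses <- combo$candidateDoses[-1]
    call <- deltaAUC(doses, v[-1, 1], v[-1, combo$anchorIdx],
                     reductionPct = config$comboReductionPct)
    comboCalls <- rbind(comboCalls, data.frame(
      compound_id = cid, delta_auc = call$deltaAUC,
      max_deficit = call$maxDeficit, combines = call$combines,
      stringsAsFactors = FALSE))
  }
  stage4 <- comboCalls$compound_id[comboCalls$combines]
  cascadeLog("stage 04: ", length(stage4), " of ", length(stage3),
             " compounds combine with the anchor (>",
             config$comboReductionPct, "% viability reduction)")
  for (cid in stage4) {
    rep <- zipSynergy(matrices[[cid]], threshold = config$synergyThreshold,
                      window = config$msaWindow)
    synergyRows <- rbind(synergyRows, data.frame(
      compound_id = cid, synergy_score = rep@overallScore,
      msa_score = rep@msaScore, method = "ZIP",
      synergistic = rep@synergistic, stringsAsFactors = FALSE))
  }
  stage5 <- if (is.null(synergyRows)) character(0)
            else synergyRows$compound_id[synergyRows$synergistic]
  cascadeLog("stage 05: ", length(stage5), " of ", length(stage4),
             " synergistic at threshold ", config$synergyThreshold)

  summary <- list(
    n_compounds = length(stage1),
    counts = list(screened = length(stage1),
                  luminescence_hits = length(stage2),
                  counter_screen_pass = length(stage3),
                  combination_pass = length(stage4),
                  synergistic = length(stage5)),
    compounds = list(luminescence_hits = sort(stage2),
                     counter_screen_pass = sort(stage3),
                     combination_pass = sort(stage4),
                     synergistic = sort(stage5)),
    excluded_plates = qc$plate_id[!qc$screenable]
  )
  if (!is.null(outDir)) {
    utils::write.csv(qc, file.path(outDir, "01_qc", "plate_qc.csv"),
                     row.names = FALSE)
    utils::write.csv(hits, file.path(outDir, "02_hits", "hit_wells.csv"),
                     row.names = FALSE)
    ctab <- counter
    ctab$is_luminescence_hit <- TRUE
    ctab$passes_counter_screen <- ctab$passes
    writeHitTable(ctab, file.path(outDir, "03_counter",
                                  "counter_screen.csv"))
    if (!is.null(comboCalls))
      utils::write.csv(comboCalls, file.path(outDir, "04_combo",
                                             "combination_calls.csv"),
                       row.names = FALSE)
    if (!is.null(synergyRows))
      utils::write.csv(synergyRows, file.path(outDir, "05_synergy",
                                              "synergy_scores.csv"),
                       row.names = FALSE)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(summary = summary, truth = truth, records = records,
                 counter = counter, comboCalls = comboCalls,
                 synergy = synergyRows, qc = qc, matrices = matrices))
}

#' Demonstration screen specification for the cascade
#'
#' A compact seeded screen used by the worked examples: 2 x 384-well
#' plates (~640 compounds), 4% spiked hits, 8% cytotoxic compounds, default
#' noise. With [comboSetup()] defaults, half the non-toxic hits are
#' designed synergistic.
#'
#' @param seed integer seed
#' @return a [syntheticScreenSpec()]
#' @export
demoScreenSpec <- function(seed = 1L) {
  syntheticScreenSpec(nPlates = 2, hitFraction = 0.04, toxicFraction = 0.08,
                      seed = seed)
}
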