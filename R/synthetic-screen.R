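## Synthetic screen generator: plates with known ground truth, and
## dose-combination surfaces with a known injected synergy landscape.

withSeed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}

## multiplicative noise with mean exactly 1; cv = 0 gives exactly 1
lognormNoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Specification of a synthetic primary screen
#'
#' Bundles the plate layout and the generative model for a simulated
#' reporter screen: per-plate/row/column multiplicative positional effects
#' (log10-normal with the given SDs), multiplicative well noise with
#' coefficient of variation `noiseCv`, a spiked fraction of true
#' downregulator hits with known percent activity, a fraction of cytotoxic
#' compounds with known percent viability, and control columns (negative
#' vehicle controls, a positive control that raises the reporter signal, and
#' lytic-background wells).
#'
#' The defaults describe the simulated study conditions: 384-well plates
#' screened at 4 uM with ~4% control coefficient of variation (so control
#' separation clears the 0.7 Z-factor gate), 2% spiked hits with true
#' activity 5--40% of control, and 5% cytotoxic compounds at 10--40% true
#' viability.
#'
#' @param nPlates number of plates
#' @param format 96 or 384
#' @param baselineSignal negative-control expected signal (arbitrary units)
#' @param rowEffectSd,colEffectSd,plateEffectSd SDs of positional effects on
#'   the log10 scale
#' @param noiseCv well-level multiplicative noise CV
#' @param hitFraction fraction of compounds spiked as true hits
#' @param hitActivityRange true percent-activity interval for hits
#' @param toxicFraction fraction of compounds spiked as cytotoxic
#' @param toxicityRange true percent-viability interval for toxic compounds
#' @param positiveControlActivity positive-control signal, percent of
#'   negative control (>100: reporter accumulation)
#' @param backgroundFraction background-well signal as a fraction of baseline
#' @param dose screening dose in uM applied to every sample well
#' @param seed integer RNG seed; identical spec + seed give identical output
#' @return a classed list (`SyntheticScreenSpec`)
#' @seealso [simulatePrimaryScreen()], [simulateViabilityScreen()]
#' @export
syntheticScreenSpec <- function(nPlates = 10, format = 384,
                                baselineSignal = 1e6,
                                rowEffectSd = 0.008, colEffectSd = 0.008,
                                plateEffectSd = 0.05, noiseCv = 0.025,
                                hitFraction = 0.02,
                                hitActivityRange = c(5, 40),
                                toxicFraction = 0.05,
                                toxicityRange = c(10, 40),
                                positiveControlActivity = 400,
                                backgroundFraction = 0.01,
                                dose = 4, seed = 1L) {
  stopifnot(nPlates >= 1, format %in% c(96, 384), baselineSignal > 0,
            rowEffectSd >= 0, colEffectSd >= 0, plateEffectSd >= 0,
            noiseCv >= 0, hitFraction >= 0, hitFraction <= 1,
            toxicFraction >= 0, toxicFraction <= 1,
            length(hitActivityRange) == 2,
            hitActivityRange[1] <= hitActivityRange[2],
            hitActivityRange[1] > 0, hitActivityRange[2] < 100,
            length(toxicityRange) == 2,
            toxicityRange[1] <= toxicityRange[2],
            toxicityRange[1] > 0, toxicityRange[2] < 100,
            dose > 0)
  structure(as.list(environment()), class = "SyntheticScreenSpec")
}

## Default control layout: on 384 plates columns 1-2 negative, 23 positive,
## 24 background; on 96 plates column 1 negative, 11 positive, 12 background.
controlLayout <- function(format) {
  dims <- plateDims(format)
  role <- matrix("sample", dims[1], dims[2])
  if (format == 384) {
    role[, 1:2] <- "negative_control"
    role[, 23] <- "positive_control"
    role[, 24] <- "background"
  } else {
    role[, 1] <- "negative_control"
    role[, 11] <- "positive_control"
    role[, 12] <- "background"
  }
  role
}

buildChannelPlates <- function(spec, truth, channel, wellEffectPct,
                               positiveControlPct, seedOffset) {
  dims <- plateDims(spec$format)
  role <- controlLayout(spec$format)
  smpIdx <- which(role == "sample")
  plates <- vector("list", spec$nPlates)
  effects <- vector("list", spec$nPlates)
  withSeed(spec$seed + seedOffset, {
    for (p in seq_len(spec$nPlates)) {
      pid <- sprintf("SIM%02d", p)
      plateMult <- 10^stats::rnorm(1, 0, spec$plateEffectSd)
      rowMult <- 10^stats::rnorm(dims[1], 0, spec$rowEffectSd)
      colMult <- 10^stats::rnorm(dims[2], 0, spec$colEffectSd)
      pos <- outer(rowMult, colMult) * plateMult
      eff <- matrix(1, dims[1], dims[2])
      onPlate <- truth$compounds$plate_id == pid
      pw <- parseWell(truth$compounds$well[onPlate], spec$format)
      eff[cbind(pw$row + 1L, pw$column + 1L)] <-
        wellEffectPct[onPlate] / 100
      eff[role == "positive_control"] <- positiveControlPct / 100
      eff[role == "background"] <- spec$backgroundFraction
      sig <- spec$baselineSignal * pos * eff *
        matrix(lognormNoise(prod(dims), spec$noiseCv), dims[1], dims[2])
      cid <- matrix(NA_character_, dims[1], dims[2])
      lib <- matrix(NA_character_, dims[1], dims[2])
      dosem <- matrix(NA_real_, dims[1], dims[2])
      cid[cbind(pw$row + 1L, pw$column + 1L)] <-
        truth$compounds$compound_id[onPlate]
      lib[cbind(pw$row + 1L, pw$column + 1L)] <-
        truth$compounds$library[onPlate]
      dosem[cbind(pw$row + 1L, pw$column + 1L)] <-
        truth$compounds$dose_uM[onPlate]
      plates[[p]] <- PlateGrid(pid, spec$format, channel, sig, role,
                               cid, lib, dosem)
      effects[[p]] <- list(plate_id = pid, plateMult = plateMult,
                           rowMult = rowMult, colMult = colMult)
    }
  })
  list(plates = stats::setNames(plates, vapply(plates, plateId, "")),
       effects = effects)
}

#' Simulate the primary luminescence screen
#'
#' Generates one compound per sample well across `nPlates` plates. Each
#' well's signal is `baseline x plateMult x rowMult x colMult x effect x
#' noise`, where `effect` is the compound's true percent activity / 100
#' (100% for non-hits), and noise is mean-1 lognormal with CV `noiseCv`.
#' Hit and cytotoxicity flags are drawn here so the luminescence and
#' viability channels share one ground truth.
#'
#' @param spec a [syntheticScreenSpec()]
#' @return list with `plates` (named list of luminescence
#'   [PlateGrid-class]s) and `truth` (list: `compounds` data.frame with
#'   per-compound true activity/viability and flags; `plateEffects` with the
#'   injected positional multipliers)
#' @export
simulatePrimaryScreen <- function(spec) {
  stopifnot(inherits(spec, "SyntheticScreenSpec"))
  dims <- plateDims(spec$format)
  role <- controlLayout(spec$format)
  smpIdx <- which(role == "sample", arr.ind = TRUE)
  nSmp <- nrow(smpIdx)
  if (nSmp == 0L && spec$hitFraction > 0)
    stop("hitFraction > 0 but the layout has no sample wells")
  n <- nSmp * spec$nPlates
  truth <- withSeed(spec$seed, {
    compounds <- data.frame(
      compound_id = sprintf("CPD-%05d", seq_len(n)),
      library = "SIMLIB",
      plate_id = rep(sprintf("SIM%02d", seq_len(spec$nPlates)), each = nSmp),
      well = rep(wellName(smpIdx[, 1] - 1L, smpIdx[, 2] - 1L, spec$format),
                 spec$nPlates),
      dose_uM = spec$dose,
      stringsAsFactors = FALSE
    )
    isHit <- stats::runif(n) < spec$hitFraction
    trueActivity <- rep(100, n)
    trueActivity[isHit] <- stats::runif(sum(isHit), spec$hitActivityRange[1],
                                        spec$hitActivityRange[2])
    isToxic <- stats::runif(n) < spec$toxicFraction
    trueViability <- rep(100, n)
    trueViability[isToxic] <- stats::runif(sum(isToxic),
                                           spec$toxicityRange[1],
                                           spec$toxicityRange[2])
    compounds$true_activity <- trueActivity
    compounds$true_viability <- trueViability
    compounds$is_true_hit <- isHit
    compounds$is_toxic <- isToxic
    list(compounds = compounds)
  })
  built <- buildChannelPlates(spec, truth, "luminescence",
                              truth$compounds$true_activity,
                              spec$positiveControlActivity, seedOffset = 1L)
  truth$plateEffects <- built$effects
  list(plates = built$plates, truth = truth)
}

#' Simulate the matched viability counter-screen
#'
#' Builds viability-channel plates for the same compounds and layout as the
#' primary screen: cytotoxic compounds read out at their true percent
#' viability, all others at 100% of control; the same multiplicative
#' positional-effect and noise model applies (fresh positional draws -- the
#' viability assay is an independent read).
#'
#' @param spec the [syntheticScreenSpec()] used for the primary screen
#' @param truth the `truth` component returned by [simulatePrimaryScreen()]
#' @return named list of viability [PlateGrid-class]s
#' @export
simulateViabilityScreen <- function(spec, truth) {
  stopifnot(inherits(spec, "SyntheticScreenSpec"))
  if (is.null(truth$compounds) ||
      nrow(truth$compounds) !=
        sum(controlLayout(spec$format) == "sample") * spec$nPlates)
    stop("truth does not match the compound set implied by spec")
  built <- buildChannelPlates(spec, truth, "viability",
                              truth$compounds$true_viability,
                              positiveControlPct = 100, seedOffset = 2L)
  built$plates
}

#' Specification of a synthetic dose-combination surface
#'
#' Two monotherapy four-parameter logistic curves, their dose grids
#' (ascending, starting at 0), an injected synergy landscape `delta` on the
#' 0--100 percent-inhibition scale (0 = exact ZIP/Bliss independence), and a
#' replicate noise CV.
#'
#' @param curve1,curve2 [DoseResponseCurve-class] objects (viability
#'   orientation, eMax at dose 0) for drug 1 (rows) and drug 2 (columns)
#' @param doses1,doses2 ascending dose vectors in uM, first element 0
#' @param delta injected synergy: a single number applied to every
#'   both-doses-positive cell, or a full grid-sized matrix (axis entries
#'   ignored)
#' @param replicateCv replicate-level multiplicative noise CV on viability
#' @param nReplicates number of replicate surfaces (averaged in the output)
#' @param seed integer RNG seed
#' @return a classed list (`SurfaceSpec`)
#' @seealso [simulateCombinationMatrix()]
#' @export
surfaceSpec <- function(curve1, curve2,
                        doses1 = c(0, 0.3125, 0.625, 1.25, 2.5, 5, 10),
                        doses2 = c(0, 0.3125, 0.625, 1.25, 2.5, 5, 10),
                        delta = 0, replicateCv = 0, nReplicates = 1L,
                        seed = 1L) {
  stopifnot(is(curve1, "DoseResponseCurve"), is(curve2, "DoseResponseCurve"),
            doses1[1] == 0, all(diff(doses1) > 0),
            doses2[1] == 0, all(diff(doses2) > 0),
            replicateCv >= 0, nReplicates >= 1)
  if (length(delta) == 1L)
    delta <- matrix(delta, length(doses1), length(doses2))
  if (!identical(dim(delta), c(length(doses1), length(doses2))))
    stop("delta must be scalar or match the dose-grid dimensions")
  structure(list(curve1 = curve1, curve2 = curve2, doses1 = doses1,
                 doses2 = doses2, delta = delta, replicateCv = replicateCv,
                 nReplicates = as.integer(nReplicates), seed = seed),
            class = "SurfaceSpec")
}

#' Simulate a dose-combination response surface
#'
#' Noise-free cell inhibition for both-doses-positive cells is
#' `100 * (y1 + y2 - y1*y2) + delta[i,j]`, clamped to [0, 100], where `y1`,
#' `y2` are the fractional monotherapy inhibitions from the two curves;
#' monotherapy axes follow the curves exactly. Responses are stored as
#' percent viability (`100 - inhibition`) with multiplicative replicate
#' noise. Cells whose pre-clamp inhibition falls outside [-20, 120] trigger
#' a warning.
#'
#' @param surface a [surfaceSpec()]
#' @param drug1Id,drug2Id identifiers stored on the output
#' @return list with `matrix` (a [CombinationMatrix-class]) and
#'   `truthDelta` (the injected landscape, NA on the axes)
#' @export
simulateCombinationMatrix <- function(surface, drug1Id = "drug1",
                                      drug2Id = "drug2") {
  stopifnot(inherits(surface, "SurfaceSpec"))
  d1 <- surface$doses1; d2 <- surface$doses2
  y1 <- 1 - predictResponse(surface$curve1, d1) / 100
  y2 <- 1 - predictResponse(surface$curve2, d2) / 100
  inh <- 100 * outer(y1, y2, function(a, b) a + b - a * b)
  interior <- outer(d1 > 0, d2 > 0, `&`)
  inh[interior] <- inh[interior] + surface$delta[interior]
  if (any(inh[interior] < -20 | inh[interior] > 120))
    warning("injected delta pushes inhibition outside [-20, 120] pre-clamp")
  inh <- pmin(pmax(inh, 0), 100)
  via <- 100 - inh
  reps <- withSeed(surface$seed, {
    lapply(seq_len(surface$nReplicates), function(r)
      via * matrix(lognormNoise(length(via), surface$replicateCv),
                   nrow(via), ncol(via)))
  })
  mean_ <- Reduce(`+`, reps) / length(reps)
  truthDelta <- surface$delta
  truthDelta[!interior] <- NA_real_
  m <- combinationMatrix(drug1Id, drug2Id, d1, d2, mean_,
                         replicates = if (surface$nReplicates > 1L) reps
                                      else list())
  list(matrix = m, truthDelta = truthDelta)
}
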