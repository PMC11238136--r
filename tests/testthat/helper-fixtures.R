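# Small in-code fixtures shared across test files.

# A 96-well plate with uniform sample signal, negative/positive controls in
# the layout used by the simulator, and optional per-well overrides.
makeFlatPlate <- function(signalValue = 1000, negValue = 1000,
                          posValue = 4000, channel = "luminescence",
                          plateId = "T1") {
  role <- screenCascade:::controlLayout(96)
  sig <- matrix(signalValue, 8, 12)
  sig[role == "negative_control"] <- negValue
  sig[role == "positive_control"] <- posValue
  sig[role == "background"] <- 10
  cid <- matrix(NA_character_, 8, 12)
  dose <- matrix(NA_real_, 8, 12)
  smp <- role == "sample"
  cid[smp] <- sprintf("C%03d", seq_len(sum(smp)))
  dose[smp] <- 4
  PlateGrid(plateId, 96, channel, sig, role, cid, dose = dose)
}

# Default curves used by the synergy generator tests: enough inhibition for
# clear dose response but headroom below 100% so injected delta up to 20
# survives the viability clamp.
headroomCurves <- function() {
  list(c1 = doseResponseCurve(40, 100, 1, 1),
       c2 = doseResponseCurve(50, 100, 0.5, 1.5))
}

olaparibGrid <- c(0, 0.3125, 0.625, 1.25, 2.5, 5, 10)
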