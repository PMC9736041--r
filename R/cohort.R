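#' Baseline generative parameters of the study structures
#'
#' One row per structure. \code{family} selects the curve family:
#' \code{"target"} (sigmoid CTV coverage centred on the prescription),
#' \code{"logistic"} (cumulative OAR falloff \code{1/(1 + exp(g (D - D50)))}
#' truncated to the prescription range, with a point mass at zero dose for
#' the unexposed remainder), or \code{"mixture"} (a logistic low-dose
#' component plus a small high-dose component near the target, emulating
#' large structures like whole brain and skin whose median dose can fall
#' below 1 Gy while their near-maximum dose stays at prescription level).
#' \code{d50} is the proton-baseline median dose in Gy (median across
#' patients), \code{sdlog} the inter-patient log-normal spread, \code{gradient}
#' the falloff steepness in 1/Gy, \code{volume} the median structure volume in
#' cm^3 with log-spread \code{volumeSdlog}. Mixture rows add the high-dose
#' component weight, centre and gradient and the exponent coupling the
#' component weight to the modality factor. Ipsi- and contralateral organs
#' are distinct structures with the contralateral baseline lower.
#'
#' @return data.frame of per-structure generator parameters.
#' @export
defaultStructureTable <- function() {
  data.frame(
    structure = c("ctv", "hippocampus_ipsi", "hippocampus_contra",
                  "inner_ear_ipsi", "inner_ear_contra", "pituitary",
                  "brainstem", "brain", "skin"),
    family = c("target", "logistic", "logistic", "logistic", "logistic",
               "logistic", "logistic", "mixture", "mixture"),
    d50 = c(NA, 20, 15, 29, 17, 12, 44, 0.5, 0.35),
    sdlog = c(NA, 0.5, 0.5, 0.45, 0.45, 0.9, 0.25, 0.5, 0.4),
    gradient = c(NA, 0.29, 0.42, 0.38, 0.57, 1.15, 0.45, 2.5, 2.5),
    volume = c(60, 1.33, 1.33, 1.1, 1.1, 0.16, 18.9, 1295, 500),
    volumeSdlog = c(0.3, 0.2, 0.2, 0.2, 0.2, 0.2, 0.15, 0.1, 0.15),
    mixWeight = c(NA, NA, NA, NA, NA, NA, NA, 0.12, 0.03),
    mixCenter = c(NA, NA, NA, NA, NA, NA, NA, 52, 40),
    mixGradient = c(NA, NA, NA, NA, NA, NA, NA, 1.5, 0.3),
    mixExponent = c(NA, NA, NA, NA, NA, NA, NA, 0.25, 0.25),
    stringsAsFactors = FALSE)
}

#' Construct a ModalityProfile
#'
#' @param modality \code{"photon"}, \code{"proton"} or \code{"helium"}.
#' @param ctvSpread logistic scale (Gy) of the CTV falloff.
#' @param oarD50Factor named numeric, multiplier on each OAR baseline median
#'   dose.
#' @param oarGradient multiplier on each OAR falloff steepness.
#' @return A validated [ModalityProfile-class].
#' @export
modalityProfile <- function(modality, ctvSpread, oarD50Factor, oarGradient) {
  new("ModalityProfile", modality = modality, ctvSpread = ctvSpread,
      oarD50Factor = oarD50Factor, oarGradient = oarGradient)
}

#' Default modality profiles emulating the study conditions
#'
#' The proton profile is the baseline (all D50 factors 1). The helium
#' profile has D50 factors below 1 for every OAR and a steeper falloff; the
#' photon profile has factors above 1 and a shallower falloff, so that OAR
#' doses order helium < proton < photon and CTV coverage sharpness orders
#' helium > proton > photon. Factor magnitudes are softly calibrated to the
#' relative inter-modality differences reported for this treatment site
#' (e.g. pituitary median dose about 9/12/15 Gy for He/H+/photons).
#'
#' @return Named list of three [ModalityProfile-class] objects.
#' @export
defaultModalityProfiles <- function() {
  oars <- c("hippocampus_ipsi", "hippocampus_contra", "inner_ear_ipsi",
            "inner_ear_contra", "pituitary", "brainstem", "brain", "skin")
  he <- c(0.75, 0.73, 0.79, 0.65, 0.75, 0.95, 0.28, 0.70)
  ph <- c(1.05, 1.20, 1.17, 1.18, 1.25, 1.05, 3.80, 1.40)
  list(
    photon = modalityProfile("photon", ctvSpread = 0.51,
                             oarD50Factor = stats::setNames(ph, oars),
                             oarGradient = 0.8),
    proton = modalityProfile("proton", ctvSpread = 0.44,
                             oarD50Factor = stats::setNames(rep(1, 8), oars),
                             oarGradient = 1.0),
    helium = modalityProfile("helium", ctvSpread = 0.30,
                             oarD50Factor = stats::setNames(he, oars),
                             oarGradient = 1.25))
}

#' Construct a CohortConfig
#'
#' Defaults reproduce the study conditions: 15 patients, three modalities,
#' 54 Gy in 30 fractions of 1.8 Gy, 0.1 Gy dose grid, the default structure
#' table and modality profiles.
#'
#' @param nPatients number of patients.
#' @param seed integer seed; all generator randomness derives from it.
#' @param prescriptionDose,nFractions,dosePerFraction fraction schedule.
#' @param binWidth dose grid resolution in Gy.
#' @param maxDose upper end of the dose grid in Gy.
#' @param effectSdlog log-scale spread of the patient-specific exponent on
#'   each modality log-factor (0 = exact constant multipliers).
#' @param structureTable see [defaultStructureTable()].
#' @param profiles see [defaultModalityProfiles()].
#' @return A validated [CohortConfig-class].
#' @examples
#' cohortConfig(seed = 1)
#' @export
cohortConfig <- function(nPatients = 15, seed = 1, prescriptionDose = 54,
                         nFractions = 30,
                         dosePerFraction = prescriptionDose / nFractions,
                         binWidth = 0.1, maxDose = 60, effectSdlog = 0.1,
                         structureTable = defaultStructureTable(),
                         profiles = defaultModalityProfiles()) {
  new("CohortConfig", nPatients = nPatients, seed = seed,
      prescriptionDose = prescriptionDose, nFractions = nFractions,
      dosePerFraction = dosePerFraction, binWidth = binWidth,
      maxDose = maxDose, effectSdlog = effectSdlog,
      structureTable = structureTable, profiles = profiles)
}

# Deterministic substream seed per (patient, structure): adding or removing a
# structure never perturbs another structure's draws, and patients are
# independent streams derived from the single global seed.
.substreamSeed <- function(seed, pidx, structure) {
  shash <- sum(utf8ToInt(structure) * seq_along(utf8ToInt(structure))) %% 100003
  as.integer((abs(seed) %% 2147483647) * 7919 + pidx * 104729 + shash * 31) %%
    2147483647L
}

# Per-(patient, structure) random effects, drawn in a fixed order from the
# substream. Shared across modalities (paired design).
.structureDraws <- function(config, pidx, structure, sdlog, volumeSdlog) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(.substreamSeed(config@seed, pidx, structure))
  list(
    effect = exp(stats::rnorm(1L) * ifelse(is.na(sdlog), 0, sdlog)),
    volume = exp(stats::rnorm(1L) * volumeSdlog),
    eta = exp(stats::rnorm(1L) * config@effectSdlog -
                config@effectSdlog^2 / 2),
    gradJitter = exp(stats::rnorm(1L) * 0.1),
    centerJitter = stats::rnorm(1L) * 0.05,
    spreadJitter = exp(stats::rnorm(1L) * 0.15))
}

# Modality factor with patient-specific exponent: f = exp(log(F) * eta).
# A profile factor of 1 is invariant (null effect stays exactly null) and
# with effectSdlog = 0 the factor is the exact profile constant.
.modalityFactor <- function(F, eta) exp(log(F) * eta)

.ctvCurve <- function(config, draws, profile, edges) {
  Dp <- config@prescriptionDose
  center <- Dp + draws$centerJitter
  s <- profile@ctvSpread * draws$spreadJitter
  # hard cap guaranteeing the coverage constraint V(0.95 Dp) >= 0.95
  sMax <- 0.98 * (center - 0.95 * Dp) / stats::qlogis(0.95)
  s <- min(s, sMax)
  v <- stats::plogis((center - edges) / s)
  v[v < 1e-7] <- 0
  v[1L] <- 1
  v[length(v)] <- 0  # the grid covers all deliverable dose; close the curve
  v
}

.oarCurve <- function(config, row, draws, profile, edges) {
  f <- .modalityFactor(profile@oarD50Factor[[row$structure]], draws$eta)
  d50 <- row$d50 * draws$effect * f
  g <- row$gradient * profile@oarGradient * draws$gradJitter
  if (identical(row$family, "mixture")) {
    w <- min(0.8, row$mixWeight * f^row$mixExponent)
    gHi <- row$mixGradient * profile@oarGradient * draws$gradJitter
    v <- w * stats::plogis(-gHi * (edges - row$mixCenter)) +
      (1 - w) * stats::plogis(-g * (edges - d50))
  } else {
    v <- stats::plogis(-g * (edges - d50))
  }
  v[edges > config@prescriptionDose + 1e-9] <- 0  # plan doses capped at Dp
  v[v < 1e-7] <- 0
  v[1L] <- 1  # all volume receives >= 0 Gy
  v
}

.generatePlan <- function(config, pidx, modality) {
  st <- config@structureTable
  profile <- config@profiles[[modality]]
  edges <- seq(0, config@maxDose, by = config@binWidth)
  pid <- sprintf("P%02d", pidx)
  curves <- list()
  for (i in seq_len(nrow(st))) {
    row <- st[i, ]
    draws <- .structureDraws(config, pidx, row$structure, row$sdlog,
                             row$volumeSdlog)
    v <- if (identical(row$family, "target"))
      .ctvCurve(config, draws, profile, edges)
    else
      .oarCurve(config, row, draws, profile, edges)
    curves[[row$structure]] <- dvhCurve(
      edges, v, kind = "cumulative", structure = row$structure,
      patientID = pid, modality = modality,
      absVolume = row$volume * draws$volume)
  }
  planSet(curves, patientID = pid, modality = modality,
          prescriptionDose = config@prescriptionDose,
          nFractions = config@nFractions,
          dosePerFraction = config@dosePerFraction)
}

#' Generate a seeded synthetic plan cohort
#'
#' Produces \code{nPatients x 3} [PlanSet-class] objects with the paired
#' statistical structure the downstream comparison assumes: per patient, all
#' baseline random effects (median-dose effect, structure volume, gradient
#' jitter, modality-effect exponent) are drawn once per structure and shared
#' across the three modalities, so inter-patient variability cancels in
#' paired contrasts and only the modality profiles differ. Every CTV curve
#' satisfies the coverage constraint (at least 95% of the volume receives at
#' least 95% of the prescription dose) by construction. A fixed seed yields
#' an identical cohort.
#'
#' @param config a [CohortConfig-class].
#' @return Named list of [PlanSet-class] (\code{"P01_photon"}, ...), ordered
#'   by patient then modality.
#' @examples
#' cohort <- generateCohort(cohortConfig(nPatients = 2, seed = 7))
#' names(cohort)
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  out <- list()
  for (pidx in seq_len(config@nPatients)) {
    for (m in .MODALITIES) {
      plan <- .generatePlan(config, pidx, m)
      out[[paste(plan@patientID, m, sep = "_")]] <- plan
    }
  }
  out
}

#' Generate a voxel-level phantom for one plan
#'
#' Builds per-voxel dose arrays whose empirical cumulative DVH reproduces the
#' generated curve of each structure, for use as a brute-force oracle for
#' DVH-derived quantities (mean dose, dose quantiles, gEUD). Voxel doses are
#' placed deterministically at the stratified quantiles \code{(i - 0.5)/N} of
#' the curve's piecewise-linear inverse CDF, so the phantom is an exact
#' function of the configuration (no additional randomness is consumed) and
#' agreement with the DVH is limited only by stratification and bin width.
#'
#' @param config a [CohortConfig-class].
#' @param patient patient index (1-based) or patient label \code{"P01"}.
#' @param modality one of photon/proton/helium.
#' @param nVoxels voxels per structure.
#' @return A [VoxelPhantom-class].
#' @examples
#' ph <- generateVoxelPhantom(cohortConfig(seed = 3), 1, "proton")
#' @export
generateVoxelPhantom <- function(config, patient, modality, nVoxels = 2000) {
  stopifnot(is(config, "CohortConfig"))
  if (is.character(patient))
    patient <- as.integer(sub("^P", "", patient))
  if (is.na(patient) || patient < 1 || patient > config@nPatients)
    .errBadArgument("patient out of range")
  if (!modality %in% .MODALITIES)
    .errBadArgument("unknown modality")
  plan <- .generatePlan(config, patient, modality)
  q <- (seq_len(nVoxels) - 0.5) / nVoxels
  doses <- lapply(plan@curves, .inverseCDF, q = q)
  vox <- vapply(plan@curves, function(cv) cv@absVolume / nVoxels, numeric(1))
  new("VoxelPhantom", patientID = plan@patientID, modality = modality,
      doses = doses, voxelVolume = vox)
}

# Vectorized inverse of a cumulative DVH: dose at volume-at-or-above q.
# Consistent with doseAtVolume(): linear interpolation, ties resolved to the
# highest dose. Trailing zeros beyond the first are dropped so the last bin
# brackets correctly.
.inverseCDF <- function(curve, q) {
  stopifnot(curve@kind == "cumulative")
  d <- curve@doseEdges
  v <- curve@relVolume
  nz <- which(v > 0)
  keep <- if (length(nz)) seq_len(min(max(nz) + 1L, length(v))) else 1L
  d <- d[keep]
  v <- v[keep]
  if (length(d) == 1L) return(rep(d, length(q)))
  stats::approx(rev(v), rev(d), xout = pmin(q, v[1L]), ties = max,
                rule = 2)$y
}
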