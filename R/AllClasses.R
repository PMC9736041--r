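#' @import methods
NULL

.MODALITIES <- c("photon", "proton", "helium")

.STUDY_STRUCTURES <- c(
  "ctv",
  "hippocampus_ipsi", "hippocampus_contra",
  "inner_ear_ipsi", "inner_ear_contra",
  "pituitary", "brainstem", "brain", "skin"
)

.VOL_TOL <- 1e-6

#' DVHCurve: a single structure's dose-volume histogram
#'
#' Stores one structure's DVH in either cumulative form (relative volume
#' receiving at least each dose edge) or differential form (relative volume
#' per half-open dose bin \code{[edge_i, edge_{i+1})}). Relative volumes are
#' dimensionless fractions of the structure volume; the absolute structure
#' volume in cm^3 is carried as metadata and only enters the integral dose.
#'
#' @slot patientID character(1), opaque patient label.
#' @slot modality character(1), one of \code{"photon"}, \code{"proton"},
#'   \code{"helium"}.
#' @slot structure character(1), structure label (free-form; the study
#'   structures are \code{ctv}, \code{hippocampus_ipsi/contra},
#'   \code{inner_ear_ipsi/contra}, \code{pituitary}, \code{brainstem},
#'   \code{brain}, \code{skin}).
#' @slot kind character(1), \code{"cumulative"} or \code{"differential"}.
#' @slot doseEdges numeric, strictly increasing dose bin edges in Gy, all
#'   non-negative. For a cumulative curve \code{relVolume} has the same
#'   length; for a differential curve it has one element fewer.
#' @slot relVolume numeric, relative volume fractions in [0, 1].
#' @slot absVolume numeric(1), structure volume in cm^3 (> 0).
#'
#' @seealso [dvhCurve()], [cumulativeToDifferential()], [doseAtVolume()]
#' @export
setClass("DVHCurve",
  representation(
    patientID = "character",
    modality = "character",
    structure = "character",
    kind = "character",
    doseEdges = "numeric",
    relVolume = "numeric",
    absVolume = "numeric"
  )
)

setValidity("DVHCurve", function(object) {
  msg <- character()
  if (length(object@modality) != 1L || !object@modality %in% .MODALITIES)
    msg <- c(msg, sprintf("modality must be one of %s",
                          paste(.MODALITIES, collapse = ", ")))
  if (length(object@kind) != 1L ||
      !object@kind %in% c("cumulative", "differential"))
    msg <- c(msg, "kind must be 'cumulative' or 'differential'")
  d <- object@doseEdges
  v <- object@relVolume
  if (length(d) < 1L || any(!is.finite(d)))
    msg <- c(msg, "doseEdges must be finite and non-empty")
  if (any(d < 0))
    msg <- c(msg, "doseEdges must be non-negative")
  if (length(d) > 1L && any(diff(d) <= 0))
    msg <- c(msg, "doseEdges must be strictly increasing")
  if (any(!is.finite(v)))
    msg <- c(msg, "relVolume must be finite")
  if (identical(object@kind, "cumulative")) {
    if (length(v) != length(d)) {
      msg <- c(msg, "cumulative curve: relVolume and doseEdges lengths differ")
    } else {
      if (length(v) > 1L && any(diff(v) > .VOL_TOL))
        msg <- c(msg, "cumulative curve: relVolume must be nonincreasing")
      if (abs(v[1L] - 1) > .VOL_TOL)
        msg <- c(msg, "cumulative curve: first relVolume must be 1")
      if (v[length(v)] < -.VOL_TOL)
        msg <- c(msg, "cumulative curve: last relVolume must be >= 0")
    }
  } else if (identical(object@kind, "differential")) {
    if (length(v) != length(d) - 1L) {
      msg <- c(msg, "differential curve: relVolume must have length(doseEdges) - 1")
    } else {
      if (any(v < -.VOL_TOL))
        msg <- c(msg, "differential curve: relVolume must be non-negative")
      if (abs(sum(v) - 1) > .VOL_TOL)
        msg <- c(msg, "differential curve: relVolume must sum to 1")
    }
  }
  if (length(object@absVolume) != 1L || !is.finite(object@absVolume) ||
      object@absVolume <= 0)
    msg <- c(msg, "absVolume must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' PlanSet: all DVH curves of one patient under one modality
#'
#' Bundles the per-structure [DVHCurve-class] objects of a single treatment
#' plan together with the prescription metadata (total prescription dose,
#' number of fractions, dose per fraction).
#'
#' @slot patientID character(1).
#' @slot modality character(1), one of photon/proton/helium.
#' @slot prescriptionDose numeric(1), prescription dose to the CTV in Gy.
#' @slot nFractions numeric(1), number of fractions.
#' @slot dosePerFraction numeric(1), dose per fraction in Gy; the fraction
#'   schedule must multiply out to the prescription dose.
#' @slot curves named list of [DVHCurve-class], one per structure, keyed by
#'   structure label.
#'
#' @seealso [planSet()], [readDVHFile()], [metricBattery()]
#' @export
setClass("PlanSet",
  representation(
    patientID = "character",
    modality = "character",
    prescriptionDose = "numeric",
    nFractions = "numeric",
    dosePerFraction = "numeric",
    curves = "list"
  )
)

setValidity("PlanSet", function(object) {
  msg <- character()
  if (length(object@modality) != 1L || !object@modality %in% .MODALITIES)
    msg <- c(msg, "modality must be one of photon, proton, helium")
  if (object@prescriptionDose <= 0)
    msg <- c(msg, "prescriptionDose must be positive")
  if (abs(object@nFractions * object@dosePerFraction -
          object@prescriptionDose) > 1e-6)
    msg <- c(msg, "nFractions * dosePerFraction must equal prescriptionDose")
  nm <- names(object@curves)
  if (length(object@curves)) {
    if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
      msg <- c(msg, "curves must be uniquely named by structure")
    ok <- vapply(object@curves, function(x) is(x, "DVHCurve"), logical(1))
    if (!all(ok)) {
      msg <- c(msg, "curves must all be DVHCurve objects")
    } else {
      str_match <- vapply(object@curves, function(x) x@structure, character(1))
      if (!identical(unname(str_match), unname(nm)))
        msg <- c(msg, "curve structure labels must match list names")
    }
  }
  if (length(msg)) msg else TRUE
})

#' LKBParameters: one endpoint's Lyman-Kutcher-Burman parameter set
#'
#' The LKB NTCP model is parameterized by TD50 (uniform whole-organ dose at
#' which the complication probability reaches 50%), the slope parameter m and
#' the volume-effect parameter n (n = 1: parallel organ, gEUD reduces to the
#' mean dose).
#'
#' @slot structure character(1), organ label the parameters were fit for
#'   (e.g. \code{"cochlea"}).
#' @slot endpoint character(1), toxicity endpoint (\code{"tinnitus"},
#'   \code{"hearing_loss"}, \code{"endocrine_dysfunction"}).
#' @slot TD50 numeric(1), Gy, > 0.
#' @slot m numeric(1), dimensionless slope, > 0.
#' @slot n numeric(1), dimensionless volume-effect parameter in (0, 1].
#'
#' @seealso [lkbParameters()], [defaultLKBParameters()], [ntcpFromDVH()]
#' @export
setClass("LKBParameters",
  representation(
    structure = "character",
    endpoint = "character",
    TD50 = "numeric",
    m = "numeric",
    n = "numeric"
  )
)

setValidity("LKBParameters", function(object) {
  msg <- character()
  if (length(object@TD50) != 1L || !is.finite(object@TD50) || object@TD50 <= 0)
    msg <- c(msg, "TD50 must be a single positive number")
  if (length(object@m) != 1L || !is.finite(object@m) || object@m <= 0)
    msg <- c(msg, "m must be a single positive number")
  if (length(object@n) != 1L || !is.finite(object@n) ||
      object@n <= 0 || object@n > 1)
    msg <- c(msg, "n must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' ModalityProfile: how one modality shapes the synthetic curves
#'
#' Encodes the modality-level dose characteristics of the synthetic cohort:
#' the width of the CTV dose falloff and, per organ at risk, a multiplier on
#' the patient's baseline median dose plus a common multiplier on the DVH
#' falloff steepness. Ion modalities are emulated with smaller D50 factors
#' and steeper gradients than photons (less lateral scattering).
#'
#' @slot modality character(1).
#' @slot ctvSpread numeric(1), Gy, logistic scale of the CTV cumulative DVH
#'   around the prescription dose (> 0; smaller = more homogeneous target
#'   coverage).
#' @slot oarD50Factor named numeric, dimensionless multiplier (> 0) on each
#'   OAR's baseline median dose.
#' @slot oarGradient numeric(1), dimensionless multiplier (> 0) on each
#'   OAR's baseline falloff steepness.
#'
#' @seealso [modalityProfile()], [cohortConfig()]
#' @export
setClass("ModalityProfile",
  representation(
    modality = "character",
    ctvSpread = "numeric",
    oarD50Factor = "numeric",
    oarGradient = "numeric"
  )
)

setValidity("ModalityProfile", function(object) {
  msg <- character()
  if (length(object@modality) != 1L || !object@modality %in% .MODALITIES)
    msg <- c(msg, "modality must be one of photon, proton, helium")
  if (length(object@ctvSpread) != 1L || object@ctvSpread <= 0)
    msg <- c(msg, "ctvSpread must be a single positive number")
  if (length(object@oarD50Factor) &&
      (is.null(names(object@oarD50Factor)) || any(object@oarD50Factor <= 0)))
    msg <- c(msg, "oarD50Factor must be a named numeric vector of positives")
  if (length(object@oarGradient) != 1L || object@oarGradient <= 0)
    msg <- c(msg, "oarGradient must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' CohortConfig: configuration of the synthetic plan cohort
#'
#' Fully specifies a virtual cohort: number of patients, RNG seed, the
#' fraction schedule, the per-structure baseline dose model, and one
#' [ModalityProfile-class] per modality. The defaults emulate the study
#' conditions: 15 patients, 54 Gy in 30 fractions of 1.8 Gy prescribed to the
#' CTV median dose, CTV coverage D95 >= 95% of prescription, and OAR median
#' doses ordered helium < proton < photon.
#'
#' @slot nPatients numeric(1), number of patients (default 15).
#' @slot seed numeric(1), integer seed controlling all randomness.
#' @slot prescriptionDose numeric(1), Gy (default 54).
#' @slot nFractions numeric(1) (default 30).
#' @slot dosePerFraction numeric(1), Gy (default 1.8).
#' @slot binWidth numeric(1), Gy, dose grid resolution of generated curves
#'   (default 0.1).
#' @slot maxDose numeric(1), Gy, upper end of the dose grid.
#' @slot effectSdlog numeric(1) >= 0, log-scale spread of the patient-specific
#'   exponent on each modality log-factor; 0 makes every modality effect an
#'   exact constant multiplier.
#' @slot structureTable data.frame, one row per structure with the baseline
#'   generative parameters (family, median dose, inter-patient log-spread,
#'   gradient, volume, mixture parameters for brain/skin-like structures).
#' @slot profiles named list of three [ModalityProfile-class] objects
#'   (photon, proton, helium).
#'
#' @seealso [cohortConfig()], [generateCohort()]
#' @export
setClass("CohortConfig",
  representation(
    nPatients = "numeric",
    seed = "numeric",
    prescriptionDose = "numeric",
    nFractions = "numeric",
    dosePerFraction = "numeric",
    binWidth = "numeric",
    maxDose = "numeric",
    effectSdlog = "numeric",
    structureTable = "data.frame",
    profiles = "list"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nPatients < 1)
    msg <- c(msg, "nPatients must be >= 1")
  if (abs(object@nFractions * object@dosePerFraction -
          object@prescriptionDose) > 1e-6)
    msg <- c(msg, "nFractions * dosePerFraction must equal prescriptionDose")
  if (object@binWidth <= 0)
    msg <- c(msg, "binWidth must be positive")
  if (object@maxDose <= object@prescriptionDose)
    msg <- c(msg, "maxDose must exceed prescriptionDose")
  if (object@effectSdlog < 0)
    msg <- c(msg, "effectSdlog must be >= 0")
  st <- object@structureTable
  need <- c("structure", "family", "d50", "sdlog", "gradient",
            "volume", "volumeSdlog")
  if (!all(need %in% names(st)))
    msg <- c(msg, sprintf("structureTable must have columns %s",
                          paste(need, collapse = ", ")))
  if (!setequal(names(object@profiles), .MODALITIES) ||
      !all(vapply(object@profiles, function(p) is(p, "ModalityProfile"),
                  logical(1))))
    msg <- c(msg, "profiles must be a list of ModalityProfile named photon, proton, helium")
  if (all(need %in% names(st)) &&
      setequal(names(object@profiles), .MODALITIES)) {
    oars <- setdiff(st$structure[st$family != "target"], NA)
    for (m in .MODALITIES) {
      f <- object@profiles[[m]]@oarD50Factor
      if (!all(oars %in% names(f)))
        msg <- c(msg, sprintf("profile '%s' lacks oarD50Factor entries for some structures", m))
    }
  }
  if (length(msg)) msg else TRUE
})

#' VoxelPhantom: per-voxel dose arrays acting as a brute-force oracle
#'
#' Holds, for each structure of one (patient, modality) plan, an array of
#' per-voxel doses whose empirical distribution matches the plan's DVH. Used
#' to validate all DVH-derived quantities (Dmean, quantiles, gEUD) against
#' direct evaluation on voxel doses.
#'
#' @slot patientID character(1).
#' @slot modality character(1).
#' @slot doses named list of numeric vectors, per-voxel doses in Gy, >= 0.
#' @slot voxelVolume named numeric, voxel volume in cm^3 per structure;
#'   structure volume = number of voxels x voxel volume.
#'
#' @seealso [generateVoxelPhantom()]
#' @export
setClass("VoxelPhantom",
  representation(
    patientID = "character",
    modality = "character",
    doses = "list",
    voxelVolume = "numeric"
  )
)

setValidity("VoxelPhantom", function(object) {
  msg <- character()
  if (length(object@doses)) {
    if (is.null(names(object@doses)))
      msg <- c(msg, "doses must be a named list")
    if (any(vapply(object@doses, function(d) any(d < 0), logical(1))))
      msg <- c(msg, "voxel doses must be non-negative")
    if (!identical(sort(names(object@doses)), sort(names(object@voxelVolume))))
      msg <- c(msg, "voxelVolume must be named like doses")
    if (any(object@voxelVolume <= 0))
      msg <- c(msg, "voxelVolume must be positive")
  }
  if (length(msg)) msg else TRUE
})
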