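#' Accessors for ionNTCP S4 classes
#'
#' Read-only accessors for the slots of [DVHCurve-class], [PlanSet-class] and
#' [LKBParameters-class] objects.
#'
#' @param x a \code{DVHCurve}, \code{PlanSet}, \code{VoxelPhantom} or
#'   \code{LKBParameters} object.
#' @return The corresponding slot value.
#' @name accessors
#' @aliases patientID modality structureName dvhKind doseEdges relVolume
#'   absVolume prescriptionDose nFractions dosePerFraction curves
#'   structureNames
#' @examples
#' cv <- uniformDVH(54)
#' dvhKind(cv)
#' doseEdges(cv)
NULL

#' @rdname accessors
setMethod("patientID", "DVHCurve", function(x) x@patientID)
#' @rdname accessors
setMethod("patientID", "PlanSet", function(x) x@patientID)
#' @rdname accessors
setMethod("patientID", "VoxelPhantom", function(x) x@patientID)

#' @rdname accessors
setMethod("modality", "DVHCurve", function(x) x@modality)
#' @rdname accessors
setMethod("modality", "PlanSet", function(x) x@modality)
#' @rdname accessors
setMethod("modality", "VoxelPhantom", function(x) x@modality)

#' @rdname accessors
setMethod("structureName", "DVHCurve", function(x) x@structure)

#' @rdname accessors
setMethod("dvhKind", "DVHCurve", function(x) x@kind)

#' @rdname accessors
setMethod("doseEdges", "DVHCurve", function(x) x@doseEdges)

#' @rdname accessors
setMethod("relVolume", "DVHCurve", function(x) x@relVolume)

#' @rdname accessors
setMethod("absVolume", "DVHCurve", function(x) x@absVolume)

#' @rdname accessors
setMethod("prescriptionDose", "PlanSet", function(x) x@prescriptionDose)
#' @rdname accessors
setMethod("prescriptionDose", "CohortConfig", function(x) x@prescriptionDose)

#' @rdname accessors
setMethod("nFractions", "PlanSet", function(x) x@nFractions)
#' @rdname accessors
setMethod("nFractions", "CohortConfig", function(x) x@nFractions)

#' @rdname accessors
setMethod("dosePerFraction", "PlanSet", function(x) x@dosePerFraction)
#' @rdname accessors
setMethod("dosePerFraction", "CohortConfig", function(x) x@dosePerFraction)

#' @rdname accessors
setMethod("curves", "PlanSet", function(x) x@curves)

#' @rdname accessors
setMethod("structureNames", "PlanSet", function(x) names(x@curves))

setMethod("show", "DVHCurve", function(object) {
  cat(sprintf("DVHCurve: %s [%s] %s/%s\n", object@structure, object@kind,
              object@patientID, object@modality))
  cat(sprintf("  dose range: %.2f - %.2f Gy over %d edges\n",
              min(object@doseEdges), max(object@doseEdges),
              length(object@doseEdges)))
  cat(sprintf("  structure volume: %.3f cm^3\n", object@absVolume))
})

setMethod("show", "PlanSet", function(object) {
  cat(sprintf("PlanSet: patient %s, modality %s\n",
              object@patientID, object@modality))
  cat(sprintf("  prescription: %g Gy in %g x %g Gy fractions\n",
              object@prescriptionDose, object@nFractions,
              object@dosePerFraction))
  cat(sprintf("  structures (%d): %s\n", length(object@curves),
              paste(names(object@curves), collapse = ", ")))
})

setMethod("show", "LKBParameters", function(object) {
  cat(sprintf("LKBParameters: %s / %s (TD50 = %g Gy, m = %g, n = %g)\n",
              object@structure, object@endpoint, object@TD50,
              object@m, object@n))
})

setMethod("show", "ModalityProfile", function(object) {
  cat(sprintf("ModalityProfile: %s (ctvSpread = %g Gy, oarGradient = %g)\n",
              object@modality, object@ctvSpread, object@oarGradient))
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(
    "CohortConfig: %g patients x 3 modalities, seed %g\n",
    object@nPatients, object@seed))
  cat(sprintf("  prescription %g Gy in %g x %g Gy, grid %g Gy to %g Gy\n",
              object@prescriptionDose, object@nFractions,
              object@dosePerFraction, object@binWidth, object@maxDose))
  cat(sprintf("  structures: %s\n",
              paste(object@structureTable$structure, collapse = ", ")))
})

setMethod("show", "VoxelPhantom", function(object) {
  cat(sprintf("VoxelPhantom: %s/%s, %d structures\n", object@patientID,
              object@modality, length(object@doses)))
})
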