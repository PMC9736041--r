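#' @rdname accessors
#' @export
setGeneric("patientID", function(x) standardGeneric("patientID"))

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname accessors
#' @export
setGeneric("structureName", function(x) standardGeneric("structureName"))

#' @rdname accessors
#' @export
setGeneric("dvhKind", function(x) standardGeneric("dvhKind"))

#' @rdname accessors
#' @export
setGeneric("doseEdges", function(x) standardGeneric("doseEdges"))

#' @rdname accessors
#' @export
setGeneric("relVolume", function(x) standardGeneric("relVolume"))

#' @rdname accessors
#' @export
setGeneric("absVolume", function(x) standardGeneric("absVolume"))

#' @rdname accessors
#' @export
setGeneric("prescriptionDose", function(x) standardGeneric("prescriptionDose"))

#' @rdname accessors
#' @export
setGeneric("nFractions", function(x) standardGeneric("nFractions"))

#' @rdname accessors
#' @export
setGeneric("dosePerFraction", function(x) standardGeneric("dosePerFraction"))

#' @rdname accessors
#' @export
setGeneric("curves", function(x) standardGeneric("curves"))

#' @rdname accessors
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))
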