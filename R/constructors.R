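#' Construct a DVHCurve
#'
#' @param doseEdges numeric, strictly increasing dose bin edges in Gy.
#' @param relVolume numeric, relative volumes: same length as
#'   \code{doseEdges} for a cumulative curve (fraction of volume receiving at
#'   least each edge), one element fewer for a differential curve (fraction
#'   of volume in each half-open bin).
#' @param kind \code{"cumulative"} or \code{"differential"}.
#' @param structure structure label.
#' @param patientID patient label.
#' @param modality \code{"photon"}, \code{"proton"} or \code{"helium"}.
#' @param absVolume structure volume in cm^3.
#' @return A validated [DVHCurve-class] object.
#' @examples
#' dvhCurve(c(0, 10, 20), c(1, 0.4, 0), structure = "ctv")
#' @export
dvhCurve <- function(doseEdges, relVolume, kind = "cumulative",
                     structure = "structure", patientID = "anon",
                     modality = "photon", absVolume = 1) {
  new("DVHCurve", patientID = patientID, modality = modality,
      structure = structure, kind = kind,
      doseEdges = as.numeric(doseEdges), relVolume = as.numeric(relVolume),
      absVolume = as.numeric(absVolume))
}

#' Construct a PlanSet
#'
#' @param curves list of [DVHCurve-class] objects (named by structure, or
#'   names are taken from the curves' structure labels).
#' @param patientID patient label.
#' @param modality treatment modality.
#' @param prescriptionDose prescription dose in Gy.
#' @param nFractions number of fractions.
#' @param dosePerFraction dose per fraction in Gy; defaults to
#'   \code{prescriptionDose / nFractions}.
#' @return A validated [PlanSet-class].
#' @examples
#' planSet(list(uniformDVH(54, structure = "ctv")), patientID = "P01")
#' @export
planSet <- function(curves, patientID = "anon", modality = "photon",
                    prescriptionDose = 54, nFractions = 30,
                    dosePerFraction = prescriptionDose / nFractions) {
  if (is(curves, "DVHCurve")) curves <- list(curves)
  if (is.null(names(curves)) || any(!nzchar(names(curves))))
    names(curves) <- vapply(curves, function(x) x@structure, character(1))
  new("PlanSet", patientID = patientID, modality = modality,
      prescriptionDose = prescriptionDose, nFractions = nFractions,
      dosePerFraction = dosePerFraction, curves = curves)
}

#' Uniform-dose and partial-volume DVH curves
#'
#' \code{uniformDVH} builds the cumulative DVH of a structure receiving a
#' single dose uniformly over its whole volume: a step from 1 to 0 across a
#' single narrow bin centred on \code{dose}, so that the differential bin
#' midpoint equals \code{dose} exactly. \code{partialVolumeDVH} builds the
#' curve of a structure of which a fraction \code{v} receives \code{dose}
#' uniformly and the remainder receives (numerically negligible) zero dose;
#' it is the canonical fixture for checking the partial-volume and gEUD
#' formulations of the LKB model against each other.
#'
#' @param dose dose in Gy received by the irradiated volume.
#' @param v relative volume in (0, 1] receiving \code{dose}.
#' @param width width in Gy of the bin carrying the dose step; kept tiny so
#'   quantile metrics on the step are sharp.
#' @param ... passed to [dvhCurve()] (labels, absVolume).
#' @return A cumulative [DVHCurve-class].
#' @examples
#' geud(uniformDVH(46.52), n = 1)  # 46.52
#' @export
uniformDVH <- function(dose, width = 1e-9, ...) {
  if (dose < width / 2)
    .errBadArgument("dose must be >= width/2 so that bin edges are >= 0")
  dvhCurve(c(dose - width / 2, dose + width / 2), c(1, 0),
           kind = "cumulative", ...)
}

#' @rdname uniformDVH
#' @export
partialVolumeDVH <- function(dose, v, width = 1e-12, ...) {
  if (v <= 0 || v > 1)
    .errBadArgument("v must lie in (0, 1]")
  if (dose < width)
    .errBadArgument("dose must exceed width")
  if (v == 1) return(uniformDVH(dose, width = width, ...))
  # zero-dose remainder confined to a vanishing bin [0, width) so its
  # contribution to power-mean sums is below double precision
  dvhCurve(c(0, width, dose - width / 2, dose + width / 2),
           c(1, v, v, 0), kind = "cumulative", ...)
}

#' Construct an LKBParameters object
#'
#' @param structure organ label the parameters were fit for.
#' @param endpoint toxicity endpoint label.
#' @param TD50 tolerance dose in Gy at 50\% complication probability.
#' @param m slope parameter (> 0).
#' @param n volume-effect parameter in (0, 1].
#' @return A validated [LKBParameters-class].
#' @examples
#' lkbParameters("cochlea", "tinnitus", TD50 = 46.52, m = 0.35, n = 1)
#' @export
lkbParameters <- function(structure, endpoint, TD50, m, n) {
  new("LKBParameters", structure = structure, endpoint = endpoint,
      TD50 = as.numeric(TD50), m = as.numeric(m), n = as.numeric(n))
}
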