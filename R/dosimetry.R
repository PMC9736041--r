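#' Dose-volume quantiles of a cumulative DVH
#'
#' \code{doseAtVolume} returns the dose D_x received by the hottest x percent
#' of the structure volume: the dose at which the cumulative volume-at-or-
#' above equals \code{x/100}, found by piecewise-linear interpolation between
#' the bracketing curve points. On flat segments (ties) the highest dose at
#' the requested volume is returned, which makes near-maximum metrics
#' conservative and the quantile deterministic. Requests outside the curve's
#' volume range clamp to the dose range. \code{volumeAtDose} is the inverse
#' direction: the relative volume receiving at least a given dose.
#'
#' @param curve a cumulative [DVHCurve-class].
#' @param x volume in percent, 0 < x <= 100.
#' @param dose dose in Gy.
#' @return Dose in Gy (\code{doseAtVolume}) or relative volume fraction in
#'   [0, 1] (\code{volumeAtDose}).
#' @examples
#' cv <- dvhCurve(c(0, 20, 40), c(1, 0.5, 0))
#' doseAtVolume(cv, 25)  # 30 Gy
#' volumeAtDose(cv, 30)  # 0.25
#' @export
doseAtVolume <- function(curve, x) {
  .checkCumulative(curve, "doseAtVolume")
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x > 100)
    .errBadArgument("x must be a single percent value in (0, 100]")
  d <- curve@doseEdges
  v <- curve@relVolume
  q <- x / 100
  if (q > v[1L]) return(d[1L])          # clamp: more volume than the curve has
  n <- length(v)
  i <- max(which(v >= q))               # ties: highest dose at this volume
  if (v[i] == q || i == n) return(d[i])
  d[i] + (v[i] - q) * (d[i + 1L] - d[i]) / (v[i] - v[i + 1L])
}

#' @rdname doseAtVolume
#' @export
volumeAtDose <- function(curve, dose) {
  .checkCumulative(curve, "volumeAtDose")
  d <- curve@doseEdges
  v <- curve@relVolume
  if (dose <= d[1L]) return(v[1L])
  if (dose >= d[length(d)]) return(v[length(v)])
  stats::approx(d, v, xout = dose, method = "linear", ties = "ordered")$y
}

.checkCumulative <- function(curve, what) {
  if (!is(curve, "DVHCurve"))
    .errBadArgument(sprintf("%s() requires a DVHCurve", what))
  if (curve@kind != "cumulative")
    .errWrongKind(sprintf("%s() requires a cumulative curve", what))
  invisible(TRUE)
}

#' Mean dose of a DVH
#'
#' The volume-weighted mean dose, evaluated on the differential form as the
#' sum of bin fractions times bin midpoint doses. Accepts either kind of
#' curve (cumulative curves are converted internally).
#'
#' @param curve a [DVHCurve-class].
#' @return Mean dose in Gy.
#' @examples
#' dMean(dvhCurve(c(0, 10, 20), c(0.6, 0.4), kind = "differential"))  # 9
#' @export
dMean <- function(curve) {
  if (!is(curve, "DVHCurve"))
    .errBadArgument("dMean() requires a DVHCurve")
  bf <- .binFractions(curve)
  sum(bf$frac * bf$dose)
}

#' Near-maximum and near-minimum DVH dose estimators
#'
#' \code{dMax} is the dose at the last cumulative point with non-zero
#' volume-at-or-above (the smallest resolvable volume); \code{dMin} is the
#' highest dose still covering 100% of the volume. Both are DVH-robust
#' estimators of the extreme doses of the distribution.
#'
#' @param curve a cumulative [DVHCurve-class].
#' @return Dose in Gy.
#' @export
dMax <- function(curve) {
  .checkCumulative(curve, "dMax")
  v <- curve@relVolume
  nz <- which(v > 0)
  if (!length(nz)) return(curve@doseEdges[1L])
  curve@doseEdges[max(nz)]
}

#' @rdname dMax
#' @export
dMin <- function(curve) {
  .checkCumulative(curve, "dMin")
  doseAtVolume(curve, 100)
}

#' Homogeneity index of target coverage
#'
#' HI = (D5 - D95) / prescription x 100. Zero means perfectly homogeneous
#' target dose; the index is invariant under joint scaling of the curve and
#' the prescription.
#'
#' @param curve cumulative CTV [DVHCurve-class].
#' @param prescription prescription dose in Gy (> 0).
#' @return Dimensionless percent.
#' @examples
#' homogeneityIndex(dvhCurve(c(50, 53, 55, 56), c(1, 0.95, 0.05, 0)), 54)
#' @export
homogeneityIndex <- function(curve, prescription) {
  .checkCumulative(curve, "homogeneityIndex")
  if (!is.numeric(prescription) || length(prescription) != 1L ||
      prescription <= 0)
    .errBadArgument("prescription must be a single positive dose")
  (doseAtVolume(curve, 5) - doseAtVolume(curve, 95)) / prescription * 100
}

#' Inhomogeneity coefficient of target coverage
#'
#' IC = (Dmax - Dmin) / Dmean, with Dmax/Dmin the near-extreme DVH dose
#' estimators of [dMax()] and [dMin()]. Larger values indicate a more
#' variable target dose; a uniform dose gives exactly 0.
#'
#' @param curve cumulative [DVHCurve-class].
#' @return Dimensionless ratio >= 0.
#' @export
inhomogeneityCoefficient <- function(curve) {
  .checkCumulative(curve, "inhomogeneityCoefficient")
  mu <- dMean(curve)
  if (mu == 0)
    .errBadArgument("inhomogeneityCoefficient undefined for zero mean dose")
  (dMax(curve) - dMin(curve)) / mu
}

#' Integral dose
#'
#' The total energy surrogate ID = Dmean x V in Gy cm^3, using the absolute
#' structure volume carried by the curve.
#'
#' @param curve a [DVHCurve-class] with positive \code{absVolume}.
#' @return Integral dose in Gy cm^3.
#' @export
integralDose <- function(curve) {
  if (!is(curve, "DVHCurve"))
    .errBadArgument("integralDose() requires a DVHCurve")
  dMean(curve) * curve@absVolume
}

.GY_METRICS <- c("Dmean", "D1", "D5", "D50", "D95", "D99", "Dmax", "Dmin")

#' Units of the dosimetric metrics
#'
#' @param metric character vector of metric labels.
#' @return Character vector: \code{"Gy"}, \code{"Gy_cm3"}, \code{"percent"}
#'   or \code{"ratio"}.
#' @export
metricUnits <- function(metric) {
  ifelse(metric %in% .GY_METRICS, "Gy",
    ifelse(metric == "ID", "Gy_cm3",
      ifelse(metric == "HI", "percent",
        ifelse(metric == "IC", "ratio", "unknown"))))
}

#' Compute the full dosimetric metric battery of a plan
#'
#' For the CTV: Dmean, D1, D95, D99, HI and IC. For every other structure
#' (organ at risk): Dmean, D1, D50 and the integral dose ID. Results are
#' returned in long format, one row per (patient, modality, structure,
#' metric).
#'
#' @param plan a [PlanSet-class].
#' @param ctvStructure label of the target structure (default \code{"ctv"}).
#' @return data.frame with columns \code{patient_id}, \code{modality},
#'   \code{structure}, \code{metric}, \code{value}, \code{unit}.
#' @examples
#' p <- planSet(list(uniformDVH(54, structure = "ctv")), patientID = "P01")
#' metricBattery(p)
#' @export
metricBattery <- function(plan, ctvStructure = "ctv") {
  stopifnot(is(plan, "PlanSet"))
  rows <- list()
  for (cv in plan@curves) {
    cum <- if (cv@kind == "cumulative") cv else differentialToCumulative(cv)
    if (identical(cv@structure, ctvStructure)) {
      vals <- c(
        Dmean = dMean(cum),
        D1 = doseAtVolume(cum, 1),
        D95 = doseAtVolume(cum, 95),
        D99 = doseAtVolume(cum, 99),
        HI = homogeneityIndex(cum, plan@prescriptionDose),
        IC = inhomogeneityCoefficient(cum))
    } else {
      vals <- c(
        Dmean = dMean(cum),
        D1 = doseAtVolume(cum, 1),
        D50 = doseAtVolume(cum, 50),
        ID = integralDose(cum))
    }
    rows[[cv@structure]] <- data.frame(
      patient_id = plan@patientID, modality = plan@modality,
      structure = cv@structure, metric = names(vals),
      value = unname(vals), unit = metricUnits(names(vals)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
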