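#' Generalized equivalent uniform dose
#'
#' gEUD is the uniform dose producing the same effect as the heterogeneous
#' distribution: the power mean \code{(sum_i v_i D_i^(1/n))^n} over the
#' differential DVH with bin midpoint doses D_i and bin fractions v_i. For
#' n = 1 it reduces exactly to the mean dose; as n decreases it moves toward
#' the maximum dose (serial organ behaviour). Zero-dose bins contribute
#' nothing (0 raised to any positive power is 0).
#'
#' @param curve a [DVHCurve-class] (either kind).
#' @param n volume-effect parameter, > 0 (the LKB registry restricts it to
#'   (0, 1], the power mean is defined for any positive n).
#' @return gEUD in Gy.
#' @examples
#' cv <- dvhCurve(c(10, 30, 30.0002), c(0.5, 0.5), kind = "differential")
#' geud(cv, n = 1)
#' @export
geud <- function(curve, n) {
  if (!is(curve, "DVHCurve"))
    .errBadArgument("geud() requires a DVHCurve")
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n <= 0)
    .errBadArgument("n must be a single positive number")
  bf <- .binFractions(curve)
  if (!length(bf$frac))
    .errBadArgument("empty curve")
  if (n == 1) return(sum(bf$frac * bf$dose))  # exact shortcut: mean dose
  sum(bf$frac * bf$dose^(1 / n))^n
}

#' Partial-volume tolerance dose
#'
#' TD50(v) = TD50 x v^(-n): the uniform dose to a fraction v of the organ at
#' which the complication probability reaches 50%. Monotone nonincreasing in
#' v; at v = 1 it equals the whole-organ TD50.
#'
#' @param params an [LKBParameters-class].
#' @param v relative volume in (0, 1].
#' @return Tolerance dose in Gy.
#' @examples
#' toleranceDosePartial(lkbParameters("cochlea", "tinnitus", 46.52, 0.35, 1),
#'                      v = 0.5)  # 93.04
#' @export
toleranceDosePartial <- function(params, v) {
  stopifnot(is(params, "LKBParameters"))
  if (!is.numeric(v) || any(v <= 0) || any(v > 1))
    .errBadArgument("v must lie in (0, 1]")
  params@TD50 * v^(-params@n)
}

#' LKB probit argument
#'
#' t = (gEUD - TD50) / (m x TD50), the standardized distance of the
#' equivalent uniform dose from the whole-organ tolerance dose; linear in
#' gEUD with slope 1/(m TD50).
#'
#' @param gEUD equivalent uniform dose in Gy.
#' @param params an [LKBParameters-class].
#' @return Dimensionless t.
#' @export
lkbT <- function(gEUD, params) {
  stopifnot(is(params, "LKBParameters"))
  (gEUD - params@TD50) / (params@m * params@TD50)
}

#' NTCP from the probit argument
#'
#' The LKB dose-response is the standard normal integral: NTCP = Phi(t),
#' evaluated with the double-precision normal CDF. t = 0 (gEUD at TD50)
#' gives exactly 50%.
#'
#' @param t dimensionless probit argument.
#' @return Complication probability in [0, 1].
#' @export
ntcpFromT <- function(t) stats::pnorm(t)

#' NTCP of a dose distribution under the LKB model
#'
#' Chains gEUD, the probit argument and the normal CDF for one structure and
#' endpoint: \code{ntcp = Phi((gEUD(curve, n) - TD50) / (m TD50))}.
#'
#' @param curve a [DVHCurve-class].
#' @param params an [LKBParameters-class].
#' @return data.frame with one row: patient_id, modality, structure,
#'   endpoint, geud (Gy), t, ntcp (probability).
#' @examples
#' pars <- lkbParameters("cochlea", "tinnitus", 46.52, 0.35, 1)
#' ntcpFromDVH(uniformDVH(46.52), pars)$ntcp  # exactly 0.5
#' @export
ntcpFromDVH <- function(curve, params) {
  stopifnot(is(curve, "DVHCurve"), is(params, "LKBParameters"))
  g <- geud(curve, params@n)
  t <- lkbT(g, params)
  data.frame(
    patient_id = curve@patientID, modality = curve@modality,
    structure = curve@structure, endpoint = params@endpoint,
    geud = g, t = t, ntcp = ntcpFromT(t), stringsAsFactors = FALSE)
}

#' Endpoint parameter registry
#'
#' \code{defaultLKBParameters} returns the shipped registry: cochlea/tinnitus
#' (TD50 46.52 Gy, m 0.35, n 1), cochlea/hearing loss (55.57, 0.14, 1) and
#' pituitary/endocrine dysfunction (60.6, 0.08, 1). The registry lives in a
#' plain-text table (\code{inst/extdata/lkb_parameters.csv}) and
#' \code{readLKBParameters} loads any file of the same layout, so the
#' parameter set is user-editable.
#'
#' @param path CSV file with columns structure, endpoint, TD50_Gy, m, n.
#' @return List of [LKBParameters-class] objects, named
#'   \code{<structure>.<endpoint>}.
#' @examples
#' defaultLKBParameters()
#' @export
defaultLKBParameters <- function() {
  readLKBParameters(system.file("extdata", "lkb_parameters.csv",
                                package = "ionNTCP", mustWork = TRUE))
}

#' @rdname defaultLKBParameters
#' @export
readLKBParameters <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("structure", "endpoint", "TD50_Gy", "m", "n")
  if (!all(need %in% names(tab)))
    .errMalformedHeader(sprintf("parameter table must have columns %s",
                                paste(need, collapse = ", ")))
  out <- lapply(seq_len(nrow(tab)), function(i)
    lkbParameters(tab$structure[i], tab$endpoint[i], tab$TD50_Gy[i],
                  tab$m[i], tab$n[i]))
  names(out) <- paste(tab$structure, tab$endpoint, sep = ".")
  out
}

#' Default mapping of plan structures to registry organs
#'
#' The auditory parameters are fitted for the cochlea and are applied to the
#' contoured inner-ear DVHs; the pituitary maps to itself. The mapping is a
#' named character vector (plan structure -> registry structure) and can be
#' overridden in [ntcpBattery()].
#'
#' @return Named character vector.
#' @export
defaultStructureMap <- function() {
  c(inner_ear_ipsi = "cochlea",
    inner_ear_contra = "cochlea",
    pituitary = "pituitary")
}

#' NTCP battery for a plan
#'
#' Evaluates every registry endpoint on every plan structure that maps to
#' its organ: with the default registry and map this yields tinnitus and
#' hearing-loss NTCP for both inner ears and endocrine-dysfunction NTCP for
#' the pituitary. Doses enter as plan total doses without fractionation
#' correction.
#'
#' @param plan a [PlanSet-class].
#' @param params list of [LKBParameters-class] (default: shipped registry).
#' @param structureMap named character vector mapping plan structure labels
#'   to registry structure labels.
#' @return data.frame, one row per (structure, endpoint) present.
#' @export
ntcpBattery <- function(plan, params = defaultLKBParameters(),
                        structureMap = defaultStructureMap()) {
  stopifnot(is(plan, "PlanSet"))
  rows <- list()
  for (sname in names(plan@curves)) {
    organ <- unname(structureMap[sname])
    if (length(organ) != 1L || is.na(organ)) next
    for (p in params) {
      if (!identical(p@structure, organ)) next
      rec <- ntcpFromDVH(plan@curves[[sname]], p)
      rows[[paste(sname, p@endpoint, sep = ".")]] <- rec
    }
  }
  if (!length(rows))
    return(data.frame(patient_id = character(), modality = character(),
                      structure = character(), endpoint = character(),
                      geud = numeric(), t = numeric(), ntcp = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
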